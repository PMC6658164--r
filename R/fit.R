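#' Fitting configuration
#'
#' Maximum-likelihood fits run bounded quasi-Newton optimizations
#' (\code{optim(method = "L-BFGS-B")}) from \code{n_restarts} Latin-hypercube
#' starting points spread over the parameter box; the best restart wins.
#' Learning rates are fitted on their natural \[0, 1\] scale with box
#' constraints (no transform), so estimates are directly comparable across
#' animals and conditions.
#'
#' @param n_restarts Number of multi-start optimizations (default 20).
#' @param bounds Named list of \code{c(lower, upper)} per parameter.
#' @param start_box Named list of \code{c(lower, upper)} start ranges for the
#'   Latin-hypercube draws. Narrower than \code{bounds}: the likelihood is
#'   nearly flat at extreme inverse temperatures, so starts drawn there stall
#'   on a vanishing numerical gradient. The optimizer itself still searches
#'   the full \code{bounds} box, and a fixed mid-range start is always
#'   included in addition to the \code{n_restarts} drawn ones.
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param restart_seed Seed for the Latin-hypercube start points (default 1).
#' @param boundary_tol Fraction of a parameter's range within which the
#'   estimate is flagged as at-bound (default 1e-3).
#' @return A \code{fit_config} list.
#' @export
fit_config <- function(n_restarts = 20L,
                       bounds = list(alpha_pos = c(0, 1), alpha_neg = c(0, 1),
                                     beta = c(0, 50), bias = c(-5, 5),
                                     gamma_win = c(-5, 5),
                                     gamma_lose = c(-5, 5),
                                     epsilon = c(0, 5), rho = c(-10, 10)),
                       start_box = list(alpha_pos = c(0.02, 0.98),
                                        alpha_neg = c(0.02, 0.98),
                                        beta = c(0.1, 8), bias = c(-2, 2),
                                        gamma_win = c(-1, 1),
                                        gamma_lose = c(-1, 1),
                                        epsilon = c(0, 1), rho = c(-3, 3)),
                       tol = 1e-6, restart_seed = 1L, boundary_tol = 1e-3) {
  stopifnot(n_restarts >= 1, tol > 0)
  for (nm in names(bounds)) {
    if (bounds[[nm]][1] > bounds[[nm]][2]) {
      stop("empty bound interval for ", nm)
    }
  }
  structure(list(n_restarts = as.integer(n_restarts), bounds = bounds,
                 start_box = start_box,
                 tol = tol, restart_seed = as.integer(restart_seed),
                 boundary_tol = boundary_tol),
            class = "fit_config")
}

#' Maximum-likelihood fit of one model to one animal-condition's sessions
#'
#' Pools all sessions of a single animal under a single treatment (value
#' state re-initialized at each session start) and minimizes the negative
#' log-likelihood over the model's free parameters from multiple seeded
#' Latin-hypercube restarts. Deterministic given the data and
#' \code{config$restart_seed}.
#'
#' @param sessions Sessions of one animal in one condition (a list or
#'   [session_set()]). Mixing animals or treatments is an error.
#' @param model A [model_spec()].
#' @param config A [fit_config()].
#' @param q_init Initial action value at each session start (default 0).
#' @return A \code{fit_result}: fitted [param_set()], negative
#'   log-likelihood \code{nll} (recomputed at the returned parameters),
#'   \code{aic} (\eqn{2k + 2\,nll}), \code{bic}
#'   (\eqn{k \log n_{trials} + 2\,nll}), per-restart objective values,
#'   convergence and per-parameter boundary flags, and session metadata.
#' @export
fit_mle <- function(sessions, model, config = fit_config(), q_init = 0) {
  sessions <- as_session_list(sessions)
  if (length(sessions) == 0L) stop("no sessions to fit")
  n_trials <- sum(vapply(sessions, function(s) nrow(s$trials), integer(1)))
  if (n_trials < 2L) stop("need at least 2 trials")
  ids <- unique(vapply(sessions, `[[`, character(1), "mouse_id"))
  trts <- unique(vapply(sessions, `[[`, character(1), "treatment"))
  if (length(ids) > 1L || length(trts) > 1L) {
    stop("sessions mix animals or conditions: ",
         paste(ids, collapse = ","), " / ", paste(trts, collapse = ","))
  }
  dat <- pool_trials(sessions)
  pv_template <- rep(0, length(PARAM_NAMES))
  names(pv_template) <- PARAM_NAMES
  free <- model$free
  lower <- vapply(free, function(nm) config$bounds[[nm]][1], numeric(1))
  upper <- vapply(free, function(nm) config$bounds[[nm]][2], numeric(1))
  objective <- function(theta) {
    pv <- pv_template
    pv[free] <- theta
    if (model$tie_alpha) pv["alpha_neg"] <- pv["alpha_pos"]
    qlearn_negloglik_cpp(dat$choice, dat$reward, dat$session_id, pv,
                         q_init, 1e-12)
  }
  s_lower <- vapply(free, function(nm) config$start_box[[nm]][1], numeric(1))
  s_upper <- vapply(free, function(nm) config$start_box[[nm]][2], numeric(1))
  starts <- with_seed(config$restart_seed, {
    u <- lhs::randomLHS(config$n_restarts, length(free))
    sweep(sweep(u, 2, s_upper - s_lower, "*"), 2, s_lower, "+")
  })
  # fixed mid-range start on top of the drawn ones
  starts <- rbind((s_lower + s_upper) / 2, starts)
  n_starts <- nrow(starts)
  best <- NULL
  restart_values <- rep(NA_real_, n_starts)
  converged_any <- FALSE
  for (r in seq_len(n_starts)) {
    res <- tryCatch(
      optim(starts[r, ], objective, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 500,
                           factr = config$tol / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(res)) next
    restart_values[r] <- res$value
    if (res$convergence == 0) converged_any <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("all ", config$n_restarts, " restarts failed for ",
         ids, "/", trts, " model ", model$model_id)
  }
  params <- expand_params(best$par, model)
  nll <- -session_loglik(sessions, params, model, q_init = q_init)
  boundary <- abs(best$par - lower) <= config$boundary_tol * (upper - lower) |
    abs(best$par - upper) <= config$boundary_tol * (upper - lower)
  names(boundary) <- free
  k <- model$k
  structure(list(model_id = model$model_id,
                 mouse_id = ids, treatment = trts,
                 params = params, free = free,
                 nll = nll, loglik = -nll,
                 n_trials = n_trials, n_sessions = length(sessions),
                 restart_values = restart_values,
                 converged = converged_any,
                 boundary = boundary,
                 aic = 2 * k + 2 * nll,
                 bic = k * log(n_trials) + 2 * nll),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit: model %d, %s/%s, %d sessions, %d trials>\n",
              x$model_id, x$mouse_id, x$treatment, x$n_sessions, x$n_trials))
  cat(sprintf("  nll %.3f  AIC %.1f  BIC %.1f  converged %s\n",
              x$nll, x$aic, x$bic, x$converged))
  est <- vapply(x$free, function(nm) x$params[[nm]], numeric(1))
  flagged <- ifelse(x$boundary, "*", "")
  cat("  ", paste(sprintf("%s=%.3f%s", x$free, est, flagged),
                  collapse = "  "), "\n")
  if (any(x$boundary)) cat("  (* at bound)\n")
  invisible(x)
}

# One row per fit for tidy tables / joins with the ground-truth schema.
fit_result_row <- function(f) {
  data.frame(mouse_id = f$mouse_id, treatment = f$treatment,
             model_id = f$model_id,
             as.list(param_vector(f$params)),
             nll = f$nll, k = length(f$free), n_trials = f$n_trials,
             n_sessions = f$n_sessions, aic = f$aic, bic = f$bic,
             converged = f$converged, any_boundary = any(f$boundary))
}

#' Fit all animal-condition groups
#'
#' Splits a session set by (animal, treatment), fits \code{model} to each
#' group, and returns the fits joined with the line metadata.
#'
#' @param sessions A [session_set()] or list of sessions.
#' @param model A [model_spec()].
#' @param config A [fit_config()].
#' @return A list with \code{fits} (named list of \code{fit_result}, keyed
#'   \code{mouse_id.treatment}) and \code{table} (one row per group with the
#'   fitted parameters on the ground-truth CSV schema plus nll/AIC/BIC).
#' @export
fit_cohort <- function(sessions, model, config = fit_config()) {
  sessions <- as_session_list(sessions)
  key <- vapply(sessions, function(s) paste(s$mouse_id, s$treatment, sep = "."),
                character(1))
  groups <- split(sessions, factor(key, levels = unique(key)))
  fits <- lapply(groups, fit_mle, model = model, config = config)
  line_of <- vapply(groups, function(g) g[[1]]$line, character(1))
  tab <- do.call(rbind, lapply(fits, fit_result_row))
  tab <- cbind(line = line_of[match(paste(tab$mouse_id, tab$treatment,
                                          sep = "."), names(groups))],
               tab)
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}

#' Information-criterion comparison of the model family
#'
#' Fits every requested model to every (animal, condition) group and
#' tabulates negative log-likelihoods, AIC and BIC. Groups whose maximized
#' log-likelihoods violate the family's nesting order (a larger model fitting
#' worse than a model nested inside it) are treated as optimization failures
#' and refitted with twice the restarts.
#'
#' @param sessions A [session_set()] or list of sessions (all groups).
#' @param models List of [model_spec()]s (default all six).
#' @param config A [fit_config()].
#' @return A \code{model_comparison} list: \code{table} (per group x model:
#'   nll, k, aic, bic), \code{summary} (per model: summed criteria), and
#'   \code{wins} (per model: number of groups where it attains the best AIC
#'   and BIC; each column sums to the number of groups).
#' @export
compare_models <- function(sessions, models = lapply(1:6, model_spec),
                           config = fit_config()) {
  sessions <- as_session_list(sessions)
  key <- vapply(sessions, function(s) paste(s$mouse_id, s$treatment, sep = "."),
                character(1))
  groups <- split(sessions, factor(key, levels = unique(key)))
  ids <- vapply(models, `[[`, integer(1), "model_id")
  # nested chains within the family (sub-model first)
  nested_pairs <- list(c(1L, 2L), c(2L, 3L), c(2L, 4L), c(3L, 5L),
                       c(4L, 5L), c(5L, 6L))
  rows <- list()
  for (g in names(groups)) {
    fits <- lapply(models, fit_mle, sessions = groups[[g]], config = config)
    names(fits) <- as.character(ids)
    ll <- vapply(fits, `[[`, numeric(1), "loglik")
    bad <- FALSE
    for (pr in nested_pairs) {
      i <- match(pr, ids)
      if (any(is.na(i))) next
      if (ll[i[2]] < ll[i[1]] - config$tol) bad <- TRUE
    }
    if (bad) {
      config2 <- config
      config2$n_restarts <- config$n_restarts * 2L
      fits <- lapply(models, fit_mle, sessions = groups[[g]],
                     config = config2)
      names(fits) <- as.character(ids)
    }
    for (f in fits) {
      rows[[length(rows) + 1L]] <-
        data.frame(group = g, mouse_id = f$mouse_id,
                   treatment = f$treatment, model_id = f$model_id,
                   nll = f$nll, k = length(f$free),
                   aic = f$aic, bic = f$bic)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  summary <- aggregate(cbind(nll, aic, bic) ~ model_id, data = tab, FUN = sum)
  best_of <- function(crit) {
    w <- tapply(seq_len(nrow(tab)), tab$group, function(i) {
      tab$model_id[i][which.min(tab[[crit]][i])]
    })
    table(factor(unlist(w), levels = ids))
  }
  wins <- data.frame(model_id = ids,
                     aic_wins = as.integer(best_of("aic")),
                     bic_wins = as.integer(best_of("bic")))
  structure(list(table = tab, summary = summary, wins = wins,
                 n_groups = length(groups)),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model comparison over", x$n_groups, "animal-condition group(s)>\n")
  print(merge(x$summary, x$wins, by = "model_id"))
  invisible(x)
}
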