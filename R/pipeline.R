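#' Per-animal measure table
#'
#' Computes the four choice metrics (P(R), P(H), P(WS), P(LS)) for every
#' session under the three scopes (all, dynamic, steady trials), then
#' averages session values within animal x treatment — the animal is the
#' statistical unit, so one value per animal enters any later ANOVA.
#' Undefined session-level metrics (zero denominators) are excluded from the
#' within-animal average.
#'
#' @param sessions TAB sessions (list or [session_set()]).
#' @param window,thresholds,align Segmentation settings for
#'   [segment_block_states()].
#' @return A data.frame with columns \code{mouse_id}, \code{line},
#'   \code{treatment}, \code{measure}, \code{scope}, \code{value}.
#' @export
build_measure_table <- function(sessions, window = 7L,
                                thresholds = c(0.70, 0.90),
                                align = "centered") {
  sessions <- as_session_list(sessions)
  metric_names <- c("p_reward", "p_high", "p_winstay", "p_loseswitch")
  rows <- vector("list", length(sessions) * 12L)
  i <- 0L
  for (s in sessions) {
    seg <- segment_block_states(s, window = window, thresholds = thresholds,
                                align = align)
    for (scope in c("all", "dynamic", "steady")) {
      cm <- compute_choice_metrics(s$trials, scope, seg)
      for (nm in metric_names) {
        i <- i + 1L
        rows[[i]] <- data.frame(mouse_id = s$mouse_id, line = s$line,
                                treatment = s$treatment, measure = nm,
                                scope = scope, value = cm[[nm]])
      }
    }
  }
  per_session <- do.call(rbind, rows)
  per_session <- per_session[is.finite(per_session$value), ]
  out <- aggregate(value ~ mouse_id + line + treatment + measure + scope,
                   data = per_session, FUN = mean)
  out[order(out$measure, out$scope, out$line, out$mouse_id, out$treatment), ]
}

# Normalize a pipeline configuration: accept a YAML file path or a list,
# fill defaults, and build the typed config objects.
normalize_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(model_id = 1L, n_restarts = 10L, restart_seed = 1L,
                   exclusion_k = 3, match_tolerance = 0.5,
                   max_fraction_removed = 0.2, n_perm = 100L, alpha = 0.05,
                   window = 7L, thresholds = c(0.70, 0.90),
                   align = "centered", input = NULL, cohort = list())
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  ch <- config$cohort
  if (!inherits(ch, "cohort_config")) {
    args <- list()
    if (!is.null(ch$n_per_line)) args$n_per_line <- unlist(ch$n_per_line)
    if (!is.null(ch$sessions_per_treatment)) {
      args$sessions_per_treatment <- ch$sessions_per_treatment
    }
    if (!is.null(ch$effect_map)) {
      args$effect_map <- lapply(ch$effect_map, unlist)
    }
    if (!is.null(ch$alpha_range) || !is.null(ch$beta_range)) {
      ar <- if (is.null(ch$alpha_range)) c(0.15, 0.35) else unlist(ch$alpha_range)
      br <- if (is.null(ch$beta_range)) c(1.5, 3) else unlist(ch$beta_range)
      args$baseline_sampler <- function() {
        param_set(alpha = runif(1, ar[1], ar[2]), beta = runif(1, br[1], br[2]))
      }
    }
    if (!is.null(ch$treatment_shift)) {
      args$durations <- duration_model(treatment_shift = ch$treatment_shift)
    }
    config$cohort <- do.call(cohort_config, args)
  }
  config
}

#' Run the end-to-end analysis pipeline
#'
#' Generates (or loads) sessions, excludes trial-duration outlier sessions,
#' matches mean durations between CNO and DMSO sessions within each line,
#' fits the Q-learning model per animal x condition, segments blocks and
#' computes the choice metrics, runs the mixed-design ANOVAs on each
#' behavioral measure and on the fitted parameters with Bonferroni post-hoc
#' tests, and (optionally) the permutation control. Every exclusion and
#' removal decision is logged. The whole run is a pure function of
#' (config, seed): rerunning writes byte-identical outputs.
#'
#' @param config A configuration list or path to a YAML file. Recognized
#'   fields: \code{cohort} (either a [cohort_config()] or a list with
#'   \code{n_per_line}, \code{sessions_per_treatment}, \code{effect_map},
#'   \code{alpha_range}, \code{beta_range}, \code{treatment_shift}),
#'   \code{input} (a sessions file to load instead of generating),
#'   \code{model_id}, \code{n_restarts}, \code{restart_seed},
#'   \code{exclusion_k}, \code{match_tolerance},
#'   \code{max_fraction_removed}, \code{n_perm} (0 skips the permutation
#'   control), \code{alpha}, \code{window}, \code{thresholds}, \code{align}.
#' @param seed Master integer seed.
#' @param out_dir Optional directory; when given, writes
#'   \code{measures.csv}, \code{fits.csv}, \code{anova.csv},
#'   \code{posthoc.csv}, \code{permutation.csv}, \code{summary.json} and
#'   \code{run.log}.
#' @return A \code{pipeline_report} list: \code{truth} (when generated),
#'   \code{fit_table}, \code{measures}, \code{anovas}, \code{posthocs},
#'   \code{permutation}, \code{exclusion_log}, \code{match_logs},
#'   \code{summary}.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL) {
  config <- normalize_pipeline_config(config)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, paste0(...))

  # --- generate or load -----------------------------------------------------
  truth <- NULL
  if (!is.null(config$input)) {
    sessions <- read_sessions(config$input)
    note("loaded ", length(sessions), " sessions from ", config$input)
    sessions <- sessions$sessions
  } else {
    cohort <- generate_cohort(config$cohort, seed)
    sessions <- cohort$sessions$sessions
    truth <- cohort$truth
    note("generated ", length(sessions), " sessions (seed ", seed, ")")
  }

  # --- outlier exclusion ----------------------------------------------------
  excl <- exclude_duration_outliers(sessions,
                                    population_key = c("line", "treatment"),
                                    k = config$exclusion_k)
  for (s in excl$dropped) {
    note("excluded outlier session ", s$mouse_id, " day ", s$day, " (",
         s$treatment, "), mean duration ", sprintf("%.2f", s$mean_duration))
  }
  sessions <- excl$kept

  # --- duration matching within line ---------------------------------------
  lines <- unique(vapply(sessions, `[[`, character(1), "line"))
  matched <- list()
  match_logs <- list()
  for (ln in lines) {
    in_line <- Filter(function(s) s$line == ln, sessions)
    cno <- Filter(function(s) s$treatment == "CNO", in_line)
    dmso <- Filter(function(s) s$treatment == "DMSO", in_line)
    mm <- match_durations(cno, dmso, tolerance = config$match_tolerance,
                          max_fraction_removed = config$max_fraction_removed)
    match_logs[[ln]] <- mm$log
    if (nrow(mm$log)) {
      for (r in seq_len(nrow(mm$log))) {
        note("matching removed ", mm$log$group[r], " session ",
             mm$log$mouse_id[r], " day ", mm$log$day[r],
             sprintf(" (%.2f s)", mm$log$mean_duration[r]))
      }
    }
    note("line ", ln, ": duration gap after matching ",
         sprintf("%.3f", mm$gap), " s")
    matched <- c(matched, mm$matched_cno, mm$matched_dmso)
  }
  sessions <- matched

  # --- model fitting --------------------------------------------------------
  model <- model_spec(config$model_id)
  fc <- fit_config(n_restarts = config$n_restarts,
                   restart_seed = config$restart_seed)
  fits <- fit_cohort(sessions, model, fc)
  note("fitted model ", model$model_id, " to ", nrow(fits$table),
       " animal-condition groups")

  # --- behavioral measures --------------------------------------------------
  measures <- build_measure_table(sessions, window = config$window,
                                  thresholds = config$thresholds,
                                  align = config$align)

  # --- ANOVAs ---------------------------------------------------------------
  anova_rows <- list()
  run_mixed <- function(d, measure, scope) {
    res <- mixed_anova_2x2(d)
    res$measure <- measure
    res$scope <- scope
    anova_rows[[length(anova_rows) + 1L]] <<- res
    res
  }
  for (nm in unique(measures$measure)) {
    for (sc in unique(measures$scope)) {
      d <- measures[measures$measure == nm & measures$scope == sc,
                    c("mouse_id", "line", "treatment", "value")]
      # animals with an undefined cell are dropped from this analysis
      counts <- table(d$mouse_id)
      d <- d[d$mouse_id %in% names(counts)[counts == 2L], ]
      run_mixed(d, nm, sc)
    }
  }
  param_measures <- list(alpha = "alpha_pos", beta = "beta")
  posthocs <- list()
  for (nm in names(param_measures)) {
    d <- data.frame(mouse_id = fits$table$mouse_id, line = fits$table$line,
                    treatment = fits$table$treatment,
                    value = fits$table[[param_measures[[nm]]]])
    run_mixed(d, paste0("fitted_", nm), "all")
    ph <- bonferroni_posthoc(
      d, list(
        list(label = paste0(nm, ": D1R CNO vs DMSO"),
             filter = list(line = "D1R"), factor = "treatment",
             levels = c("CNO", "DMSO"), paired = TRUE),
        list(label = paste0(nm, ": D2R CNO vs DMSO"),
             filter = list(line = "D2R"), factor = "treatment",
             levels = c("CNO", "DMSO"), paired = TRUE)))
    ph$measure <- paste0("fitted_", nm)
    posthocs[[nm]] <- ph
  }
  anovas <- do.call(rbind, anova_rows)
  posthocs <- do.call(rbind, posthocs)
  rownames(posthocs) <- NULL

  # --- permutation control --------------------------------------------------
  permutation <- NULL
  if (config$n_perm > 0L) {
    pm <- measures[measures$scope %in% c("dynamic", "steady"), ]
    counts <- table(pm$mouse_id)
    complete <- names(counts)[counts == 16L]
    pm <- pm[pm$mouse_id %in% complete, ]
    permutation <- permutation_interaction_count(
      pm, n_perm = config$n_perm, alpha = config$alpha,
      seed = derive_seeds(seed, 1L))
    note("permutation control: observed ", permutation$observed_count,
         " significant interaction(s); ", permutation$n_reaching, " of ",
         permutation$n_perm, " permutations reached >= ",
         permutation$threshold)
  }

  # --- summary --------------------------------------------------------------
  ip <- function(measure) {
    r <- anovas[anovas$measure == measure &
                  anovas$effect == "line:treatment", ]
    if (nrow(r)) r$p[1] else NA_real_
  }
  php <- function(label) {
    r <- posthocs[posthocs$label == label, ]
    if (nrow(r)) r$p_bonferroni[1] else NA_real_
  }
  alpha_cut <- config$alpha
  summary <- list(
    n_sessions_analyzed = length(sessions),
    n_animals = length(unique(measures$mouse_id)),
    model_id = model$model_id,
    interaction_p = list(fitted_alpha = ip("fitted_alpha"),
                         fitted_beta = ip("fitted_beta")),
    posthoc_p = list(alpha_D1R = php("alpha: D1R CNO vs DMSO"),
                     alpha_D2R = php("alpha: D2R CNO vs DMSO"),
                     beta_D1R = php("beta: D1R CNO vs DMSO"),
                     beta_D2R = php("beta: D2R CNO vs DMSO")),
    double_dissociation = list(
      beta_interaction_significant = isTRUE(ip("fitted_beta") < alpha_cut),
      alpha_interaction_significant = isTRUE(ip("fitted_alpha") < alpha_cut),
      beta_localized_to_D1R =
        isTRUE(php("beta: D1R CNO vs DMSO") < alpha_cut) &&
        !isTRUE(php("beta: D2R CNO vs DMSO") < alpha_cut),
      alpha_localized_to_D2R =
        isTRUE(php("alpha: D2R CNO vs DMSO") < alpha_cut) &&
        !isTRUE(php("alpha: D1R CNO vs DMSO") < alpha_cut)),
    permutation = if (!is.null(permutation)) {
      list(observed_count = permutation$observed_count,
           n_reaching_threshold = permutation$n_reaching,
           threshold = permutation$threshold,
           n_perm = permutation$n_perm)
    })

  report <- structure(list(truth = truth, fit_table = fits$table,
                           fits = fits$fits, measures = measures,
                           anovas = anovas, posthocs = posthocs,
                           permutation = permutation,
                           exclusion_log = excl$log,
                           match_logs = match_logs,
                           summary = summary, log = log_lines,
                           config = config, seed = as.integer(seed)),
                      class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(measures, file.path(out_dir, "measures.csv"), row.names = FALSE)
    write.csv(fits$table, file.path(out_dir, "fits.csv"), row.names = FALSE)
    write.csv(anovas, file.path(out_dir, "anova.csv"), row.names = FALSE)
    write.csv(posthocs, file.path(out_dir, "posthoc.csv"), row.names = FALSE)
    if (!is.null(permutation)) {
      write.csv(data.frame(permutation = seq_along(permutation$perm_counts),
                           n_significant = permutation$perm_counts),
                file.path(out_dir, "permutation.csv"), row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline report>\n")
  cat("  sessions analyzed:", x$summary$n_sessions_analyzed,
      " animals:", x$summary$n_animals, "\n")
  cat(sprintf("  line x drug interaction: fitted beta p = %.4g, fitted alpha p = %.4g\n",
              x$summary$interaction_p$fitted_beta,
              x$summary$interaction_p$fitted_alpha))
  dd <- x$summary$double_dissociation
  cat("  double dissociation detected:",
      dd$beta_interaction_significant && dd$alpha_interaction_significant &&
        dd$beta_localized_to_D1R && dd$alpha_localized_to_D2R, "\n")
  invisible(x)
}

#' Parameter-recovery experiment
#'
#' Validates the estimation pipeline on synthetic ground truth: simulates
#' one or more cohorts, fits the model to every animal x condition, joins
#' fits with the generating parameters, and reports per-parameter recovery
#' statistics (truth-vs-fit correlation, median absolute error, bias)
#' together with, per cohort replicate, whether the line x drug interaction
#' on fitted alpha and beta reached significance and whether the Bonferroni
#' post-hoc tests localized each effect to the correct line. Recovery
#' statistics are computed only from the ground-truth and fit tables.
#'
#' @param config List with optional fields \code{cohort} (a
#'   [cohort_config()]), \code{model_id}, \code{n_restarts},
#'   \code{restart_seed}, \code{n_replicates} (default 1), \code{alpha}
#'   (default 0.05).
#' @param seed Master integer seed; replicate seeds are derived from it.
#' @return A \code{recovery_report}: \code{parameters} (per free parameter:
#'   correlation, median absolute error, bias), \code{replicates} (per
#'   cohort: interaction p-values and localization flags), \code{joined}
#'   (truth-fit table).
#' @export
parameter_recovery_experiment <- function(config = list(), seed = 1L) {
  defaults <- list(cohort = cohort_config(), model_id = 1L,
                   n_restarts = 10L, restart_seed = 1L, n_replicates = 1L,
                   alpha = 0.05)
  for (nm in names(defaults)) {
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  }
  model <- model_spec(config$model_id)
  fc <- fit_config(n_restarts = config$n_restarts,
                   restart_seed = config$restart_seed)
  rep_seeds <- derive_seeds(seed, config$n_replicates)
  joined_all <- list()
  rep_rows <- list()
  for (r in seq_len(config$n_replicates)) {
    cohort <- generate_cohort(config$cohort, rep_seeds[r])
    fits <- fit_cohort(cohort$sessions, model, fc)
    joined <- merge(cohort$truth, fits$table,
                    by = c("mouse_id", "treatment"),
                    suffixes = c("_true", "_fit"))
    joined$replicate <- r
    joined_all[[r]] <- joined
    ad <- function(col) {
      data.frame(mouse_id = fits$table$mouse_id, line = fits$table$line,
                 treatment = fits$table$treatment,
                 value = fits$table[[col]])
    }
    res_a <- mixed_anova_2x2(ad("alpha_pos"))
    res_b <- mixed_anova_2x2(ad("beta"))
    p_a <- res_a$p[res_a$effect == "line:treatment"]
    p_b <- res_b$p[res_b$effect == "line:treatment"]
    loc <- function(col) {
      ph <- bonferroni_posthoc(
        ad(col), list(
          list(label = "D1R", filter = list(line = "D1R"),
               factor = "treatment", levels = c("CNO", "DMSO"),
               paired = TRUE),
          list(label = "D2R", filter = list(line = "D2R"),
               factor = "treatment", levels = c("CNO", "DMSO"),
               paired = TRUE)))
      setNames(ph$p_bonferroni, ph$label)
    }
    la <- loc("alpha_pos")
    lb <- loc("beta")
    rep_rows[[r]] <- data.frame(
      replicate = r, seed = rep_seeds[r],
      alpha_interaction_p = p_a, beta_interaction_p = p_b,
      alpha_localized_to_D2R = isTRUE(la["D2R"] < config$alpha) &&
        !isTRUE(la["D1R"] < config$alpha),
      beta_localized_to_D1R = isTRUE(lb["D1R"] < config$alpha) &&
        !isTRUE(lb["D2R"] < config$alpha))
  }
  joined <- do.call(rbind, joined_all)
  params <- do.call(rbind, lapply(model$free, function(nm) {
    tr <- joined[[paste0(nm, "_true")]]
    ft <- joined[[paste0(nm, "_fit")]]
    data.frame(parameter = nm,
               correlation = if (sd(tr) > 0) cor(tr, ft) else NA_real_,
               mae = median(abs(ft - tr)),
               bias = mean(ft - tr))
  }))
  structure(list(parameters = params,
                 replicates = do.call(rbind, rep_rows),
                 joined = joined, model_id = model$model_id),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<parameter recovery: model", x$model_id, "-",
      nrow(x$replicates), "replicate(s)>\n")
  print(x$parameters, row.names = FALSE)
  invisible(x)
}
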