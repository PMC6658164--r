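#' Two-way mixed-design ANOVA (2 between x 2 within)
#'
#' Classical sums-of-squares decomposition for one between-subjects factor
#' (mouse line) and one within-subjects factor (drug), fitted through
#' \code{aov} with an \code{Error(subject)} stratum. With two within-subject
#' levels sphericity is trivially satisfied. The animal is the statistical
#' unit: supply one value per animal per drug level.
#'
#' @param data A data.frame with columns \code{mouse_id}, \code{line},
#'   \code{treatment} and \code{value}: exactly one value per animal per
#'   treatment level, two lines, two treatments.
#' @return An \code{anova_result} data.frame with one row per effect
#'   (\code{line}, \code{treatment}, \code{line:treatment}): sum of squares,
#'   \code{df1}, \code{df2}, \code{F}, \code{p}. Degenerate data with zero
#'   error variance yield \code{NA} F and p rather than an error.
#' @export
mixed_anova_2x2 <- function(data) {
  req <- c("mouse_id", "line", "treatment", "value")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(data$value))) {
    stop("undefined values must be removed before the ANOVA")
  }
  tab <- table(data$mouse_id, data$treatment)
  if (any(tab != 1L)) {
    bad <- rownames(tab)[apply(tab != 1L, 1, any)]
    stop("animal(s) without exactly one value per treatment: ",
         paste(bad, collapse = ", "))
  }
  if (length(unique(data$line)) != 2L || length(unique(data$treatment)) != 2L) {
    stop("design must be 2 lines x 2 treatments")
  }
  d <- data.frame(subject = factor(data$mouse_id),
                  line = factor(data$line),
                  treatment = factor(data$treatment),
                  value = data$value)
  fit <- aov(value ~ line * treatment + Error(subject), data = d)
  sm <- summary(fit)
  between <- sm[["Error: subject"]][[1]]
  within <- sm[["Error: Within"]][[1]]
  total_ss <- sum((d$value - mean(d$value))^2)
  pick <- function(strat, term) {
    i <- match(term, trimws(rownames(strat)))
    resid <- nrow(strat)     # residual row is last
    ss <- strat[i, "Sum Sq"]
    df1 <- strat[i, "Df"]
    ss_e <- strat[resid, "Sum Sq"]
    df2 <- strat[resid, "Df"]
    # guard the 0/0 artifacts of exactly additive or constant data: sums of
    # squares below numerical noise (relative to the data's total SS) are
    # treated as exact zeros
    tol <- 1e-10 * max(total_ss, .Machine$double.xmin)
    if (total_ss <= 0) {
      F <- NA_real_; p <- NA_real_          # constant data: undefined
    } else {
      if (ss < tol) ss <- 0
      if (ss_e < tol) {
        F <- if (ss == 0) 0 else Inf
        p <- if (ss == 0) 1 else 0
      } else {
        F <- (ss / df1) / (ss_e / df2)
        p <- pf(F, df1, df2, lower.tail = FALSE)
      }
    }
    data.frame(effect = term, ss = ss, df1 = df1, df2 = df2, F = F, p = p)
  }
  out <- rbind(pick(between, "line"),
               pick(within, "treatment"),
               pick(within, "line:treatment"))
  rownames(out) <- NULL
  structure(out, design = "mixed_2x2", class = c("anova_result", "data.frame"))
}

#' Two-way between-groups ANOVA (2 x 3, Type-II)
#'
#' Factorial ANOVA with one value per animal and two between-subjects
#' factors (mouse line x animal group, e.g. CNO / DMSO / eGFP-CNO). Type-II
#' sums of squares (via \code{car::Anova}) accommodate mildly unbalanced
#' cells.
#'
#' @param data A data.frame with columns \code{mouse_id}, \code{line},
#'   \code{group} and \code{value}, one row per animal.
#' @return An \code{anova_result} data.frame with rows \code{line},
#'   \code{group} and \code{line:group}.
#' @export
between_anova_2x3 <- function(data) {
  req <- c("mouse_id", "line", "group", "value")
  miss <- setdiff(req, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(data$mouse_id)) stop("one value per animal is required")
  d <- data.frame(line = factor(data$line), group = factor(data$group),
                  value = data$value)
  if (any(table(d$line, d$group) == 0L)) stop("empty design cell")
  fit <- lm(value ~ line * group, data = d)
  a <- car::Anova(fit, type = "II")
  df_res <- a["Residuals", "Df"]
  terms <- c("line", "group", "line:group")
  out <- do.call(rbind, lapply(terms, function(tm) {
    F <- a[tm, "F value"]
    p <- a[tm, "Pr(>F)"]
    data.frame(effect = tm, ss = a[tm, "Sum Sq"], df1 = a[tm, "Df"],
               df2 = df_res,
               F = if (is.finite(F)) F else NA_real_,
               p = if (is.finite(p)) p else NA_real_)
  }))
  rownames(out) <- NULL
  structure(out, design = "between_2x3",
            class = c("anova_result", "data.frame"))
}

#' Bonferroni-corrected post-hoc comparisons
#'
#' Runs the requested pairwise cell comparisons (paired t tests for
#' within-subject drug contrasts, two-sample t tests for between-group
#' contrasts) and multiplies each raw p-value by the family size (the number
#' of comparisons supplied), capping at 1.
#'
#' @param data A data.frame with columns \code{mouse_id}, \code{value}, and
#'   whatever factor columns the comparisons reference.
#' @param comparisons A list; each element is a list with \code{label},
#'   optional \code{filter} (named list of column = value restrictions),
#'   \code{factor} (column defining the two cells), \code{levels} (the pair
#'   to compare) and \code{paired} (logical; paired tests match observations
#'   by \code{mouse_id}).
#' @return A data.frame with one row per comparison: label, n per cell,
#'   means, raw and Bonferroni-corrected p. Comparisons with fewer than two
#'   observations in a cell are skipped with a warning.
#' @export
bonferroni_posthoc <- function(data, comparisons) {
  m <- length(comparisons)
  rows <- list()
  for (cmp in comparisons) {
    d <- data
    for (col in names(cmp$filter)) d <- d[d[[col]] == cmp$filter[[col]], ]
    a <- d[d[[cmp$factor]] == cmp$levels[1], ]
    b <- d[d[[cmp$factor]] == cmp$levels[2], ]
    if (isTRUE(cmp$paired)) {
      common <- intersect(a$mouse_id, b$mouse_id)
      a <- a[match(common, a$mouse_id), ]
      b <- b[match(common, b$mouse_id), ]
    }
    if (nrow(a) < 2L || nrow(b) < 2L) {
      warning("comparison '", cmp$label, "' has a cell with < 2 observations; skipped")
      next
    }
    tt <- tryCatch(
      if (isTRUE(cmp$paired)) {
        t.test(a$value, b$value, paired = TRUE)
      } else {
        t.test(a$value, b$value, var.equal = TRUE)
      },
      error = function(e) NULL)
    if (is.null(tt) || !is.finite(tt$p.value)) {
      # constant data: no evidence of a difference when the cells agree
      p_raw <- if (isTRUE(all.equal(mean(a$value), mean(b$value)))) 1 else
        NA_real_
      tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = p_raw)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(label = cmp$label, n1 = nrow(a), n2 = nrow(b),
                 mean1 = mean(a$value), mean2 = mean(b$value),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 p_bonferroni = min(1, m * tt$p.value))
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), n1 = integer(0), n2 = integer(0),
               mean1 = numeric(0), mean2 = numeric(0), t = numeric(0),
               df = numeric(0), p_raw = numeric(0),
               p_bonferroni = numeric(0))
  attr(out, "family_size") <- m
  out
}

# Count, over the 8 (measure, scope) analyses, how many mixed ANOVAs show a
# pseudo-line x drug interaction below `alpha`, for a given assignment of
# animals to pseudo-lines.
count_significant_interactions <- function(measures, assignment, alpha) {
  analyses <- unique(measures[, c("measure", "scope")])
  count <- 0L
  ps <- numeric(0)
  for (i in seq_len(nrow(analyses))) {
    d <- measures[measures$measure == analyses$measure[i] &
                    measures$scope == analyses$scope[i], ]
    d$line <- assignment[d$mouse_id]
    res <- mixed_anova_2x2(d)
    p <- res$p[res$effect == "line:treatment"]
    ps <- c(ps, p)
    if (is.finite(p) && p < alpha) count <- count + 1L
  }
  list(count = count, p_values = ps)
}

#' Permutation control for the count of significant interactions
#'
#' The dissociation logic rests on finding several significant line x drug
#' interactions among eight ANOVAs (four choice measures x dynamic/steady
#' state). This control repeats those eight mixed ANOVAs after randomly
#' reassigning animals to two pseudo-lines of the original sizes (sampling
#' without replacement) and counts, per permutation, the interactions with
#' \eqn{p < \alpha}.
#'
#' @param measures A measure table: columns \code{mouse_id}, \code{line},
#'   \code{treatment}, \code{measure}, \code{scope}, \code{value}, with one
#'   value per animal per cell and every animal present in all 8
#'   (measure, scope) analyses under both drug levels.
#' @param n_perm Number of permutations (default 100).
#' @param alpha Per-ANOVA significance level (default 0.05).
#' @param seed Integer seed.
#' @param threshold Count of significant interactions a permutation must
#'   reach to be tallied in \code{n_reaching} (default 3, the observed
#'   count the control was designed around).
#' @return A \code{permutation_control} list: \code{observed_count} (with
#'   the true labels), \code{perm_counts} (integer vector of length
#'   \code{n_perm}), \code{n_reaching} (permutations with count >=
#'   \code{threshold}), \code{threshold} (3), \code{n_perm}, \code{alpha}.
#' @export
permutation_interaction_count <- function(measures, n_perm = 100L,
                                          alpha = 0.05, seed = 1L,
                                          threshold = 3L) {
  if (n_perm < 1L) stop("n_perm must be >= 1")
  analyses <- unique(measures[, c("measure", "scope")])
  animals <- unique(measures$mouse_id)
  per_animal <- table(measures$mouse_id)
  if (length(unique(per_animal)) != 1L ||
      unique(per_animal) != 2L * nrow(analyses)) {
    stop("every animal needs one value per treatment for all ",
         nrow(analyses), " analyses")
  }
  true_line <- setNames(
    measures$line[match(animals, measures$mouse_id)], animals)
  observed <- count_significant_interactions(measures, true_line, alpha)
  sizes <- table(true_line)
  lines <- names(sizes)
  perm_counts <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      shuffled <- sample(animals)
      assignment <- setNames(rep(lines, times = sizes), shuffled)[animals]
      names(assignment) <- animals
      count_significant_interactions(measures, assignment, alpha)$count
    }, integer(1))
  })
  structure(list(observed_count = observed$count,
                 observed_p_values = observed$p_values,
                 perm_counts = perm_counts,
                 n_reaching = sum(perm_counts >= threshold),
                 threshold = as.integer(threshold),
                 n_perm = as.integer(n_perm), alpha = alpha),
            class = "permutation_control")
}

#' @export
print.permutation_control <- function(x, ...) {
  cat(sprintf("<permutation control: observed %d significant interaction(s); %d of %d permutations reached >= %d>\n",
              x$observed_count, x$n_reaching, x$n_perm, x$threshold))
  invisible(x)
}
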