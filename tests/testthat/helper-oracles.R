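# Independent step-by-step recomputation of the Q-learning log-likelihood,
# written directly from the update and softmax equations in plain R. Used as
# the oracle against the package's likelihood path.
oracle_loglik <- function(sessions, params, q_init = 0, floor = 1e-12) {
  if (inherits(sessions, "bandit_session")) sessions <- list(sessions)
  total <- 0
  for (s in sessions) {
    qL <- q_init; qR <- q_init; uL <- 0; uR <- 0
    tr <- s$trials
    for (t in seq_len(nrow(tr))) {
      z <- params$beta * (qL - qR) + params$rho * (uL - uR) - params$bias
      pL <- 1 / (1 + exp(-z))
      p <- if (tr$choice[t] == "L") pL else 1 - pL
      total <- total + log(max(p, floor))
      if (tr$choice[t] == "L") {
        qL <- if (tr$reward[t] == 1) {
          (1 - params$alpha_pos) * qL + params$alpha_pos - params$gamma_win
        } else {
          (1 - params$alpha_neg) * qL - params$gamma_lose
        }
        uL <- 0; uR <- uR + params$epsilon
      } else {
        qR <- if (tr$reward[t] == 1) {
          (1 - params$alpha_pos) * qR + params$alpha_pos - params$gamma_win
        } else {
          (1 - params$alpha_neg) * qR - params$gamma_lose
        }
        uR <- 0; uL <- uL + params$epsilon
      }
    }
  }
  total
}

# Textbook sums-of-squares decomposition for the 2 (between) x 2 (within)
# mixed design, computed directly from cell/subject/grand means.
oracle_mixed_anova <- function(df) {
  # df: mouse_id, line, treatment, value; balanced, complete
  subjects <- unique(df$mouse_id)
  n <- length(subjects)
  lines <- sort(unique(df$line))
  drugs <- sort(unique(df$treatment))
  grand <- mean(df$value)
  subj_mean <- tapply(df$value, df$mouse_id, mean)
  subj_line <- tapply(df$line, df$mouse_id, function(x) x[1])
  line_mean <- tapply(df$value, df$line, mean)
  drug_mean <- tapply(df$value, df$treatment, mean)
  cell_mean <- tapply(df$value, list(df$line, df$treatment), mean)
  n_line <- table(subj_line)[lines]
  # between-subjects part (2 observations per subject)
  ss_line <- 2 * sum(n_line * (line_mean[lines] - grand)^2)
  ss_subj <- 2 * sum((subj_mean - line_mean[subj_line])^2)
  # within-subjects part
  ss_drug <- n * sum((drug_mean - grand)^2)
  ss_int <- sum(vapply(lines, function(l) {
    sum(n_line[l] * (cell_mean[l, drugs] - line_mean[l] - drug_mean[drugs] +
                       grand)^2)
  }, numeric(1)))
  ss_total <- sum((df$value - grand)^2)
  ss_err2 <- ss_total - ss_line - ss_subj - ss_drug - ss_int
  df_line <- length(lines) - 1
  df_subj <- n - length(lines)
  df_drug <- length(drugs) - 1
  df_int <- df_line * df_drug
  df_err2 <- df_subj * df_drug
  F_line <- (ss_line / df_line) / (ss_subj / df_subj)
  F_drug <- (ss_drug / df_drug) / (ss_err2 / df_err2)
  F_int <- (ss_int / df_int) / (ss_err2 / df_err2)
  list(ss = c(line = ss_line, treatment = ss_drug, interaction = ss_int),
       F = c(line = F_line, treatment = F_drug, interaction = F_int),
       p = c(line = pf(F_line, df_line, df_subj, lower.tail = FALSE),
             treatment = pf(F_drug, df_drug, df_err2, lower.tail = FALSE),
             interaction = pf(F_int, df_int, df_err2, lower.tail = FALSE)))
}

# Type-II sums of squares for a two-factor between-subjects design, from
# residual sums of squares of explicitly nested least-squares fits.
oracle_type2_anova <- function(df) {
  # df: line, group, value
  rss <- function(form) sum(lm(form, data = df)$residuals^2)
  r_full <- rss(value ~ line * group)
  ss_line <- rss(value ~ group) - rss(value ~ line + group)
  ss_group <- rss(value ~ line) - rss(value ~ line + group)
  ss_int <- rss(value ~ line + group) - r_full
  n <- nrow(df)
  a <- length(unique(df$line))
  b <- length(unique(df$group))
  df_res <- n - a * b
  list(ss = c(line = ss_line, group = ss_group, interaction = ss_int),
       F = c(line = (ss_line / (a - 1)) / (r_full / df_res),
             group = (ss_group / (b - 1)) / (r_full / df_res),
             interaction = (ss_int / ((a - 1) * (b - 1))) / (r_full / df_res)))
}

# Paired one-sided sign test that `x` (CNO - DMSO differences) is negative.
sign_test_drop <- function(d) {
  binom.test(sum(d < 0), length(d), p = 0.5, alternative = "greater")$p.value
}

# CNO - DMSO difference per animal for one measure/scope from a measure table.
paired_differences <- function(measures, measure, scope, line) {
  d <- measures[measures$measure == measure & measures$scope == scope &
                  measures$line == line, ]
  w <- reshape(d[, c("mouse_id", "treatment", "value")], idvar = "mouse_id",
               timevar = "treatment", direction = "wide")
  w <- w[complete.cases(w), ]
  w$value.CNO - w$value.DMSO
}
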