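mk_mixed <- function(values, lines, ids = NULL) {
  # values: named per animal c(DMSO, CNO)
  n <- length(values)
  if (is.null(ids)) ids <- sprintf("m%02d", seq_len(n))
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(mouse_id = ids[i], line = lines[i],
               treatment = c("DMSO", "CNO"),
               value = values[[i]])
  }))
}

test_that("mixed 2x2 ANOVA matches the hand-computed decomposition", {
  d <- mk_mixed(list(c(10, 12), c(11, 15), c(20, 19), c(23, 25)),
                c("D1R", "D1R", "D2R", "D2R"))
  res <- mixed_anova_2x2(d)
  oracle <- oracle_mixed_anova(d)
  expect_equal(res$ss, unname(oracle$ss), tolerance = 1e-8)
  expect_equal(res$F, unname(oracle$F), tolerance = 1e-8)
  expect_equal(res$p, unname(oracle$p), tolerance = 1e-8)
  expect_equal(res$df1, c(1, 1, 1))
  expect_equal(res$df2, c(2, 2, 2))
  # a larger unbalanced-line fixture (4 + 3 animals)
  set.seed(8)
  vals <- lapply(1:7, function(i) round(rnorm(2, 10 + i, 2), 2))
  d2 <- mk_mixed(vals, c(rep("D1R", 4), rep("D2R", 3)))
  res2 <- mixed_anova_2x2(d2)
  oracle2 <- oracle_mixed_anova(d2)
  expect_equal(res2$F, unname(oracle2$F), tolerance = 1e-8)
  expect_equal(res2$df2, c(5, 5, 5))    # (1, n - 2) with n = 7
})

test_that("mirrored drug profiles have exactly zero interaction", {
  # both lines share the same drug effect; subjects differ in level
  d <- mk_mixed(list(c(10, 13), c(12, 15), c(20, 23), c(25, 28)),
                c("D1R", "D1R", "D2R", "D2R"))
  res <- mixed_anova_2x2(d)
  expect_equal(res$ss[res$effect == "line:treatment"], 0, tolerance = 1e-12)
  expect_equal(res$F[res$effect == "line:treatment"], 0, tolerance = 1e-12)
})

test_that("degenerate inputs give NA F, missing cells give clear errors", {
  d <- mk_mixed(list(c(5, 5), c(5, 5), c(5, 5), c(5, 5)),
                c("D1R", "D1R", "D2R", "D2R"))
  res <- mixed_anova_2x2(d)
  expect_true(all(is.na(res$F)))
  expect_true(all(is.na(res$p)))
  d_missing <- mk_mixed(list(c(1, 2), c(2, 3), c(4, 5), c(5, 6)),
                        c("D1R", "D1R", "D2R", "D2R"))
  d_missing <- d_missing[-2, ]
  expect_error(mixed_anova_2x2(d_missing), "m01")
})

test_that("between-groups 2x3 ANOVA reproduces Type-II sums of squares", {
  set.seed(21)
  d <- data.frame(
    mouse_id = sprintf("m%02d", 1:16),
    line = rep(c("D1R", "D2R"), c(9, 7)),
    group = c(rep(c("CNO", "DMSO", "eGFP-CNO"), 3),
              c("CNO", "CNO", "DMSO", "DMSO", "DMSO", "eGFP-CNO", "eGFP-CNO")),
    value = round(rnorm(16, 70, 8), 1))
  res <- between_anova_2x3(d)
  oracle <- oracle_type2_anova(d)
  expect_equal(res$ss, unname(oracle$ss), tolerance = 1e-8)
  expect_equal(res$F, unname(oracle$F), tolerance = 1e-8)
  expect_equal(res$df1, c(1, 2, 2))
  expect_equal(res$df2, rep(16 - 6, 3))
  expect_error(between_anova_2x3(d[d$group != "eGFP-CNO" | d$line != "D1R", ]),
               "empty design cell")
})

test_that("duplicating every value across lines kills the line effect", {
  base <- data.frame(mouse_id = sprintf("a%d", 1:6),
                     line = "D1R",
                     group = rep(c("CNO", "DMSO", "eGFP-CNO"), 2),
                     value = c(3, 5, 7, 4, 6, 8))
  mirror <- base
  mirror$mouse_id <- sprintf("b%d", 1:6)
  mirror$line <- "D2R"
  res <- between_anova_2x3(rbind(base, mirror))
  expect_equal(res$ss[res$effect == "line"], 0, tolerance = 1e-12)
})

test_that("Bonferroni correction is the capped multiple of the raw p", {
  set.seed(3)
  d <- mk_mixed(lapply(1:8, function(i) rnorm(2, 10, 2)),
                rep(c("D1R", "D2R"), each = 4))
  cmps <- list(
    list(label = "D1R drug", filter = list(line = "D1R"),
         factor = "treatment", levels = c("CNO", "DMSO"), paired = TRUE),
    list(label = "D2R drug", filter = list(line = "D2R"),
         factor = "treatment", levels = c("CNO", "DMSO"), paired = TRUE))
  ph <- bonferroni_posthoc(d, cmps)
  expect_equal(ph$p_bonferroni, pmin(1, 2 * ph$p_raw))
  expect_true(all(ph$p_bonferroni >= ph$p_raw))
  # identical cells: raw p = 1, corrected p = 1
  d_eq <- mk_mixed(list(c(4, 4), c(6, 6), c(5, 5), c(7, 7)),
                   rep(c("D1R", "D2R"), each = 2))
  ph_eq <- bonferroni_posthoc(d_eq, cmps)
  expect_equal(ph_eq$p_raw, c(1, 1))
  expect_equal(ph_eq$p_bonferroni, c(1, 1))
  # under-filled cells are skipped with a warning
  expect_warning(
    bonferroni_posthoc(d[d$mouse_id %in% c("m01", "m05", "m06"), ], cmps[1]),
    "skipped")
})

test_that("mixed-ANOVA interaction p-values are uniform under the null", {
  set.seed(14)
  ps <- vapply(1:200, function(i) {
    d <- mk_mixed(lapply(1:10, function(j) rnorm(2)),
                  rep(c("D1R", "D2R"), each = 5))
    res <- mixed_anova_2x2(d)
    res$p[res$effect == "line:treatment"]
  }, numeric(1))
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("permutation control reproduces the observed count and its seed", {
  set.seed(2)
  tab <- null_measure_table()
  res <- permutation_interaction_count(tab, n_perm = 20, seed = 5)
  res2 <- permutation_interaction_count(tab, n_perm = 20, seed = 5)
  expect_identical(res$perm_counts, res2$perm_counts)
  expect_length(res$observed_p_values, 8L)
  # the observed count equals an explicit rerun of the eight ANOVAs
  count <- 0L
  for (ms in unique(tab$measure)) {
    for (sc in unique(tab$scope)) {
      d <- tab[tab$measure == ms & tab$scope == sc, ]
      p <- mixed_anova_2x2(d)$p[3]
      if (is.finite(p) && p < 0.05) count <- count + 1L
    }
  }
  expect_identical(res$observed_count, count)
  expect_error(permutation_interaction_count(tab, n_perm = 0), "n_perm")
  # the paper's control ran 100 permutations by default
  expect_equal(eval(formals(permutation_interaction_count)$n_perm), 100L)
})
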