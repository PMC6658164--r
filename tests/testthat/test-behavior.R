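test_that("duration outlier exclusion drops only sessions beyond mean + 3 SD", {
  pop <- c(lapply(1:19, function(i) duration_session(10, day = i)),
           list(duration_session(100, day = 20)))
  res <- exclude_duration_outliers(pop)
  # mean 14.5, SD ~20.12, threshold ~74.9: only the 100 s session goes
  expect_length(res$dropped, 1L)
  expect_equal(res$dropped[[1]]$mean_duration, 100)
  expect_length(res$kept, 19L)
  expect_equal(res$log$threshold, 14.5 + 3 * sd(c(rep(10, 19), 100)))
})

test_that("equal durations and small populations exclude nothing", {
  pop <- lapply(1:5, function(i) duration_session(10, day = i))
  res <- exclude_duration_outliers(pop)
  expect_length(res$dropped, 0L)       # zero-SD edge: strict > never fires
  expect_warning(res1 <- exclude_duration_outliers(pop[1]), "fewer than 2")
  expect_length(res1$kept, 1L)
})

test_that("outliers are judged only against their own population", {
  # stage-4 sessions run ~100 s; stage-3 sessions ~10 s. A 130 s stage-4
  # session is unremarkable within stage 4 and must survive, even though it
  # would be an extreme outlier against the pooled durations.
  st3 <- lapply(1:10, function(i) {
    duration_session(10 + 0.1 * i, day = i, task = "reversal", stage = 3)
  })
  st4 <- lapply(1:10, function(i) {
    duration_session(100 + 3 * i, day = i, task = "reversal", stage = 4)
  })
  res <- exclude_duration_outliers(c(st3, st4))
  expect_length(res$dropped, 0L)
  expect_equal(nrow(res$log), 2L)
})

test_that("duration matching removes the single most effective session", {
  cno <- list(duration_session(10, mouse_id = "c", day = 1, treatment = "CNO"),
              duration_session(11, mouse_id = "c", day = 2, treatment = "CNO"),
              duration_session(30, mouse_id = "c", day = 3, treatment = "CNO"))
  dmso <- list(duration_session(10, mouse_id = "c", day = 4),
               duration_session(11, mouse_id = "c", day = 5),
               duration_session(12, mouse_id = "c", day = 6))
  res <- match_durations(cno, dmso, tolerance = 1, max_fraction_removed = 0.5)
  expect_equal(nrow(res$log), 1L)
  expect_equal(res$log$group, "CNO")
  expect_equal(res$log$mean_duration, 30)
  expect_lte(res$gap, 1)
  # replaying the log on the inputs reproduces the matched sets
  removed_days <- res$log$day[res$log$group == "CNO"]
  replay <- Filter(function(s) !(s$day %in% removed_days), cno)
  expect_equal(replay, res$matched_cno)
  # already within tolerance: a no-op
  res0 <- match_durations(cno[1:2], dmso[1:2], tolerance = 1)
  expect_equal(nrow(res0$log), 0L)
  expect_length(res0$matched_cno, 2L)
})

test_that("segmentation handles saturated and zero-max blocks", {
  # every trial on the high side: first smoothed value already exceeds both
  # thresholds, so no dynamic state and the whole block is steady
  s_hi <- fixture_session(choice = rep("L", 20), reward = rep(1, 20),
                          high_side = rep("L", 20))
  seg <- segment_block_states(s_hi)
  expect_length(seg$blocks[[1]]$dynamic, 0L)
  expect_equal(seg$blocks[[1]]$steady, 1:20)
  # no high-side choice: M = 0, strict 'exceeds' never fires
  s_lo <- fixture_session(choice = rep("R", 20), reward = rep(0, 20),
                          high_side = rep("L", 20))
  seg <- segment_block_states(s_lo)
  expect_equal(seg$blocks[[1]]$dynamic, 1:20)
  expect_length(seg$blocks[[1]]$steady, 0L)
})

test_that("segmentation matches an independent hand trace on a ramp block", {
  # 40-trial block: 10 low-side then 30 high-side choices
  choices <- c(rep("R", 10), rep("L", 30))
  s <- fixture_session(choice = choices, reward = rep(1, 40),
                       high_side = rep("L", 40))
  seg <- segment_block_states(s, window = 7)
  # independent trace of the centered truncated moving average
  h <- as.numeric(choices == "L")
  sm <- vapply(1:40, function(t) mean(h[max(1, t - 3):min(40, t + 3)]),
               numeric(1))
  M <- max(sm)
  exp_dyn_end <- which(sm > 0.7 * M)[1]
  exp_steady_start <- which(sm > 0.9 * M)[1]
  expect_equal(seg$blocks[[1]]$smoothed, sm)
  expect_equal(seg$blocks[[1]]$dynamic, seq_len(exp_dyn_end - 1))
  expect_equal(seg$blocks[[1]]$steady, seq.int(exp_steady_start, 40))
  # the three segments tile the block
  b <- seg$blocks[[1]]
  gap <- b$n_trials - length(b$dynamic) - length(b$steady)
  expect_equal(length(b$dynamic) + gap + length(b$steady), 40)
  expect_gte(gap, 0)
})

test_that("segmentation is invariant to relabeling left and right", {
  set.seed(5)
  s <- simulate_tab_session(param_set(alpha = 0.3, beta = 2), model_spec(1),
                            seed = 12)
  flip <- function(x) ifelse(x == "L", "R", "L")
  tr <- s$trials
  tr$choice <- flip(tr$choice)
  tr$high_side <- flip(tr$high_side)
  bp <- s$block_probs
  s2 <- session(s$mouse_id, s$line, s$treatment, s$task, s$stage, s$day,
                trials = tr,
                block_probs = data.frame(block = bp$block,
                                         p_left = bp$p_right,
                                         p_right = bp$p_left))
  seg1 <- segment_block_states(s)
  seg2 <- segment_block_states(s2)
  for (b in seq_along(seg1$blocks)) {
    expect_identical(seg1$blocks[[b]]$dynamic, seg2$blocks[[b]]$dynamic)
    expect_identical(seg1$blocks[[b]]$steady, seg2$blocks[[b]]$steady)
  }
})

test_that("choice metrics count stays, switches and rewards correctly", {
  s <- fixture_session(choice = c("L", "L", "R", "R", "L"),
                       reward = c(1, 0, 0, 1, 0),
                       high_side = rep("L", 5))
  cm <- compute_choice_metrics(s$trials)
  expect_equal(cm$p_reward, 2 / 5)
  expect_equal(cm$p_high, 3 / 5)
  # predecessors: t2 (win, stay), t3 (loss, switch), t4 (loss, stay),
  # t5 (win, switch) -> P(WS) = 1/2, P(LS) = 1/2
  expect_equal(cm$p_winstay, 1 / 2)
  expect_equal(cm$p_loseswitch, 1 / 2)
  expect_equal(cm$counts$denominator, c(5, 5, 2, 2))
  # no rewarded trials: P(WS) undefined, P(LS) defined
  s0 <- fixture_session(choice = c("L", "R", "L"), reward = c(0, 0, 0))
  cm0 <- compute_choice_metrics(s0$trials)
  expect_true(is.na(cm0$p_winstay))
  expect_false(is.na(cm0$p_loseswitch))
  expect_error(compute_choice_metrics(s$trials, "dynamic"),
               "requires a segmentation")
})

test_that("scoped metrics use the true preceding trial as predecessor", {
  # block of 12: first 6 low-side, last 6 high-side; steady state begins
  # inside the block, so trial predecessors at the scope edge lie outside it
  choices <- c(rep("R", 6), rep("L", 6))
  rewards <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1, 1, 1)
  s <- fixture_session(choice = choices, reward = rewards,
                       high_side = rep("L", 12))
  seg <- segment_block_states(s, window = 3)
  cm <- compute_choice_metrics(s$trials, "steady", seg)
  st <- seg$blocks[[1]]$steady
  expect_gt(st[1], 1)
  # oracle: evaluate predecessors on the raw trial sequence
  idx <- st[st >= 2]
  prev_win <- rewards[idx - 1] == 1
  stays <- choices[idx] == choices[idx - 1]
  expect_equal(cm$p_winstay, sum(stays[prev_win]) / sum(prev_win))
  expect_equal(cm$counts$denominator[3], sum(prev_win))
  # all-scope metrics equal the weighted recomputation from raw indicators
  cm_all <- compute_choice_metrics(s$trials, "all")
  expect_equal(cm_all$p_reward, mean(rewards))
  expect_equal(cm_all$p_high, mean(choices == "L"))
})

test_that("pre-transition profile is flat for agents, rising for an oracle", {
  # bookkeeping: every completed block contributes one trial per position
  p <- param_set(alpha = 0.3, beta = 2)
  sess <- lapply(1:50, function(i) {
    simulate_tab_session(p, model_spec(1), seed = 400 + i, day = i)
  })
  prof <- pre_transition_choice_profile(sess, window = 10)
  expect_equal(prof$n, rep(50L * 3L, 10))   # 3 completed blocks per session
  # memoryless agents cannot anticipate the uncued transition
  fit <- lm(p_low ~ position, data = prof)
  slope_t <- summary(fit)$coefficients["position", ]
  p_pos <- pt(slope_t["t value"], df = fit$df.residual, lower.tail = FALSE)
  expect_gt(p_pos, 0.01)
  # constructed anticipating chooser: switches 5 trials before transitions
  sw <- lapply(sess[1:10], function(s) {
    tr <- s$trials
    for (b in unique(tr$block_index)[-4]) {
      rows <- which(tr$block_index == b)
      late <- tail(rows, 5)
      tr$choice[rows] <- tr$high_side[rows]
      tr$choice[late] <- ifelse(tr$high_side[late] == "L", "R", "L")
    }
    session(s$mouse_id, s$line, s$treatment, s$task, s$stage, s$day,
            trials = tr, block_probs = s$block_probs)
  })
  prof_sw <- pre_transition_choice_profile(sw, window = 10)
  prof_sw <- prof_sw[order(prof_sw$position), ]
  expect_equal(prof_sw$p_low, c(rep(0, 5), rep(1, 5)))
})

test_that("Q-value profiles use blocks 2-4 with truncated windows", {
  p <- param_set(alpha = 0.3, beta = 2)
  m <- model_spec(1)
  sess <- lapply(1:4, function(d) {
    simulate_tab_session(p, m, seed = 40 + d, mouse_id = "a", day = d,
                         treatment = "DMSO")
  })
  f <- fit_mle(sess, m, fit_config(n_restarts = 5))
  qp <- qvalue_block_profile(sess, list(a.DMSO = f))
  expect_equal(sort(unique(qp$aligned_post$position)), 1:15)
  expect_equal(sort(unique(qp$aligned_pre$position)), -10:-1)
  expect_setequal(qp$state_means$state, c("dynamic", "steady"))
  # truncation: 12-trial blocks cap the post window at 12
  short <- simulate_tab_session(p, m,
                                tab_task_config(block_lengths = 12L),
                                seed = 99, mouse_id = "a", treatment = "DMSO")
  f2 <- fit_mle(list(short), m, fit_config(n_restarts = 5))
  qp2 <- qvalue_block_profile(list(short), list(a.DMSO = f2))
  expect_equal(max(qp2$aligned_post$position), 12)
  expect_error(qvalue_block_profile(sess, list()), "no fit for")
})
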