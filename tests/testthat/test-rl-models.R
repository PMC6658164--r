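test_that("value updates follow the outcome-dependent learning rule", {
  m <- model_spec(1)
  q <- action_values(0.4, 0.2)
  out <- update_values(q, "L", 1, param_set(alpha = 0.5, beta = 1), m)
  expect_equal(out$q_left, 0.7)
  expect_equal(out$q_right, 0.2)   # unchosen side untouched

  m5 <- model_spec(5)
  p5 <- param_set(alpha_pos = 0.5, alpha_neg = 0.3, beta = 1,
                  gamma_win = 0.1, gamma_lose = 0.05)
  out <- update_values(action_values(0.4, 0), "L", 1, p5, m5)
  expect_equal(out$q_left, 0.5 * 0.4 + 0.5 * 1 - 0.1)  # 0.6
  out <- update_values(action_values(0.4, 0), "L", 0, p5, m5)
  expect_equal(out$q_left, 0.7 * 0.4 - 0.05)

  # zero learning rate: values unchanged whatever the outcome
  p0 <- param_set(alpha = 0, beta = 2)
  for (rw in c(0, 1)) {
    out <- update_values(action_values(0.3, 0.6), "R", rw, p0, m)
    expect_equal(out$q_left, 0.3)
    expect_equal(out$q_right, 0.6)
  }
})

test_that("softmax choice probability matches the logistic form", {
  m <- model_spec(1)
  for (beta in c(0, 0.5, 3, 40)) {
    expect_equal(choice_prob_left(action_values(0.5, 0.5),
                                  param_set(alpha = 0.5, beta = beta), m),
                 0.5)
  }
  expect_equal(choice_prob_left(action_values(1, 0),
                                param_set(alpha = 0.5, beta = log(3)), m),
               0.75)
  # logistic antisymmetry in the bias at beta = 0
  m2 <- model_spec(2)
  p_pos <- choice_prob_left(action_values(0, 0),
                            param_set(alpha = 0.5, beta = 0, bias = 1), m2)
  p_neg <- choice_prob_left(action_values(0, 0),
                            param_set(alpha = 0.5, beta = 0, bias = -1), m2)
  expect_equal(p_pos + p_neg, 1)
  expect_lt(p_pos, 0.5)   # positive b disfavors left (verbatim sign convention)
  expect_equal(left_bias(param_set(alpha = 0.5, beta = 1, bias = 1)), -1)
  # saturates without numerical exceptions
  expect_equal(choice_prob_left(action_values(1e4, -1e4),
                                param_set(alpha = 0.5, beta = 50), m), 1)
})

test_that("P(L) + P(R) = 1 and P(L) increases with beta when Q_L > Q_R", {
  set.seed(11)
  for (i in 1:20) {
    mid <- sample(1:6, 1)
    m <- model_spec(mid)
    p <- random_params_for_model(mid)
    q <- action_values(runif(1, -1, 2), runif(1, -1, 2),
                       runif(1, 0, 3), runif(1, 0, 3))
    pL <- choice_prob_left(q, p, m)
    expect_gte(pL, 0)
    expect_lte(pL, 1)
    # P(R) via the mirrored state equals 1 - P(L) when bias/uncertainty mirror
    q_sw <- action_values(q$q_right, q$q_left, q$u_right, q$u_left)
    p_nb <- do.call(param_set, modifyList(unclass(p), list(bias = 0)))
    m_nb <- m
    expect_equal(choice_prob_left(q, p_nb, m_nb) +
                   choice_prob_left(q_sw, p_nb, m_nb), 1)
  }
  m <- model_spec(1)
  q <- action_values(0.8, 0.3)
  probs <- vapply(c(0.5, 1, 2, 4, 8), function(b) {
    choice_prob_left(q, param_set(alpha = 0.5, beta = b), m)
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
})

test_that("session log-likelihood matches closed forms and is additive", {
  s <- fixture_session(choice = c("L", "L", "R", "R", "L"),
                       reward = c(1, 0, 0, 1, 0))
  m2 <- model_spec(2)
  # beta = 0, b = 0: every choice has probability exactly 1/2
  p_null <- param_set(alpha = 0.3, beta = 0, bias = 0)
  expect_equal(session_loglik(s, p_null, m2), 5 * log(0.5))
  # matches the independent trial-by-trial oracle on the 5-trial fixture
  p <- param_set(alpha = 0.4, beta = 2.5, bias = 0.3)
  expect_equal(session_loglik(s, p, m2), oracle_loglik(s, p), tolerance = 1e-12)
  # additivity over sessions under per-session re-initialization
  s2 <- fixture_session(choice = c("R", "L", "L"), reward = c(0, 1, 1),
                        day = 2L)
  expect_equal(session_loglik(list(s, s2), p, m2),
               session_loglik(s, p, m2) + session_loglik(s2, p, m2))
  expect_error(session_loglik(list(), p, m2), "at least one")
})

test_that("log-likelihood equals the step-by-step oracle on short sessions", {
  set.seed(202)
  for (i in 1:30) {
    mid <- sample(1:6, 1)
    m <- model_spec(mid)
    p <- random_params_for_model(mid)
    n <- sample(2:10, 1)
    s <- fixture_session(choice = sample(c("L", "R"), n, replace = TRUE),
                         reward = sample(0:1, n, replace = TRUE),
                         high_side = rep(sample(c("L", "R"), 1), n))
    expect_equal(session_loglik(s, p, m), oracle_loglik(s, p),
                 tolerance = 1e-10)
  }
})

test_that("value trajectory replays the observed history", {
  s <- fixture_session(choice = c("L", "L", "R", "L"), reward = c(1, 0, 1, 1),
                       high_side = rep("L", 4))
  m <- model_spec(1)
  p <- param_set(alpha = 0.5, beta = 2)
  traj <- value_trajectory(s, p, m)
  expect_equal(traj$q_left[1], 0)    # configured initial values
  expect_equal(traj$q_right[1], 0)
  # equals iterative application of update_values (pre-choice values)
  q <- action_values(0, 0)
  for (t in 1:4) {
    expect_equal(traj$q_left[t], q$q_left)
    expect_equal(traj$q_right[t], q$q_right)
    expect_equal(traj$p_left[t], choice_prob_left(q, p, m))
    q <- update_values(q, s$trials$choice[t], s$trials$reward[t], p, m)
  }
  # q_high maps through high_side
  expect_equal(traj$q_high, traj$q_left)
  expect_equal(traj$q_low, traj$q_right)
  # alpha = 1: the trial after the first rewarded high-side choice has q_high = 1
  p1 <- param_set(alpha = 1, beta = 2)
  traj1 <- value_trajectory(s, p1, m)
  expect_equal(traj1$q_high[2], 1)
})

test_that("nested models attain non-decreasing maximized likelihoods", {
  gen <- param_set(alpha_pos = 0.4, alpha_neg = 0.3, beta = 2, bias = 0.3,
                   gamma_win = 0.1, gamma_lose = -0.1)
  sess <- lapply(1:3, function(d) {
    simulate_tab_session(gen, model_spec(5), seed = 500 + d, day = d)
  })
  fc <- fit_config(n_restarts = 8)
  ll <- vapply(c(1, 2, 4, 5), function(mid) {
    fit_mle(sess, model_spec(mid), fc)$loglik
  }, numeric(1))
  expect_true(all(diff(ll) >= -1e-4))  # model 5 >= 4 >= 2 >= 1
})

test_that("chosen-side value converges to the reward probability", {
  # an agent forced to choose L with reward Bernoulli(0.6): E[Q_L] -> 0.6
  set.seed(33)
  n <- 3000
  rewards <- rbinom(n, 1, 0.6)
  s <- fixture_session(choice = rep("L", n), reward = rewards)
  traj <- value_trajectory(s, param_set(alpha = 0.2, beta = 1), model_spec(1))
  tail_q <- traj$q_left[(n - 500):n]
  # stationary variance of Q under alpha = 0.2: alpha * p(1-p) / (2 - alpha)
  mc_se <- sqrt(0.2 * 0.6 * 0.4 / (2 - 0.2)) / sqrt(50)  # ~50 indep. stretches
  expect_lt(abs(mean(tail_q) - 0.6), 3 * mc_se)
})

test_that("parameter sets and model constraints are enforced", {
  expect_error(param_set(alpha = 1.2, beta = 1), "learning rates")
  expect_error(param_set(alpha = 0.5, beta = -1), "beta")
  expect_error(model_spec(7), "between 1 and 6")
  expect_error(
    session_loglik(fixture_session("L", 1),
                   param_set(alpha = 0.5, beta = 1, bias = 2), model_spec(1)),
    "constrains bias")
  expect_error(
    update_values(action_values(), "L", 1,
                  param_set(alpha_pos = 0.2, alpha_neg = 0.6, beta = 1),
                  model_spec(2)),
    "alpha_pos = alpha_neg")
})
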