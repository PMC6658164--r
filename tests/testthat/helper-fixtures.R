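# Build a small session from explicit trial vectors. block_probs are derived
# from high_side (0.72/0.12 per block) for TAB sessions.
fixture_session <- function(choice, reward,
                            high_side = rep("L", length(choice)),
                            block_index = rep(1L, length(choice)),
                            duration = rep(10, length(choice)),
                            mouse_id = "m1", line = "D1R", treatment = "DMSO",
                            task = "TAB", stage = NA, day = 1L,
                            p_high = 0.72, p_low = 0.12) {
  trials <- data.frame(trial_index = seq_along(choice),
                       block_index = as.integer(block_index),
                       choice = choice, reward = as.integer(reward),
                       duration = duration, high_side = high_side)
  block_probs <- NULL
  if (task == "TAB") {
    blocks <- unique(trials$block_index)
    first_high <- vapply(blocks, function(b) {
      high_side[match(b, block_index)]
    }, character(1))
    block_probs <- data.frame(
      block = blocks,
      p_left = ifelse(first_high == "L", p_high, p_low),
      p_right = ifelse(first_high == "R", p_high, p_low))
  }
  session(mouse_id = mouse_id, line = line, treatment = treatment,
          task = task, stage = stage, day = day, trials = trials,
          block_probs = block_probs)
}

# A session whose durations are all `dur` (choices irrelevant).
duration_session <- function(dur, mouse_id = "m1", day = 1L,
                             treatment = "DMSO", line = "D1R", stage = NA,
                             task = "TAB") {
  fixture_session(choice = c("L", "R", "L", "R"), reward = c(1, 0, 1, 0),
                  duration = rep(dur, 4), mouse_id = mouse_id, day = day,
                  treatment = treatment, line = line, stage = stage,
                  task = task)
}

# Exchangeable measure table: iid values, no line effect anywhere.
null_measure_table <- function(n1 = 10, n2 = 9) {
  ids <- sprintf("m%02d", seq_len(n1 + n2))
  g <- expand.grid(
    mouse_id = ids,
    treatment = c("DMSO", "CNO"),
    measure = c("p_reward", "p_high", "p_winstay", "p_loseswitch"),
    scope = c("dynamic", "steady"), stringsAsFactors = FALSE)
  g$line <- ifelse(match(g$mouse_id, ids) <= n1, "D1R", "D2R")
  g$value <- rnorm(nrow(g))
  g
}

# Draw a random valid parameter set for a given model variant.
random_params_for_model <- function(model_id) {
  ms <- model_spec(model_id)
  a_pos <- runif(1, 0.05, 0.95)
  a_neg <- if (ms$tie_alpha) a_pos else runif(1, 0.05, 0.95)
  param_set(alpha_pos = a_pos, alpha_neg = a_neg,
            beta = runif(1, 0, 8),
            bias = if ("bias" %in% ms$free) runif(1, -2, 2) else 0,
            gamma_win = if ("gamma_win" %in% ms$free) runif(1, -0.5, 0.5) else 0,
            gamma_lose = if ("gamma_lose" %in% ms$free) runif(1, -0.5, 0.5) else 0,
            epsilon = if ("epsilon" %in% ms$free) runif(1, 0, 1) else 0,
            rho = if ("rho" %in% ms$free) runif(1, -2, 2) else 0)
}
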