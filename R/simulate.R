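#' @name synthetic-data
#' @title Seeded generators for tasks, agents and cohorts
#'
#' @description
#' Generators that emulate the study design: a dynamic two-armed-bandit (TAB)
#' task with four uncued blocks whose 72%/12% reward probabilities reverse at
#' each transition, a five-stage reversal task with progressively increasing
#' reversal frequency, log-normal trial durations with a session-level random
#' effect and a CNO shift, and full two-line cohorts of Q-learning agents
#' with known ground-truth parameters. All randomness flows through the
#' supplied seed (R's default Mersenne-Twister generator) and the caller's
#' RNG state is left untouched.
NULL

#' TAB task configuration
#'
#' Four blocks per session; each block length is drawn uniformly from
#' \code{block_lengths}; one side rewards with probability \code{p_high}
#' (default 0.72) and the other with \code{p_low} (default 0.12), and the
#' assignment reverses at every block transition.
#'
#' @param n_blocks Number of blocks (default 4).
#' @param block_lengths Candidate block lengths (default \code{c(35,40,45,50)}).
#' @param p_high,p_low Reward probabilities of the richer / leaner side.
#' @param first_block_side Side that is richer in block 1: \code{"L"},
#'   \code{"R"}, or \code{"random"}.
#' @return A \code{tab_task_config} list.
#' @export
tab_task_config <- function(n_blocks = 4, block_lengths = c(35L, 40L, 45L, 50L),
                            p_high = 0.72, p_low = 0.12,
                            first_block_side = "random") {
  stopifnot(n_blocks >= 1, all(block_lengths >= 1),
            p_low >= 0, p_low < p_high, p_high <= 1,
            first_block_side %in% c("L", "R", "random"))
  structure(list(n_blocks = as.integer(n_blocks),
                 block_lengths = as.integer(block_lengths),
                 p_high = p_high, p_low = p_low,
                 first_block_side = first_block_side),
            class = "tab_task_config")
}

#' Reversal task configuration
#'
#' Five training stages: stages 1-4 run 60-trial daily sessions and stage 5
#' runs 90-trial sessions. Stages 1-2 have a fixed rewarded side (stage 2 the
#' opposite of stage 1); from stage 3 on the rewarded side flips across
#' sessions; stage 4 adds one within-session reversal taking effect at trial
#' 31 and stage 5 two, at trials 31 and 61.
#'
#' @param stage_days Days of training per stage (defaults 3, 4, 4, 4, 4).
#' @param trials_per_session Trials per daily session per stage.
#' @param within_session_reversal_trials List (per stage) of trial indices at
#'   which the rewarded side changes within a session.
#' @param across_session_reversal Logical per stage: rewarded side flips from
#'   the previous day's.
#' @return A \code{reversal_task_config} list.
#' @export
reversal_task_config <- function(stage_days = c(3L, 4L, 4L, 4L, 4L),
                                 trials_per_session = c(60L, 60L, 60L, 60L, 90L),
                                 within_session_reversal_trials =
                                   list(integer(0), integer(0), integer(0),
                                        31L, c(31L, 61L)),
                                 across_session_reversal =
                                   c(FALSE, FALSE, TRUE, TRUE, TRUE)) {
  stopifnot(length(stage_days) == 5, length(trials_per_session) == 5,
            length(within_session_reversal_trials) == 5,
            length(across_session_reversal) == 5)
  for (st in 1:5) {
    rv <- within_session_reversal_trials[[st]]
    if (length(rv) &&
        any(rv <= 1L | rv > trials_per_session[st])) {
      stop("within-session reversal trials must lie strictly inside the session")
    }
  }
  structure(list(stage_days = as.integer(stage_days),
                 trials_per_session = as.integer(trials_per_session),
                 within_session_reversal_trials =
                   lapply(within_session_reversal_trials, as.integer),
                 across_session_reversal = across_session_reversal),
            class = "reversal_task_config")
}

#' Trial-duration model
#'
#' Durations are log-normal: per session a random effect is drawn with sd
#' \code{session_sd} on the log scale, and per trial
#' \code{log(duration) = log_mean + session effect + N(0, log_sd)}. CNO
#' sessions have their durations multiplied by \code{treatment_shift},
#' producing the systematic slowing that the outlier-exclusion and
#' duration-matching stages are designed to handle.
#'
#' @param log_mean Mean of log duration (default \code{log(8)}: 8-second
#'   trials).
#' @param log_sd Per-trial sd on the log scale (default 0.35).
#' @param session_sd Session-level random-effect sd on the log scale
#'   (default 0.25).
#' @param treatment_shift Multiplicative duration factor for CNO sessions
#'   (default 1.3).
#' @return A \code{duration_model} list.
#' @export
duration_model <- function(log_mean = log(8), log_sd = 0.35,
                           session_sd = 0.25, treatment_shift = 1.3) {
  stopifnot(log_sd >= 0, session_sd >= 0, treatment_shift > 0)
  structure(list(log_mean = log_mean, log_sd = log_sd,
                 session_sd = session_sd, treatment_shift = treatment_shift),
            class = "duration_model")
}

# Draw n per-trial durations for one session (all > 0 by construction).
draw_durations <- function(n, dmodel, treatment = "DMSO") {
  shift <- if (treatment == "CNO") dmodel$treatment_shift else 1
  sess_effect <- rnorm(1, 0, dmodel$session_sd)
  shift * exp(dmodel$log_mean + sess_effect + rnorm(n, 0, dmodel$log_sd))
}

#' Cohort configuration
#'
#' Defines a synthetic two-line TAB cohort: \code{n_per_line} animals per
#' line (defaults 20 D1R, 19 D2R), each tested on 10 CNO and 10 DMSO
#' sessions on alternating days with the first-day drug counterbalanced
#' across animals. Each animal draws a baseline parameter set from
#' \code{baseline_sampler}; its CNO parameters are the baseline multiplied by
#' \code{effect_map[[line]]} (defaults: CNO scales \code{beta} by 0.6 in D1R
#' and both learning rates by 0.5 in D2R — the inactivation effects on
#' action-selection gain and learning rate).
#'
#' @param n_per_line Named integer vector, animals per line.
#' @param sessions_per_treatment Sessions per drug per animal (default 10).
#' @param model A [model_spec()] for the generating agents (default model 1).
#' @param baseline_sampler Function() returning a [param_set()] for one
#'   animal; the default draws \code{alpha ~ U(0.15, 0.35)} and
#'   \code{beta ~ U(1.5, 3)}, a regime calibrated so that realized
#'   dynamic-state lengths (~7-8 trials) and session-level P(H) match
#'   values typical of over-trained mice on this task.
#' @param effect_map Named list (per line) of named multiplicative factors on
#'   parameters, applied to CNO sessions. Factor names must be parameter
#'   names; \code{"alpha"} scales both learning rates.
#' @param task A [tab_task_config()].
#' @param durations A [duration_model()].
#' @return A \code{cohort_config} list.
#' @export
cohort_config <- function(n_per_line = c(D1R = 20L, D2R = 19L),
                          sessions_per_treatment = 10L,
                          model = model_spec(1),
                          baseline_sampler = NULL,
                          effect_map = list(D1R = c(beta = 0.6),
                                            D2R = c(alpha = 0.5)),
                          task = tab_task_config(),
                          durations = duration_model()) {
  stopifnot(all(names(n_per_line) %in% LINE_LEVELS), all(n_per_line >= 1),
            sessions_per_treatment >= 1)
  if (is.null(baseline_sampler)) {
    baseline_sampler <- function() {
      param_set(alpha = runif(1, 0.15, 0.35), beta = runif(1, 1.5, 3))
    }
  }
  for (line in names(effect_map)) {
    fac <- effect_map[[line]]
    bad <- setdiff(names(fac), c(PARAM_NAMES, "alpha"))
    if (length(bad)) {
      stop("effect map names unknown parameter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(fac <= 0)) stop("effect factors must be > 0", call. = FALSE)
  }
  structure(list(n_per_line = n_per_line,
                 sessions_per_treatment = as.integer(sessions_per_treatment),
                 model = model, baseline_sampler = baseline_sampler,
                 effect_map = effect_map, task = task, durations = durations),
            class = "cohort_config")
}

# Apply a named multiplicative effect vector to a param_set.
apply_effect <- function(params, factors) {
  p <- unclass(params)
  for (nm in names(factors)) {
    if (nm == "alpha") {
      p$alpha_pos <- p$alpha_pos * factors[[nm]]
      p$alpha_neg <- p$alpha_neg * factors[[nm]]
    } else {
      p[[nm]] <- p[[nm]] * factors[[nm]]
    }
  }
  do.call(param_set, p)
}

#' Simulate one TAB session
#'
#' Draws the block structure from \code{task}, then runs a Q-learning agent
#' through it: on every trial the choice is sampled from the softmax
#' probability, the reward is Bernoulli with the chosen side's current block
#' probability, and the agent's values are updated. Action values start at
#' \code{q_init} for both sides and are \emph{not} reset at (uncued) block
#' transitions.
#'
#' @param params A [param_set()] for the agent.
#' @param model A [model_spec()]; \code{params} must satisfy its constraints.
#' @param task A [tab_task_config()].
#' @param seed Integer seed; identical inputs give identical sessions.
#' @param mouse_id,line,treatment,day Session metadata.
#' @param durations Optional [duration_model()] for trial durations.
#' @param q_init Initial action value (default 0).
#' @return A [session()].
#' @export
simulate_tab_session <- function(params, model, task = tab_task_config(),
                                 seed, mouse_id = "sim", line = "D1R",
                                 treatment = "DMSO", day = 1L,
                                 durations = duration_model(),
                                 q_init = 0) {
  validate_params_for_model(params, model)
  with_seed(seed, {
    lens <- task$block_lengths[sample.int(length(task$block_lengths),
                                          task$n_blocks, replace = TRUE)]
    first <- task$first_block_side
    if (first == "random") first <- sample(SIDE_LEVELS, 1)
    high <- character(task$n_blocks)
    high[1] <- first
    if (task$n_blocks > 1) {
      for (b in 2:task$n_blocks) high[b] <- setdiff(SIDE_LEVELS, high[b - 1])
    }
    block_probs <- data.frame(
      block = seq_len(task$n_blocks),
      p_left = ifelse(high == "L", task$p_high, task$p_low),
      p_right = ifelse(high == "R", task$p_high, task$p_low))
    n <- sum(lens)
    block_index <- rep(seq_len(task$n_blocks), times = lens)
    choice <- character(n)
    reward <- integer(n)
    pv <- param_vector(params)
    ap <- pv[1]; an <- pv[2]; beta <- pv[3]; b <- pv[4]
    gw <- pv[5]; gl <- pv[6]; eps <- pv[7]; rho <- pv[8]
    qL <- q_init; qR <- q_init; uL <- 0; uR <- 0
    for (t in seq_len(n)) {
      pL <- plogis(beta * (qL - qR) + rho * (uL - uR) - b)
      ch <- if (runif(1) < pL) "L" else "R"
      p_rew <- if (ch == "L") block_probs$p_left[block_index[t]] else
        block_probs$p_right[block_index[t]]
      rw <- as.integer(runif(1) < p_rew)
      choice[t] <- ch
      reward[t] <- rw
      if (ch == "L") {
        qL <- if (rw == 1) (1 - ap) * qL + ap - gw else (1 - an) * qL - gl
        uL <- 0; uR <- uR + eps
      } else {
        qR <- if (rw == 1) (1 - ap) * qR + ap - gw else (1 - an) * qR - gl
        uR <- 0; uL <- uL + eps
      }
    }
    trials <- data.frame(trial_index = seq_len(n), block_index = block_index,
                         choice = choice, reward = reward,
                         duration = draw_durations(n, durations, treatment),
                         high_side = high[block_index])
    session(mouse_id = mouse_id, line = line, treatment = treatment,
            task = "TAB", stage = NA, day = day, trials = trials,
            block_probs = block_probs)
  })
}

#' Simulate one reversal-task session
#'
#' The currently rewarded side pays with probability 1 and the other side
#' never pays. \code{high_side} tracks the rewarded side, including
#' within-session flips: a reversal configured "at trial 31" means trials
#' 1-30 reward one side and trial 31 onward the other.
#'
#' @inheritParams simulate_tab_session
#' @param stage Training stage 1-5.
#' @param config A [reversal_task_config()].
#' @param rewarded_side_at_start "L" or "R".
#' @return A [session()] of 60 trials (stages 1-4) or 90 trials (stage 5),
#'   with \code{block_index} constant 1.
#' @export
simulate_reversal_session <- function(params, model, stage,
                                      config = reversal_task_config(),
                                      rewarded_side_at_start = "L", seed,
                                      mouse_id = "sim", line = "D1R",
                                      treatment = "DMSO", day = 1L,
                                      durations = duration_model(),
                                      q_init = 0) {
  if (!is.numeric(stage) || length(stage) != 1L || !(stage %in% 1:5)) {
    stop("stage must be an integer between 1 and 5")
  }
  stopifnot(rewarded_side_at_start %in% SIDE_LEVELS)
  validate_params_for_model(params, model)
  stage <- as.integer(stage)
  n <- config$trials_per_session[stage]
  flips <- config$within_session_reversal_trials[[stage]]
  with_seed(seed, {
    high_side <- character(n)
    cur <- rewarded_side_at_start
    for (t in seq_len(n)) {
      if (t %in% flips) cur <- setdiff(SIDE_LEVELS, cur)
      high_side[t] <- cur
    }
    choice <- character(n)
    reward <- integer(n)
    pv <- param_vector(params)
    ap <- pv[1]; an <- pv[2]; beta <- pv[3]; b <- pv[4]
    gw <- pv[5]; gl <- pv[6]; eps <- pv[7]; rho <- pv[8]
    qL <- q_init; qR <- q_init; uL <- 0; uR <- 0
    for (t in seq_len(n)) {
      pL <- plogis(beta * (qL - qR) + rho * (uL - uR) - b)
      ch <- if (runif(1) < pL) "L" else "R"
      rw <- as.integer(ch == high_side[t])
      choice[t] <- ch
      reward[t] <- rw
      if (ch == "L") {
        qL <- if (rw == 1) (1 - ap) * qL + ap - gw else (1 - an) * qL - gl
        uL <- 0; uR <- uR + eps
      } else {
        qR <- if (rw == 1) (1 - ap) * qR + ap - gw else (1 - an) * qR - gl
        uR <- 0; uL <- uL + eps
      }
    }
    trials <- data.frame(trial_index = seq_len(n),
                         block_index = rep(1L, n),
                         choice = choice, reward = reward,
                         duration = draw_durations(n, durations, treatment),
                         high_side = high_side)
    session(mouse_id = mouse_id, line = line, treatment = treatment,
            task = "reversal", stage = stage, day = day, trials = trials,
            block_probs = NULL)
  })
}

#' Generate a full synthetic TAB cohort with ground truth
#'
#' For each animal a baseline parameter set is drawn; the animal's CNO
#' parameters are the baseline with the line's effect map applied. CNO and
#' DMSO sessions alternate across days (the first-day drug alternates across
#' animals within line), each simulated with [simulate_tab_session()] and
#' per-session duration draws.
#'
#' @param config A [cohort_config()].
#' @param seed Master integer seed.
#' @return A list with \code{sessions} (a [session_set()]) and \code{truth}
#'   (a data.frame with one row per animal x treatment: \code{mouse_id, line,
#'   treatment, alpha_pos, alpha_neg, beta, bias, gamma_win, gamma_lose,
#'   epsilon, rho}).
#' @export
generate_cohort <- function(config = cohort_config(), seed) {
  stopifnot(inherits(config, "cohort_config"))
  lines <- names(config$n_per_line)
  n_animals <- sum(config$n_per_line)
  n_sessions_each <- 2L * config$sessions_per_treatment
  seeds <- derive_seeds(seed, n_animals * (1L + n_sessions_each))
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seeds[seed_i]
  }
  sessions <- vector("list", n_animals * n_sessions_each)
  truth <- vector("list", 2L * n_animals)
  si <- 0L
  ti <- 0L
  animal_counter <- 0L
  for (line in lines) {
    for (a in seq_len(config$n_per_line[[line]])) {
      animal_counter <- animal_counter + 1L
      mouse_id <- sprintf("%s_%02d", line, a)
      base <- with_seed(next_seed(), config$baseline_sampler())
      fac <- config$effect_map[[line]]
      cno <- if (is.null(fac)) base else apply_effect(base, fac)
      pars <- list(DMSO = base, CNO = cno)
      # alternate drug across days; first-day drug counterbalanced across
      # animals (odd animals start on DMSO, even on CNO)
      first_drug <- if (animal_counter %% 2L == 1L) "DMSO" else "CNO"
      drugs <- rep(c(first_drug, setdiff(c("DMSO", "CNO"), first_drug)),
                   length.out = n_sessions_each)
      for (d in seq_len(n_sessions_each)) {
        si <- si + 1L
        sessions[[si]] <- simulate_tab_session(
          pars[[drugs[d]]], config$model, config$task, seed = next_seed(),
          mouse_id = mouse_id, line = line, treatment = drugs[d],
          day = d, durations = config$durations)
      }
      for (trt in c("DMSO", "CNO")) {
        ti <- ti + 1L
        truth[[ti]] <- data.frame(mouse_id = mouse_id, line = line,
                                  treatment = trt,
                                  as.list(param_vector(pars[[trt]])))
      }
    }
  }
  list(sessions = session_set(sessions,
                              provenance = sprintf("generate_cohort(seed=%d)",
                                                   as.integer(seed))),
       truth = do.call(rbind, truth))
}
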