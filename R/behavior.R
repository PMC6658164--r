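#' Exclude trial-duration outlier sessions
#'
#' Single-pass exclusion of slow sessions: within each population (sessions
#' sharing the \code{population_key} fields), a session is dropped when its
#' mean trial duration exceeds the population mean plus \code{k} sample
#' standard deviations, both computed \emph{including} the candidate
#' sessions. Populations are never pooled: a session is judged only against
#' its own population.
#'
#' @param sessions A list of sessions or [session_set()].
#' @param population_key Character vector of session fields defining the
#'   populations (default \code{c("line", "treatment", "task", "stage")}).
#' @param k SD multiplier (default 3).
#' @return A list with \code{kept} and \code{dropped} (lists of sessions)
#'   and \code{log} (one row per population: n, mean, sd, threshold,
#'   n_dropped). Populations with fewer than 2 sessions produce a warning
#'   and exclude nothing.
#' @export
exclude_duration_outliers <- function(sessions,
                                      population_key = c("line", "treatment",
                                                         "task", "stage"),
                                      k = 3) {
  sessions <- as_session_list(sessions)
  keys <- vapply(sessions, function(s) {
    paste(vapply(population_key, function(f) as.character(s[[f]]),
                 character(1)), collapse = "|")
  }, character(1))
  kept <- list()
  dropped <- list()
  log_rows <- list()
  for (key in unique(keys)) {
    idx <- which(keys == key)
    pop <- sessions[idx]
    durs <- session_mean_durations(pop)
    if (length(pop) < 2L) {
      warning("population '", key, "' has fewer than 2 sessions; no exclusion")
      kept <- c(kept, pop)
      log_rows[[length(log_rows) + 1L]] <-
        data.frame(population = key, n = length(pop), mean = mean(durs),
                   sd = NA_real_, threshold = NA_real_, n_dropped = 0L)
      next
    }
    m <- mean(durs)
    s <- sd(durs)
    thr <- m + k * s
    out <- durs > thr
    kept <- c(kept, pop[!out])
    dropped <- c(dropped, pop[out])
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(population = key, n = length(pop), mean = m, sd = s,
                 threshold = thr, n_dropped = sum(out))
  }
  list(kept = kept, dropped = dropped, log = do.call(rbind, log_rows))
}

#' Match mean trial durations between CNO and DMSO sessions
#'
#' Greedy trimming: while the absolute difference of the two groups' mean
#' session durations exceeds \code{tolerance}, remove either the longest
#' remaining CNO session or the shortest remaining DMSO session — whichever
#' single removal shrinks the gap more — until the gap is within tolerance or
#' the removal budget (\code{max_fraction_removed} of the initial combined
#' session count) is spent. Every removal is logged; replaying the log on the
#' inputs reproduces the matched sets.
#'
#' @param cno,dmso Lists of sessions (non-empty).
#' @param tolerance Acceptable |mean(CNO) - mean(DMSO)| in seconds
#'   (default 0.5).
#' @param max_fraction_removed Removal budget as a fraction of the combined
#'   initial session count (default 0.2).
#' @return A list with \code{matched_cno}, \code{matched_dmso}, \code{log}
#'   (one row per removal: step, group, mouse_id, day, mean_duration,
#'   gap_before, gap_after) and \code{gap} (final mean difference). A warning
#'   is raised if the budget runs out before the tolerance is met.
#' @export
match_durations <- function(cno, dmso, tolerance = 0.5,
                            max_fraction_removed = 0.2) {
  cno <- as_session_list(cno)
  dmso <- as_session_list(dmso)
  if (length(cno) == 0L || length(dmso) == 0L) {
    stop("both session lists must be non-empty")
  }
  budget <- floor(max_fraction_removed * (length(cno) + length(dmso)))
  log_rows <- list()
  gap <- function(a, b) {
    abs(mean(session_mean_durations(a)) - mean(session_mean_durations(b)))
  }
  step <- 0L
  while (gap(cno, dmso) > tolerance && step < budget &&
         length(cno) > 1L && length(dmso) > 1L) {
    g0 <- gap(cno, dmso)
    i_cno <- which.max(session_mean_durations(cno))
    i_dmso <- which.min(session_mean_durations(dmso))
    g_cno <- gap(cno[-i_cno], dmso)
    g_dmso <- gap(cno, dmso[-i_dmso])
    step <- step + 1L
    if (g_cno <= g_dmso) {
      s <- cno[[i_cno]]
      cno <- cno[-i_cno]
      grp <- "CNO"
      g1 <- g_cno
    } else {
      s <- dmso[[i_dmso]]
      dmso <- dmso[-i_dmso]
      grp <- "DMSO"
      g1 <- g_dmso
    }
    log_rows[[step]] <- data.frame(step = step, group = grp,
                                   mouse_id = s$mouse_id, day = s$day,
                                   mean_duration = s$mean_duration,
                                   gap_before = g0, gap_after = g1)
  }
  final_gap <- gap(cno, dmso)
  if (final_gap > tolerance) {
    warning(sprintf("duration matching stopped with gap %.3f s > tolerance %.3f s",
                    final_gap, tolerance))
  }
  list(matched_cno = cno, matched_dmso = dmso,
       log = if (length(log_rows)) do.call(rbind, log_rows) else
         data.frame(step = integer(0), group = character(0),
                    mouse_id = character(0), day = integer(0),
                    mean_duration = numeric(0), gap_before = numeric(0),
                    gap_after = numeric(0)),
       gap = final_gap)
}

# Moving average of a 0/1 series; centered (+/- (window-1)/2) or trailing
# window, truncated at the block edges. Never crosses block boundaries.
smooth_series <- function(h, window, align = c("centered", "trailing")) {
  align <- match.arg(align)
  n <- length(h)
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(t) {
    if (align == "centered") {
      mean(h[max(1L, t - half):min(n, t + half)])
    } else {
      mean(h[max(1L, t - window + 1L):t])
    }
  }, numeric(1))
}

#' Segment a TAB session's blocks into dynamic and steady states
#'
#' Per block, the indicator of choosing the currently higher-probability side
#' is smoothed with a moving average of \code{window} trials (centered,
#' truncated at the block boundaries; smoothing never crosses blocks). With
#' \eqn{M} the block maximum of the smoothed series, the dynamic state runs
#' from the block start up to (not including) the first trial whose smoothed
#' value strictly exceeds \eqn{0.70 M}, and the steady state runs from the
#' first trial strictly exceeding \eqn{0.90 M} to the block end. Trials
#' between the two ranges belong to neither state.
#'
#' @param session A TAB [session()].
#' @param window Moving-average width in trials (default 7).
#' @param thresholds Fractions of the block maximum ending the dynamic state
#'   and starting the steady state (default \code{c(0.70, 0.90)}).
#' @param align Moving-average alignment, \code{"centered"} (default) or
#'   \code{"trailing"}.
#' @return A \code{state_segmentation}: per block, the smoothed P(H) series,
#'   the block maximum, and the dynamic/steady trial ranges both
#'   block-relative (\code{dynamic}, \code{steady}) and as absolute session
#'   trial indices (\code{dynamic_abs}, \code{steady_abs}).
#' @export
segment_block_states <- function(session, window = 7L,
                                 thresholds = c(0.70, 0.90),
                                 align = c("centered", "trailing")) {
  stopifnot(inherits(session, "bandit_session"))
  if (session$task != "TAB") stop("segmentation is defined for TAB sessions")
  align <- match.arg(align)
  tr <- session$trials
  blocks <- unique(tr$block_index)
  out <- lapply(blocks, function(b) {
    rows <- which(tr$block_index == b)
    n <- length(rows)
    if (n < 2L) {
      warning("block ", b, " has fewer than 2 trials; empty segmentation")
      return(list(block = b, smoothed = numeric(0), max = NA_real_,
                  dynamic = integer(0), steady = integer(0),
                  dynamic_abs = integer(0), steady_abs = integer(0),
                  n_trials = n, first_trial = rows[1]))
    }
    h <- as.numeric(tr$choice[rows] == tr$high_side[rows])
    s <- smooth_series(h, window, align)
    m <- max(s)
    first_dyn_end <- which(s > thresholds[1] * m)[1]   # NA when M = 0
    first_steady <- which(s > thresholds[2] * m)[1]
    dynamic <- if (is.na(first_dyn_end)) seq_len(n) else
      seq_len(first_dyn_end - 1L)
    steady <- if (is.na(first_steady)) integer(0) else seq.int(first_steady, n)
    list(block = b, smoothed = s, max = m,
         dynamic = as.integer(dynamic), steady = as.integer(steady),
         dynamic_abs = rows[dynamic], steady_abs = rows[steady],
         n_trials = n, first_trial = rows[1])
  })
  structure(list(blocks = out, window = as.integer(window),
                 thresholds = thresholds, align = align,
                 n_trials = nrow(tr)),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  cat("<state segmentation:", length(x$blocks), "block(s), window",
      x$window, paste0("(", x$align, ")"), "thresholds",
      paste(x$thresholds, collapse = "/"), ">\n")
  for (b in x$blocks) {
    cat(sprintf("  block %d (%d trials): dynamic %d, steady %d\n",
                b$block, b$n_trials, length(b$dynamic), length(b$steady)))
  }
  invisible(x)
}

# Absolute trial indices in scope for a session of `n` trials.
scope_indices <- function(scope, segmentation, n) {
  if (scope == "all") return(seq_len(n))
  if (is.null(segmentation)) {
    stop("scope '", scope, "' requires a segmentation")
  }
  field <- if (scope == "dynamic") "dynamic_abs" else "steady_abs"
  sort(unlist(lapply(segmentation$blocks, `[[`, field)))
}

#' Choice metrics: P(R), P(H), P(WS), P(LS)
#'
#' Computes, over the in-scope trials of one session, the proportion of
#' rewarded trials (P(R)), higher-reward-probability-side choices (P(H)),
#' win-stay (P(WS): repeats of the previous choice among trials whose
#' predecessor was rewarded) and lose-switch (P(LS): switches among trials
#' whose predecessor was unrewarded). The predecessor is always the actual
#' preceding trial of the session — even when that trial falls outside the
#' scope window — and predecessor relations never cross session boundaries
#' (the session's first trial has none). A zero denominator yields
#' \code{NA} (undefined, distinct from 0).
#'
#' @param trials A session's trial data.frame, or a [session()].
#' @param scope \code{"all"}, \code{"dynamic"} or \code{"steady"}.
#' @param segmentation A [segment_block_states()] result; required unless
#'   \code{scope = "all"}.
#' @return A \code{choice_metrics} object: \code{p_reward}, \code{p_high},
#'   \code{p_winstay}, \code{p_loseswitch}, each with its numerator and
#'   denominator.
#' @export
compute_choice_metrics <- function(trials, scope = c("all", "dynamic", "steady"),
                                   segmentation = NULL) {
  scope <- match.arg(scope)
  if (inherits(trials, "bandit_session")) trials <- trials$trials
  n <- nrow(trials)
  idx <- scope_indices(scope, segmentation, n)
  prop <- function(num, den) {
    list(value = if (den > 0) num / den else NA_real_, num = num, den = den)
  }
  pr <- prop(sum(trials$reward[idx] == 1L), length(idx))
  ph <- prop(sum(trials$choice[idx] == trials$high_side[idx]), length(idx))
  with_pred <- idx[idx >= 2L]
  prev_rewarded <- trials$reward[with_pred - 1L] == 1L
  stay <- trials$choice[with_pred] == trials$choice[with_pred - 1L]
  ws <- prop(sum(stay[prev_rewarded]), sum(prev_rewarded))
  ls <- prop(sum(!stay[!prev_rewarded]), sum(!prev_rewarded))
  structure(list(p_reward = pr$value, p_high = ph$value,
                 p_winstay = ws$value, p_loseswitch = ls$value,
                 counts = data.frame(
                   metric = c("p_reward", "p_high", "p_winstay", "p_loseswitch"),
                   numerator = c(pr$num, ph$num, ws$num, ls$num),
                   denominator = c(pr$den, ph$den, ws$den, ls$den)),
                 scope = scope, n_trials = n),
            class = "choice_metrics")
}

#' @export
print.choice_metrics <- function(x, ...) {
  cat(sprintf("<choice metrics (%s, %d trials)> P(R)=%.3f P(H)=%.3f P(WS)=%.3f P(LS)=%.3f\n",
              x$scope, x$n_trials, x$p_reward, x$p_high, x$p_winstay,
              x$p_loseswitch))
  invisible(x)
}

#' Choice profile approaching block transitions
#'
#' Pools, across all blocks that are followed by a transition (i.e. all but
#' each session's last block), the probability of choosing the
#' lower-reward-probability side at each trial position relative to the
#' upcoming transition. A flat profile is the signature of an animal (or
#' agent) that cannot anticipate the uncued reversals.
#'
#' @param sessions TAB sessions with at least 2 blocks (list or
#'   [session_set()]).
#' @param window Number of pre-transition positions (default 10). If longer
#'   than the shortest contributing block, positions are truncated per block
#'   with a warning.
#' @return A data.frame with one row per position \code{-window..-1}:
#'   \code{position}, \code{n_low} (lower-probability-side choices),
#'   \code{n} (trials contributing), \code{p_low}.
#' @export
pre_transition_choice_profile <- function(sessions, window = 10L) {
  sessions <- as_session_list(sessions)
  n_low <- integer(window)
  n_tot <- integer(window)
  truncated <- FALSE
  for (s in sessions) {
    tr <- s$trials
    blocks <- unique(tr$block_index)
    if (length(blocks) < 2L) stop("sessions need at least 2 blocks")
    for (b in blocks[-length(blocks)]) {
      rows <- which(tr$block_index == b)
      len <- length(rows)
      w <- min(window, len)
      if (w < window) truncated <- TRUE
      for (d in seq_len(w)) {       # d trials before the transition
        t <- rows[len - d + 1L]
        n_tot[d] <- n_tot[d] + 1L
        if (tr$choice[t] != tr$high_side[t]) n_low[d] <- n_low[d] + 1L
      }
    }
  }
  if (truncated) {
    warning("window longer than the shortest block; positions truncated")
  }
  data.frame(position = -seq_len(window), n_low = n_low, n = n_tot,
             p_low = ifelse(n_tot > 0, n_low / n_tot, NA_real_))
}

#' Fitted action-value profiles around block transitions
#'
#' Replays each session with its animal-condition's fitted parameters
#' ([value_trajectory()]) and aggregates the values of the higher- and
#' lower-probability sides (\eqn{Q_{high}}, \eqn{Q_{low}}): aligned to the
#' first \code{n_post} trials after a block transition and the last
#' \code{n_pre} trials of a block (windows truncated at block edges), and
#' averaged over dynamic-state and steady-state trials. Only
#' \code{blocks} (default 2-4) contribute; the first block follows no
#' transition and is excluded throughout.
#'
#' @param sessions TAB sessions (list or [session_set()]).
#' @param fits Named list of \code{fit_result}s keyed
#'   \code{"mouse_id.treatment"} (as returned in \code{fit_cohort()$fits}).
#'   A session without a matching fit is an error.
#' @param blocks Blocks to use (default \code{2:4}).
#' @param n_post,n_pre Post-transition / pre-end alignment window lengths
#'   (defaults 15 and 10).
#' @param window,thresholds,align Segmentation settings passed to
#'   [segment_block_states()].
#' @param q_init Initial action value used in the replay.
#' @return A \code{q_profile} list: \code{aligned_post} and
#'   \code{aligned_pre} (per animal x treatment x position mean q_high/q_low;
#'   positions are 1..n_post after transition and -n_pre..-1 before block
#'   end) and \code{state_means} (per animal x treatment x state mean
#'   q_high/q_low).
#' @export
qvalue_block_profile <- function(sessions, fits, blocks = 2:4,
                                 n_post = 15L, n_pre = 10L, window = 7L,
                                 thresholds = c(0.70, 0.90),
                                 align = "centered", q_init = 0) {
  sessions <- as_session_list(sessions)
  acc <- list()
  add <- function(key, pos_type, position, q_high, q_low) {
    acc[[length(acc) + 1L]] <<-
      data.frame(key = key, type = pos_type, position = position,
                 q_high = q_high, q_low = q_low)
  }
  meta <- list()
  for (s in sessions) {
    key <- paste(s$mouse_id, s$treatment, sep = ".")
    f <- fits[[key]]
    if (is.null(f)) stop("no fit for animal/condition ", key)
    meta[[key]] <- data.frame(mouse_id = s$mouse_id, line = s$line,
                              treatment = s$treatment)
    traj <- value_trajectory(s, f$params, model_spec(f$model_id),
                             q_init = q_init)
    seg <- segment_block_states(s, window = window, thresholds = thresholds,
                                align = align)
    tr <- s$trials
    for (b in intersect(blocks, unique(tr$block_index))) {
      rows <- which(tr$block_index == b)
      len <- length(rows)
      post <- seq_len(min(n_post, len))
      add(key, "post", post, traj$q_high[rows[post]], traj$q_low[rows[post]])
      pre <- seq.int(len - min(n_pre, len) + 1L, len)
      add(key, "pre", pre - len - 1L,
          traj$q_high[rows[pre]], traj$q_low[rows[pre]])
      bl <- seg$blocks[[match(b, vapply(seg$blocks, `[[`, integer(1), "block"))]]
      if (length(bl$dynamic_abs)) {
        add(key, "dynamic", 0L, traj$q_high[bl$dynamic_abs],
            traj$q_low[bl$dynamic_abs])
      }
      if (length(bl$steady_abs)) {
        add(key, "steady", 0L, traj$q_high[bl$steady_abs],
            traj$q_low[bl$steady_abs])
      }
    }
  }
  all <- do.call(rbind, acc)
  meta <- do.call(rbind, meta)
  meta$key <- rownames(meta)
  agg <- function(df, by_position) {
    keys <- if (by_position) list(key = df$key, position = df$position) else
      list(key = df$key)
    out <- aggregate(df[, c("q_high", "q_low")], by = keys, FUN = mean)
    merge(meta, out, by = "key")
  }
  post <- agg(all[all$type == "post", ], TRUE)
  pre <- agg(all[all$type == "pre", ], TRUE)
  state_means <- do.call(rbind, lapply(c("dynamic", "steady"), function(st) {
    d <- all[all$type == st, ]
    if (nrow(d) == 0L) return(NULL)
    out <- agg(d, FALSE)
    out$state <- st
    out
  }))
  structure(list(aligned_post = post[order(post$key, post$position), ],
                 aligned_pre = pre[order(pre$key, pre$position), ],
                 state_means = state_means, blocks = blocks,
                 n_post = n_post, n_pre = n_pre),
            class = "q_profile")
}

#' @export
print.q_profile <- function(x, ...) {
  cat("<Q-value block profile: blocks", paste(x$blocks, collapse = ","),
      "-", length(unique(x$state_means$key)), "animal-condition group(s)>\n")
  invisible(x)
}
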