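#' Q-learning model parameter set
#'
#' Bundles the eight parameters of the full Q-learning model family. Action
#' values of the chosen side are updated toward the outcome with learning rate
#' \code{alpha_pos} (rewarded trials) or \code{alpha_neg} (unrewarded trials),
#' minus a perseveration penalty \code{gamma_win} / \code{gamma_lose}; the
#' unchosen side is left untouched. Choice follows a softmax of the value
#' difference with inverse temperature \code{beta} and a side-bias term
#' \code{bias} (written \eqn{b}); the uncertainty-exploration variant adds
#' \code{epsilon} (accumulation rate) and \code{rho} (exploration gain).
#'
#' The softmax is \eqn{P_L = 1/(1 + \exp(-\beta(Q_L - Q_R) + b))}: note that a
#' \emph{positive} \code{bias} lowers the probability of choosing left. Use
#' [left_bias()] to read the left-favoring bias \eqn{-b}.
#'
#' @param alpha Convenience: sets both \code{alpha_pos} and \code{alpha_neg}.
#' @param alpha_pos,alpha_neg Learning rates in \[0, 1\] for rewarded and
#'   unrewarded outcomes.
#' @param beta Inverse temperature, >= 0. Smaller values give more random,
#'   less value-dependent choices.
#' @param bias Side-bias term \eqn{b} inside the softmax exponent.
#' @param gamma_win,gamma_lose Penalty applied to the chosen action's value
#'   after rewarded / unrewarded trials (positive values discourage repeating
#'   the same choice).
#' @param epsilon Per-trial uncertainty increment for the unchosen action
#'   (>= 0); the accumulator resets to zero when the action is chosen.
#' @param rho Gain on the uncertainty difference added to the softmax
#'   argument.
#' @return A \code{param_set} object (named list).
#' @examples
#' param_set(alpha = 0.5, beta = 3)
#' @export
param_set <- function(alpha = NULL, alpha_pos = 0.5, alpha_neg = 0.5,
                      beta = 3, bias = 0, gamma_win = 0, gamma_lose = 0,
                      epsilon = 0, rho = 0) {
  if (!is.null(alpha)) {
    alpha_pos <- alpha
    alpha_neg <- alpha
  }
  p <- list(alpha_pos = alpha_pos, alpha_neg = alpha_neg, beta = beta,
            bias = bias, gamma_win = gamma_win, gamma_lose = gamma_lose,
            epsilon = epsilon, rho = rho)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stop("parameter '", nm, "' must be a single finite number")
    }
  }
  if (p$alpha_pos < 0 || p$alpha_pos > 1 || p$alpha_neg < 0 || p$alpha_neg > 1) {
    stop("learning rates must lie in [0, 1]")
  }
  if (p$beta < 0) stop("beta must be >= 0")
  if (p$epsilon < 0) stop("epsilon must be >= 0")
  structure(p, class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat("Q-learning parameter set\n")
  print(unlist(x))
  invisible(x)
}

#' Left-favoring bias implied by a parameter set
#'
#' The softmax convention places \code{+bias} inside the exponent of
#' \eqn{P_L}, so a positive \code{bias} disfavors the left target. This
#' accessor returns \code{-bias}, the bias \emph{toward} the left target.
#'
#' @param params A [param_set()].
#' @return A number; positive values favor the left target.
#' @export
left_bias <- function(params) {
  -params$bias
}

# Canonical parameter order shared with the C++ kernel and the ground-truth
# CSV schema.
PARAM_NAMES <- c("alpha_pos", "alpha_neg", "beta", "bias",
                 "gamma_win", "gamma_lose", "epsilon", "rho")

param_vector <- function(params) {
  vapply(PARAM_NAMES, function(nm) params[[nm]], numeric(1))
}

#' Model variants of the Q-learning family
#'
#' Returns the specification of one of the six model variants:
#' \describe{
#'   \item{1}{\code{alpha}, \code{beta} (learning rates tied, no bias).}
#'   \item{2}{adds the side bias \code{bias}.}
#'   \item{3}{splits \code{alpha_pos} / \code{alpha_neg}, keeps the bias.}
#'   \item{4}{tied learning rates plus bias and the win-stay / lose-switch
#'     penalties \code{gamma_win}, \code{gamma_lose}.}
#'   \item{5}{all six of the above free.}
#'   \item{6}{model 5 plus uncertainty-based exploration (\code{epsilon},
#'     \code{rho}).}
#' }
#' Constrained parameters are fixed at zero; in models 1, 2 and 4 the two
#' learning rates are constrained equal.
#'
#' @param model_id Integer 1-6.
#' @return A \code{model_spec} object with elements \code{model_id},
#'   \code{free} (fitted parameter names), \code{tie_alpha}, and \code{k}
#'   (number of free parameters).
#' @export
model_spec <- function(model_id) {
  if (!is.numeric(model_id) || length(model_id) != 1L ||
      !(model_id %in% 1:6)) {
    stop("model_id must be an integer between 1 and 6")
  }
  model_id <- as.integer(model_id)
  free <- switch(model_id,
    c("alpha_pos", "beta"),
    c("alpha_pos", "beta", "bias"),
    c("alpha_pos", "alpha_neg", "beta", "bias"),
    c("alpha_pos", "beta", "bias", "gamma_win", "gamma_lose"),
    c("alpha_pos", "alpha_neg", "beta", "bias", "gamma_win", "gamma_lose"),
    c("alpha_pos", "alpha_neg", "beta", "bias", "gamma_win", "gamma_lose",
      "epsilon", "rho"))
  tie_alpha <- model_id %in% c(1L, 2L, 4L)
  structure(list(model_id = model_id, free = free, tie_alpha = tie_alpha,
                 k = length(free)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Q-learning model", x$model_id, "- free parameters:",
      paste(x$free, collapse = ", "),
      if (x$tie_alpha) "(alpha_pos = alpha_neg)" else "", "\n")
  invisible(x)
}

# Check that `params` satisfies the equality/zero constraints of `model`.
validate_params_for_model <- function(params, model, tol = 1e-12) {
  stopifnot(inherits(params, "param_set"), inherits(model, "model_spec"))
  if (model$tie_alpha && abs(params$alpha_pos - params$alpha_neg) > tol) {
    stop("model ", model$model_id, " constrains alpha_pos = alpha_neg")
  }
  fixed <- setdiff(PARAM_NAMES, c(model$free,
                                  if (model$tie_alpha) "alpha_neg"))
  for (nm in fixed) {
    if (abs(params[[nm]]) > tol) {
      stop("model ", model$model_id, " constrains ", nm, " = 0")
    }
  }
  invisible(TRUE)
}

# Expand a free-parameter vector (ordered as model$free) into a full
# param_set, applying the model's constraints.
expand_params <- function(theta, model) {
  p <- setNames(as.list(rep(0, length(PARAM_NAMES))), PARAM_NAMES)
  p[model$free] <- theta
  if (model$tie_alpha) p$alpha_neg <- p$alpha_pos
  do.call(param_set, p)
}

#' Action-value state
#'
#' The per-trial learner state: the two action values \eqn{Q_L}, \eqn{Q_R}
#' and, for the uncertainty-exploration variant, the per-action uncertainty
#' accumulators \eqn{U_L}, \eqn{U_R}.
#'
#' @param q_left,q_right Action values.
#' @param u_left,u_right Uncertainty accumulators (default 0).
#' @return An \code{action_values} object.
#' @export
action_values <- function(q_left = 0, q_right = 0, u_left = 0, u_right = 0) {
  stopifnot(is.finite(q_left), is.finite(q_right),
            is.finite(u_left), is.finite(u_right))
  structure(list(q_left = q_left, q_right = q_right,
                 u_left = u_left, u_right = u_right),
            class = "action_values")
}

#' One-trial action-value update
#'
#' Applies the chosen-action update
#' \eqn{Q_a \leftarrow (1-\alpha_{pos}) Q_a + \alpha_{pos} R - \gamma_{win}}
#' on rewarded trials and
#' \eqn{Q_a \leftarrow (1-\alpha_{neg}) Q_a + \alpha_{neg} R - \gamma_{lose}}
#' on unrewarded trials; the unchosen action's value is unchanged. The
#' uncertainty accumulator of the chosen action resets to zero and the
#' unchosen one grows by \code{epsilon}.
#'
#' @param q An [action_values()] state.
#' @param choice "L" or "R".
#' @param reward 0 or 1.
#' @param params A [param_set()] valid for \code{model}.
#' @param model A [model_spec()].
#' @return The updated [action_values()].
#' @export
update_values <- function(q, choice, reward, params, model) {
  stopifnot(inherits(q, "action_values"))
  validate_params_for_model(params, model)
  if (!choice %in% c("L", "R")) stop("choice must be 'L' or 'R'")
  if (!reward %in% c(0, 1)) stop("reward must be 0 or 1")
  upd <- function(qa) {
    if (reward == 1) {
      (1 - params$alpha_pos) * qa + params$alpha_pos - params$gamma_win
    } else {
      (1 - params$alpha_neg) * qa - params$gamma_lose
    }
  }
  if (choice == "L") {
    q$q_left <- upd(q$q_left)
    q$u_left <- 0
    q$u_right <- q$u_right + params$epsilon
  } else {
    q$q_right <- upd(q$q_right)
    q$u_right <- 0
    q$u_left <- q$u_left + params$epsilon
  }
  q
}

#' Softmax probability of choosing the left target
#'
#' \eqn{P_L = 1/(1 + \exp(-\beta(Q_L - Q_R) + b))}, with the uncertainty term
#' \eqn{\rho (U_L - U_R)} added to the exponent argument for the exploration
#' variant. Computed through \code{plogis}, so extreme arguments saturate to
#' 0/1 without overflow.
#'
#' @inheritParams update_values
#' @return The probability of a left choice; \eqn{P_R = 1 - P_L}.
#' @examples
#' choice_prob_left(action_values(1, 0), param_set(alpha = 0.5, beta = log(3)),
#'                  model_spec(1)) # 0.75
#' @export
choice_prob_left <- function(q, params, model) {
  stopifnot(inherits(q, "action_values"))
  validate_params_for_model(params, model)
  plogis(params$beta * (q$q_left - q$q_right) +
           params$rho * (q$u_left - q$u_right) - params$bias)
}

#' Log-likelihood of observed choices under a Q-learning model
#'
#' Replays each session's observed choices and rewards through the model's
#' value update, re-initializing the learner state at every session start,
#' and sums the log probability of each observed choice. Predicted
#' probabilities are clamped at \code{prob_floor} before the log so the
#' result is always finite.
#'
#' @param sessions A [session()], list of sessions, or [session_set()].
#' @param params A [param_set()] satisfying the model's constraints.
#' @param model A [model_spec()].
#' @param q_init Initial action value for both sides at each session start
#'   (default 0).
#' @param prob_floor Probability floor before taking logs (default 1e-12).
#' @return The summed log-likelihood (a non-positive number in practice).
#' @export
session_loglik <- function(sessions, params, model, q_init = 0,
                           prob_floor = 1e-12) {
  sessions <- as_session_list(sessions)
  if (length(sessions) == 0L) stop("at least one session is required")
  validate_params_for_model(params, model)
  dat <- pool_trials(sessions)
  -qlearn_negloglik_cpp(dat$choice, dat$reward, dat$session_id,
                        param_vector(params), q_init, prob_floor)
}

# Flatten a list of sessions into the integer vectors the C++ kernel takes.
pool_trials <- function(sessions) {
  choice <- integer(0)
  reward <- integer(0)
  session_id <- integer(0)
  for (i in seq_along(sessions)) {
    tr <- sessions[[i]]$trials
    choice <- c(choice, ifelse(tr$choice == "L", 1L, 2L))
    reward <- c(reward, as.integer(tr$reward))
    session_id <- c(session_id, rep.int(i, nrow(tr)))
  }
  list(choice = choice, reward = reward, session_id = session_id)
}

# Accept a single session, plain list of sessions, or a session_set.
as_session_list <- function(x) {
  if (inherits(x, "bandit_session")) return(list(x))
  if (inherits(x, "session_set")) return(x$sessions)
  if (is.list(x)) return(x)
  stop("expected a session, list of sessions, or session_set")
}

#' Per-trial value trajectory for a session
#'
#' Replays the session's observed choices and rewards with the supplied
#' parameters and returns, per trial, the \emph{pre-choice} action values,
#' the softmax probability of a left choice, and the values of the currently
#' higher- and lower-reward-probability sides (\code{q_high}, \code{q_low},
#' mapped through each trial's \code{high_side}).
#'
#' @param session A [session()].
#' @inheritParams session_loglik
#' @return A \code{value_trajectory}: a data.frame with columns
#'   \code{trial_index}, \code{block_index}, \code{q_left}, \code{q_right},
#'   \code{p_left}, \code{q_high}, \code{q_low}.
#' @export
value_trajectory <- function(session, params, model, q_init = 0) {
  stopifnot(inherits(session, "bandit_session"))
  validate_params_for_model(params, model)
  tr <- session$trials
  m <- qlearn_trajectory_cpp(ifelse(tr$choice == "L", 1L, 2L),
                             as.integer(tr$reward),
                             param_vector(params), q_init)
  out <- data.frame(trial_index = tr$trial_index,
                    block_index = tr$block_index,
                    q_left = m[, 1], q_right = m[, 2], p_left = m[, 5])
  out$q_high <- ifelse(tr$high_side == "L", out$q_left, out$q_right)
  out$q_low <- ifelse(tr$high_side == "L", out$q_right, out$q_left)
  class(out) <- c("value_trajectory", "data.frame")
  out
}
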