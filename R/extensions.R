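# History-dependent (Rescorla-Wagner) trial generation and the
# multi-categorical softmax trial-generating condition.
#
# Values toward stimuli are learned by the delta rule
#   v_t(u) = v_{t-1}(u) + lambda * (r_t(u) - v_{t-1}(u)),
# whose expansion to the initial value is
#   v_t(u) = lambda * sum_{n=0}^{t-2} gamma^n r_{t-n}(u) + gamma^{t-1} v_1(u),
# with gamma = 1 - lambda. Trial indexing: v_1 is the initial value and
# the first reward arrives on trial 2, so after trials 2..t the current
# value is v_t. The history term c(u) at trial t collects the rewards of
# trials 2..t-1: c(u) = lambda * sum_{n=1}^{t-2} gamma^n r_{t-n}(u).

#' Initialise a Rescorla-Wagner learner state
#'
#' @param initial_values Named numeric vector of initial values `v_1(u)`
#'   per stimulus (at least two stimuli for trial generation).
#' @param learning_rate Delta-rule learning rate `lambda` in (0, 1].
#' @return An object of class `rw_state` with the current values, the
#'   per-stimulus reward history and the current trial index `t`.
#' @export
rw_init <- function(initial_values, learning_rate) {
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must be in (0, 1]")
  if (is.null(names(initial_values)) || any(names(initial_values) == ""))
    stop("initial_values must be a named vector")
  structure(list(
    values = initial_values,
    initial_values = initial_values,
    rewards = stats::setNames(
      rep(list(numeric(0)), length(initial_values)),
      names(initial_values)),
    t = 1L,
    learning_rate = learning_rate,
    gamma = 1 - learning_rate
  ), class = "rw_state")
}

#' Delta-rule update of one stimulus value
#'
#' Applies `v <- v + lambda * (r - v)` to the named stimulus and appends
#' the reward to that stimulus's history. Other stimuli are unchanged.
#' Does not advance the trial index; see [rw_trial()] for a full trial in
#' which every stimulus receives a reward.
#'
#' @param state An `rw_state`.
#' @param stimulus Stimulus name.
#' @param reward Observed reward for that stimulus on this trial.
#' @return The updated `rw_state`.
#' @export
rw_update <- function(state, stimulus, reward) {
  stopifnot(inherits(state, "rw_state"))
  if (!stimulus %in% names(state$values))
    stop("unknown stimulus: ", stimulus)
  v <- state$values[[stimulus]]
  state$values[[stimulus]] <- v + state$learning_rate * (reward - v)
  state$rewards[[stimulus]] <- c(state$rewards[[stimulus]], reward)
  state
}

#' Advance one trial, updating every stimulus
#'
#' Applies [rw_update()] to each stimulus with its reward for this trial
#' and increments the trial index, so that the stored values are `v_t`.
#'
#' @param state An `rw_state`.
#' @param rewards Named numeric vector with one reward per stimulus.
#' @return The updated `rw_state` with `t` incremented.
#' @export
rw_trial <- function(state, rewards) {
  stopifnot(inherits(state, "rw_state"))
  if (!setequal(names(rewards), names(state$values)))
    stop("rewards must name every stimulus exactly once")
  for (u in names(rewards)) state <- rw_update(state, u, rewards[[u]])
  state$t <- state$t + 1L
  state
}

# Expanded-form value (initial-value expansion of the delta rule) from a
# reward path; used as the algebraic cross-check of the recursion.
rw_value_expanded <- function(initial_value, rewards, learning_rate) {
  gamma <- 1 - learning_rate
  t <- length(rewards) + 1L  # rewards arrive on trials 2..t
  if (t == 1L) return(initial_value)
  # reward on trial t-n carries weight gamma^n, n = 0..t-2
  n <- 0:(t - 2L)
  learning_rate * sum(gamma^n * rev(rewards)) + gamma^(t - 1L) * initial_value
}

# History terms c(u) at the state's upcoming trial t+1: discounted sum of
# past rewards excluding the upcoming trial's own reward.
rw_history_terms <- function(state) {
  gamma <- state$gamma
  vapply(state$rewards, function(r) {
    if (length(r) == 0L) return(0)
    n <- seq_along(r)  # most recent reward has n = 1
    state$learning_rate * sum(gamma^n * rev(r))
  }, numeric(1))
}

#' Reward inducing a target choice probability under RW learning
#'
#' Given the learner's state before trial `t` and the reward that will be
#' delivered for stimulus `u2`, returns the reward for stimulus `u1` such
#' that, after both values are updated by the delta rule, the sigmoid
#' choice probability for `u1` equals `p1`:
#' `r_t(u1) = log(p1/(1-p1))/(lambda*beta) + r_t(u2)
#'            + (c2 - c1 + gamma^(t-1) * (v_1(u2) - v_1(u1))) / lambda`.
#' With no prior knowledge and no history, `p1 = 0.5` gives
#' `r_t(u1) = r_t(u2)`.
#'
#' @param state An `rw_state` with (at least) stimuli `u1` and `u2`.
#' @param p1 Target probability of selecting `u1`, strictly in (0, 1).
#' @param r_u2 Reward to be delivered for `u2` on this trial.
#' @param beta Sensitivity of the sigmoid response model, `> 0`.
#' @param u1,u2 Stimulus names (default: the first two in the state).
#' @return The reward `r_t(u1)`.
#' @export
rw_trial_reward <- function(state, p1, r_u2, beta,
                            u1 = names(state$values)[1],
                            u2 = names(state$values)[2]) {
  stopifnot(inherits(state, "rw_state"))
  if (p1 <= 0 || p1 >= 1) stop("target probability must be in (0, 1)")
  if (beta <= 0) stop("beta must be > 0")
  lam <- state$learning_rate
  gamma <- state$gamma
  t_next <- state$t + 1L
  cc <- rw_history_terms(state)
  log(p1 / (1 - p1)) / (lam * beta) + r_u2 +
    (cc[[u2]] - cc[[u1]] +
       gamma^(t_next - 1L) *
         (state$initial_values[[u2]] - state$initial_values[[u1]])) / lam
}

#' Softmax choice probabilities
#'
#' @param beta Sensitivity, `> 0`.
#' @param v Numeric vector of option values.
#' @return Probabilities summing to 1 (computed with the max-shift trick).
#' @export
softmax_probs <- function(beta, v) {
  z <- beta * v
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Option values inducing prescribed multinomial choice probabilities
#'
#' Solves the coupled trial-generating conditions
#' `v_k = log(sum_{j != k} exp(beta * v_j)) / beta + log(p_k/(1-p_k)) / beta`
#' so that `softmax(beta * v)` reproduces the targets. The system is
#' invariant to adding a constant to all values; the gauge is fixed by
#' anchoring the last value to 0. Solved by damped fixed-point iteration
#' on the conditions.
#'
#' @param target_probs Probabilities `p_k`, each in (0, 1), summing to 1
#'   (length `K >= 2`).
#' @param beta Sensitivity, `> 0`.
#' @param tol Convergence tolerance on the induced probabilities
#'   (default 1e-10).
#' @param max_iter Iteration cap.
#' @param damping Step damping in (0, 1].
#' @return Numeric vector `v` with `v[K] = 0` and
#'   `softmax_probs(beta, v)` equal to `target_probs` within `tol`; errors
#'   with the residual if the iteration fails to converge.
#' @export
softmax_trial_values <- function(target_probs, beta, tol = 1e-10,
                                 max_iter = 1000, damping = 0.5) {
  K <- length(target_probs)
  if (K < 2) stop("need at least 2 options")
  if (any(target_probs <= 0 | target_probs >= 1))
    stop("each target probability must be in (0, 1)")
  if (abs(sum(target_probs) - 1) > 1e-8)
    stop("target probabilities must sum to 1")
  if (beta <= 0) stop("beta must be > 0")
  v <- numeric(K)
  for (iter in seq_len(max_iter)) {
    new_v <- vapply(seq_len(K), function(k) {
      log(sum(exp(beta * v[-k]))) / beta +
        log(target_probs[k] / (1 - target_probs[k])) / beta
    }, numeric(1))
    v <- (1 - damping) * v + damping * new_v
    v <- v - v[K]  # gauge: anchor the last value at 0
    if (max(abs(softmax_probs(beta, v) - target_probs)) < tol)
      return(v)
  }
  resid <- max(abs(softmax_probs(beta, v) - target_probs))
  stop("softmax condition did not converge; residual = ", format(resid))
}
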