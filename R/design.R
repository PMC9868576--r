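# Adaptive trial generation: invert the fitted response model to pick
# immediate rewards that induce prescribed choice probabilities, with
# iterative delay adjustment and penny clamping for unattainable targets.

#' Design grid for the two-run protocol
#'
#' Defaults are the standard intertemporal-choice grid: delays of
#' 7, 30, 90, 180 and 365 days, delayed rewards of 5, 10, 20, 50 and 100
#' currency units, nine target probabilities 0.1 to 0.9, and four
#' representative discounting parameter pairs spanning shallow to steep
#' discounting (used for run A only; configurable, not normative values).
#'
#' @param delays Delays in days.
#' @param delayed_rewards Delayed reward magnitudes.
#' @param targets Target immediate-choice probabilities, each in (0, 1).
#' @param representative_params List of `c(kappa, s)` pairs for run A.
#' @return An object of class `design_grid`.
#' @export
design_grid <- function(delays = c(7, 30, 90, 180, 365),
                        delayed_rewards = c(5, 10, 20, 50, 100),
                        targets = seq(0.1, 0.9, by = 0.1),
                        representative_params = list(
                          c(kappa = 0.002, s = 1),
                          c(kappa = 0.01,  s = 1),
                          c(kappa = 0.05,  s = 1),
                          c(kappa = 0.2,   s = 1))) {
  stopifnot(all(delays >= 0), all(delayed_rewards > 0),
            all(targets > 0 & targets < 1))
  structure(list(delays = delays, delayed_rewards = delayed_rewards,
                 targets = targets,
                 representative_params = representative_params),
            class = "design_grid")
}

#' Immediate reward inducing a target choice probability
#'
#' Closed-form inversion of the logistic response model:
#' `r_imm = df(D) * r_del + log(p / (1 - p)) / beta`, where `df(D)` is the
#' model's discount factor at delay `D`. Feeding the result back through
#' the response model returns `p` exactly (up to float error), before any
#' clamping.
#'
#' @param params A `param_vector` (supplies the discounting parameters and
#'   `beta`).
#' @param r_del Delayed reward.
#' @param delay Delay in days.
#' @param p Target immediate-choice probability, strictly in (0, 1).
#' @return The (unclamped) immediate reward; may fall outside
#'   `[0, r_del]` for extreme targets or parameters.
#' @export
solve_immediate_reward <- function(params, r_del, delay, p) {
  if (any(p <= 0 | p >= 1))
    stop("target probability must satisfy 0 < p < 1")
  beta <- param_beta(params)
  if (beta <= 0) stop("beta must be > 0")
  discount_factor(params, delay) * r_del + log(p / (1 - p)) / beta
}

# Candidate delays visited by the iterative adjustment: geometric steps
# from the current delay toward 1 or 365 (integer days), bound included.
.delay_ladder <- function(delay, direction) {
  out <- integer(0)
  d <- delay
  bound <- if (direction < 0) 1 else 365
  repeat {
    d <- if (direction < 0) floor(d / 2) else ceiling(d * 2)
    d <- max(1, min(365, d))
    out <- c(out, d)
    if (d == bound) break
  }
  out
}

#' Clamp an unattainable generated trial
#'
#' When the inverted immediate reward falls outside `(0, r_del)`, the
#' delay is first adjusted iteratively (shorter delays raise the
#' discounted value and hence the immediate reward; longer delays lower
#' it) within `[1, 365]` days. If no delay resolves the problem,
#' non-positive immediate rewards are set to 1 penny (0.01) and immediate
#' rewards at or above the delayed reward are set to `r_del - 0.01`.
#'
#' @param r_imm Raw immediate reward from [solve_immediate_reward()].
#' @param r_del Delayed reward.
#' @param delay Original delay in days.
#' @param params The `param_vector` used to generate the trial.
#' @param p The target probability (used to re-solve at adjusted delays).
#' @return List with `r_imm`, `delay` and logical `adjusted`.
#' @export
apply_clamping <- function(r_imm, r_del, delay, params, p) {
  lo <- 0.01
  hi <- r_del - 0.01
  if (r_imm >= lo && r_imm <= hi)
    return(list(r_imm = r_imm, delay = delay, adjusted = FALSE))
  direction <- if (r_imm < lo) -1 else 1
  for (d in .delay_ladder(delay, direction)) {
    cand <- solve_immediate_reward(params, r_del, d, p)
    if (cand >= lo && cand <= hi)
      return(list(r_imm = cand, delay = d, adjusted = TRUE))
  }
  # unresolved at the delay bounds: fall back to the penny rules at the
  # original delay
  list(r_imm = if (r_imm < lo) lo else hi, delay = delay, adjusted = TRUE)
}

#' Generate the inference run (run A)
#'
#' One indifference trial (target probability 0.5) per combination of
#' delay, delayed reward and representative discounting parameter pair:
#' `r_imm = df(kappa_j, s_j; D) * r_del`, clamped to at most
#' `r_del - 0.01`. With the default grid this yields
#' 5 delays x 5 rewards x 4 parameter pairs = 100 trials.
#'
#' @param grid A [design_grid()].
#' @return Data frame of trials with columns `r_imm`, `r_del`,
#'   `delay_days`, `target_p`, `rep_param_set`, `adjusted`.
#' @export
generate_run_a <- function(grid = design_grid()) {
  stopifnot(inherits(grid, "design_grid"))
  rows <- list()
  for (j in seq_along(grid$representative_params)) {
    rp <- grid$representative_params[[j]]
    # beta is irrelevant at p = 0.5 (log-odds term vanishes); any valid
    # value serves
    pv <- param_vector("modified_hyperboloid",
                       kappa = rp[["kappa"]], s = rp[["s"]], beta = 1)
    for (D in grid$delays) for (r_del in grid$delayed_rewards) {
      r_imm <- discount_factor(pv, D) * r_del
      cl <- apply_clamping(r_imm, r_del, D, pv, 0.5)
      rows[[length(rows) + 1L]] <- data.frame(
        r_imm = cl$r_imm, r_del = r_del, delay_days = cl$delay,
        target_p = 0.5, rep_param_set = j, adjusted = cl$adjusted)
    }
  }
  do.call(rbind, rows)
}

#' Generate the induction run (run B)
#'
#' For each target probability, delay and delayed reward, solves for the
#' immediate reward inducing the target under the fitted model, applies
#' the clamping rules, and records the model-predicted probability of the
#' emitted (possibly adjusted) trial. With the default grid this yields
#' 9 targets x 5 delays x 5 rewards = 225 trials.
#'
#' @param fit A `fit_result` (typically from run A) or a `param_vector`.
#' @param grid A [design_grid()].
#' @return Data frame with columns `r_imm`, `r_del`, `delay_days`,
#'   `target_p`, `predicted_p` (recomputed after any adjustment) and
#'   `adjusted`.
#' @export
generate_run_b <- function(fit, grid = design_grid()) {
  stopifnot(inherits(grid, "design_grid"))
  params <- if (inherits(fit, "fit_result")) fit$params else fit
  stopifnot(inherits(params, "param_vector"))
  beta <- param_beta(params)
  rows <- vector("list",
                 length(grid$targets) * length(grid$delays) *
                   length(grid$delayed_rewards))
  i <- 0L
  for (p in grid$targets) for (D in grid$delays)
    for (r_del in grid$delayed_rewards) {
      r_imm <- solve_immediate_reward(params, r_del, D, p)
      cl <- apply_clamping(r_imm, r_del, D, params, p)
      pred <- p_immediate(beta, cl$r_imm,
                          discount_value(params, r_del, cl$delay))
      i <- i + 1L
      rows[[i]] <- data.frame(
        r_imm = cl$r_imm, r_del = r_del, delay_days = cl$delay,
        target_p = p, predicted_p = pred, adjusted = cl$adjusted)
    }
  do.call(rbind, rows)
}
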