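# Discounting model zoo and probabilistic response model.
#
# Every model maps a reward r and a delay D (days) to a subjective value
# v in [0, r]; a logistic response model then maps the value difference
# between the delayed and the immediate option to an immediate-choice
# probability. Delays are in days throughout, so rate parameters are
# per-day (for shape parameters s != 1 the unit of kappa is day^-s).

# Internal registry. Each entry: ordered parameter names, closed bounds,
# value function of (params, r, delay), and the number of free parameters
# fitted by MLE (the control model has beta structurally fixed to 1).
.model_registry <- local({
  rate_up <- 1000
  reg <- list(
    hyperbolic = list(
      param_names = c("kappa", "beta"),
      lower = c(kappa = 0, beta = 0.001),
      upper = c(kappa = rate_up, beta = 2),
      value = function(p, r, delay) r / (1 + p[["kappa"]] * delay)
    ),
    exponential = list(
      param_names = c("kappa", "beta"),
      lower = c(kappa = 0, beta = 0.001),
      upper = c(kappa = rate_up, beta = 2),
      value = function(p, r, delay) r * exp(-p[["kappa"]] * delay)
    ),
    constant_sensitivity = list(
      param_names = c("kappa", "s", "beta"),
      lower = c(kappa = 0, s = 0, beta = 0.001),
      upper = c(kappa = rate_up, s = 1, beta = 2),
      value = function(p, r, delay) r * exp(-(p[["kappa"]] * delay)^p[["s"]])
    ),
    modified_hyperboloid = list(
      param_names = c("kappa", "s", "beta"),
      lower = c(kappa = 0, s = 0, beta = 0.001),
      upper = c(kappa = rate_up, s = 1, beta = 2),
      value = function(p, r, delay) r / (1 + p[["kappa"]] * delay^p[["s"]])
    ),
    quasi_hyperbolic = list(
      param_names = c("b", "delta", "beta"),
      lower = c(b = 0, delta = 0, beta = 0.001),
      upper = c(b = 1, delta = 1, beta = 2),
      value = function(p, r, delay) {
        ifelse(delay == 0, r, r * p[["b"]] * p[["delta"]]^delay)
      }
    ),
    hyperboloid = list(
      param_names = c("kappa", "s", "beta"),
      lower = c(kappa = 0, s = 0, beta = 0.001),
      upper = c(kappa = rate_up, s = 1, beta = 2),
      value = function(p, r, delay) r / (1 + p[["kappa"]] * delay)^p[["s"]]
    ),
    double_exponential = list(
      param_names = c("omega", "kappa1", "kappa2", "beta"),
      lower = c(omega = 0, kappa1 = 0, kappa2 = 0, beta = 0.001),
      upper = c(omega = 1, kappa1 = rate_up, kappa2 = rate_up, beta = 2),
      value = function(p, r, delay) {
        r * (p[["omega"]] * exp(-p[["kappa1"]] * delay) +
               (1 - p[["omega"]]) * exp(-p[["kappa2"]] * delay))
      }
    ),
    control = list(
      param_names = c("kappa", "s"),
      lower = c(kappa = 0, s = 0),
      upper = c(kappa = rate_up, s = 1),
      value = function(p, r, delay) r / (1 + p[["kappa"]] * delay^p[["s"]]),
      fixed_beta = 1
    )
  )
  for (nm in names(reg)) reg[[nm]]$name <- nm
  reg
})

#' Names of the discounting models in the registry
#'
#' @return Character vector of the eight registered model names.
#' @export
model_names <- function() names(.model_registry)

#' Look up a discounting model specification
#'
#' A model specification bundles the ordered parameter names, their closed
#' box bounds, the value function and (for the control model) the
#' structurally fixed response sensitivity `beta = 1`.
#'
#' @param name One of [model_names()].
#' @return An object of class `model_spec`.
#' @examples
#' spec <- model_spec("modified_hyperboloid")
#' spec$param_names
#' @export
model_spec <- function(name) {
  name <- match.arg(name, names(.model_registry))
  spec <- .model_registry[[name]]
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name, "\n")
  b <- rbind(lower = x$lower, upper = x$upper)
  colnames(b) <- x$param_names
  print(b)
  if (!is.null(x$fixed_beta)) cat("beta fixed to", x$fixed_beta, "\n")
  invisible(x)
}

#' Construct an in-bounds parameter vector for a model
#'
#' @param model A `model_spec` or a model name.
#' @param ... Named parameter values, e.g. `kappa = 0.05, s = 1, beta = 0.3`.
#'   For the control model `beta` must not be supplied (it is fixed to 1).
#' @return A named object of class `param_vector` carrying the model spec.
#' @examples
#' param_vector("modified_hyperboloid", kappa = 0.05, s = 1, beta = 0.3)
#' @export
param_vector <- function(model, ...) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  vals <- c(...)
  missing <- setdiff(spec$param_names, names(vals))
  if (length(missing) > 0L)
    stop("missing parameter(s) for ", spec$name, ": ",
         paste(missing, collapse = ", "))
  extra <- setdiff(names(vals), spec$param_names)
  if (length(extra) > 0L)
    stop("unknown parameter(s) for ", spec$name, ": ",
         paste(extra, collapse = ", "))
  vals <- vals[spec$param_names]
  validate_params(spec, vals)
  structure(as.list(vals), spec = spec, class = "param_vector")
}

# Bounds check; errors name the offending parameter.
validate_params <- function(spec, vals) {
  for (nm in spec$param_names) {
    v <- vals[[nm]]
    if (!is.finite(v) || v < spec$lower[[nm]] || v > spec$upper[[nm]])
      stop(sprintf("parameter '%s' = %g out of bounds [%g, %g] for model %s",
                   nm, v, spec$lower[[nm]], spec$upper[[nm]], spec$name))
  }
  invisible(TRUE)
}

#' @export
print.param_vector <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("<param_vector>", spec$name, ":",
      paste(sprintf("%s=%g", names(x), unlist(x)), collapse = ", "), "\n")
  invisible(x)
}

# Response sensitivity of a param_vector (fixed to 1 for the control model).
param_beta <- function(params) {
  spec <- attr(params, "spec")
  if (!is.null(spec$fixed_beta)) spec$fixed_beta else params[["beta"]]
}

#' Subjective (discounted) value of a delayed reward
#'
#' Evaluates the model's value function `v = f(r, D)`; for the modified
#' hyperboloid this is `v = r / (1 + kappa * D^s)`. At delay 0 every model
#' returns the reward unchanged.
#'
#' @param params A `param_vector`.
#' @param r Reward magnitude(s), currency units, `>= 0`. Vectorised.
#' @param delay Delay(s) in days, `>= 0`. Vectorised (recycled with `r`).
#' @return Subjective value(s) in `[0, r]`.
#' @examples
#' p <- param_vector("modified_hyperboloid", kappa = 0.05, s = 1, beta = 0.3)
#' discount_value(p, r = 50, delay = 90)  # 50 / 5.5
#' @export
discount_value <- function(params, r, delay) {
  stopifnot(inherits(params, "param_vector"))
  spec <- attr(params, "spec")
  validate_params(spec, params)
  if (any(r < 0)) stop("reward must be >= 0")
  if (any(delay < 0)) stop("delay must be >= 0")
  v <- spec$value(params, r, delay)
  # delay 0 always maps to the undiscounted reward (covers 0^0 edge cases
  # in the shape-parameter models)
  v[delay == 0] <- rep_len(r, length(v))[delay == 0]
  v
}

#' Discount factor at a given delay
#'
#' The multiplier on reward implied by the model at delay `D`, i.e.
#' `discount_value(params, 1, D)`. Equals 1 at delay 0 and is
#' non-increasing in delay for all in-bound parameters.
#'
#' @inheritParams discount_value
#' @return Fraction(s) in `[0, 1]`.
#' @export
discount_factor <- function(params, delay) {
  discount_value(params, 1, delay)
}

#' Immediate-choice probability under the logistic response model
#'
#' `p_imm = 1 / (1 + exp(beta * (v_del - v_imm)))`: the probability of
#' choosing the immediate option given the two subjective values and the
#' sensitivity `beta`. Equals 0.5 at indifference (`v_imm = v_del`) and is
#' increasing in `v_imm`.
#'
#' @param beta Sensitivity (inverse temperature), `> 0`.
#' @param v_imm,v_del Subjective values of the immediate and delayed
#'   option. Vectorised.
#' @return Probability(ies) in `(0, 1)`.
#' @examples
#' p_immediate(0.3, v_imm = 10, v_del = 9)  # 1 / (1 + exp(-0.3))
#' @export
p_immediate <- function(beta, v_imm, v_del) {
  if (any(beta <= 0)) stop("beta must be > 0")
  stats::plogis(beta * (v_imm - v_del))
}

# Vectorised immediate-choice probabilities for a set of trials. `trials`
# is any data frame with columns r_imm, r_del, delay_days.
trial_p_immediate <- function(params, trials) {
  v_del <- discount_value(params, trials$r_del, trials$delay_days)
  p_immediate(param_beta(params), trials$r_imm, v_del)
}

#' Bernoulli log-likelihood of a choice sequence
#'
#' Sum over trials of `log p(choice)` under the model, where the
#' per-trial immediate-choice probability comes from the discounting model
#' plus logistic response model. Probabilities are truncated to
#' `[1e-10, 1 - 1e-10]` so the log-likelihood is always finite.
#'
#' @param params A `param_vector`.
#' @param data A choice data frame with columns `r_imm`, `r_del`,
#'   `delay_days` and `choice` (1 = immediate, 0 = delayed).
#' @return The log-likelihood (a finite scalar).
#' @export
log_likelihood <- function(params, data) {
  if (NROW(data) == 0L) stop("empty choice data")
  if (!all(data$choice %in% c(0, 1))) stop("choice must be binary (0/1)")
  p <- trial_p_immediate(params, data)
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  sum(ifelse(data$choice == 1, log(p), log1p(-p)))
}
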