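# Synthetic Bernoulli agents: simulate choice data from any zoo model so
# the full two-run protocol can be studied without human data.

#' Define a synthetic choice agent
#'
#' @param params A `param_vector` (the agent's true generative
#'   parameters).
#' @param seed Integer seed for the agent's choice stream.
#' @param label Optional label.
#' @return An object of class `agent_spec`.
#' @export
agent_spec <- function(params, seed, label = NULL) {
  stopifnot(inherits(params, "param_vector"))
  structure(list(params = params, seed = as.integer(seed),
                 label = label %||% paste0("agent_", seed)),
            class = "agent_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate choices of an agent on a set of trials
#'
#' Each choice is an independent Bernoulli draw with success (immediate
#' choice) probability given by the agent's discounting plus response
#' model. Reproducible given the agent's seed.
#'
#' @param agent An [agent_spec()] (or a `param_vector`, with `seed`
#'   supplied explicitly).
#' @param trials Trial data frame with columns `r_imm`, `r_del`,
#'   `delay_days`.
#' @param seed Overrides the agent's seed when given.
#' @return The trial data frame with added columns `choice` (1 =
#'   immediate, 0 = delayed) and `p_true` (the generating probability).
#' @export
simulate_choices <- function(agent, trials, seed = NULL) {
  if (inherits(agent, "param_vector")) {
    if (is.null(seed)) stop("seed required when passing a param_vector")
    agent <- agent_spec(agent, seed)
  }
  stopifnot(inherits(agent, "agent_spec"))
  p <- trial_p_immediate(agent$params, trials)
  set.seed(seed %||% agent$seed)
  trials$p_true <- p
  trials$choice <- stats::rbinom(length(p), 1, p)
  trials
}

#' Sample a population of synthetic agents
#'
#' Discounting rates are drawn log-uniformly and shape/sensitivity
#' parameters uniformly over the given ranges (mirroring the optimiser's
#' start distribution). Defaults span moderate, recoverable discounting:
#' `kappa` in [0.002, 0.2] (log-uniform), `s` in [0.4, 1], `beta` in
#' [0.1, 1] for the modified hyperboloid.
#'
#' @param n Number of agents.
#' @param model Model name (default `"modified_hyperboloid"`).
#' @param ranges Named list of `c(lower, upper)` ranges per parameter;
#'   must lie within the model's bounds.
#' @param seed Master seed; each agent receives a derived sub-seed so the
#'   population and every agent's choice stream are reproducible.
#' @return List of [agent_spec()]s.
#' @export
sample_population <- function(n, model = "modified_hyperboloid",
                              ranges = list(kappa = c(0.002, 0.2),
                                            s = c(0.4, 1),
                                            beta = c(0.1, 1)),
                              seed = 1) {
  spec <- model_spec(model)
  if (!setequal(names(ranges), spec$param_names))
    stop("ranges must name exactly the parameters of ", spec$name)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (length(rg) != 2 || rg[1] > rg[2]) stop("bad range for ", nm)
    if (rg[1] < spec$lower[[nm]] || rg[2] > spec$upper[[nm]])
      stop("range for ", nm, " outside model bounds")
  }
  is_rate <- function(nm) nm %in% c("kappa", "kappa1", "kappa2")
  set.seed(seed)
  agent_seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    vals <- vapply(spec$param_names, function(nm) {
      rg <- ranges[[nm]]
      if (is_rate(nm) && rg[1] > 0)
        exp(stats::runif(1, log(rg[1]), log(rg[2])))
      else stats::runif(1, rg[1], rg[2])
    }, numeric(1))
    agent_spec(do.call(param_vector, c(list(spec), as.list(vals))),
               seed = agent_seeds[i],
               label = sprintf("agent_%03d", i))
  })
}

#' Run the full two-run adaptive protocol on synthetic agents
#'
#' For each agent: simulate run-A choices on the shared inference run,
#' fit the working model (or the whole zoo), generate that agent's
#' individualised run B from the run-A fit, simulate run-B choices, and
#' (when the zoo is fitted on both runs) assemble the cross-run
#' prediction-error report. Agents whose simulated run-A discounted-choice
#' rate is outside `[min_rate, 1 - min_rate]` are excluded as degenerate
#' (all-one-choice behaviour carries no information about the trade-off).
#'
#' @param agents List of [agent_spec()]s.
#' @param grid A [design_grid()].
#' @param seed Master seed for per-stage sub-seeds (fitting starts and
#'   choice streams).
#' @param models Models to fit (default: only the working
#'   `"modified_hyperboloid"`; pass [model_names()] for the full zoo and a
#'   PE report).
#' @param design_model Model whose run-A fit generates run B (default
#'   `"modified_hyperboloid"`); must be among `models`.
#' @param n_starts Starts per fit.
#' @param min_rate Degeneracy filter on the run-A discounted-choice rate
#'   (default 0.05).
#' @return List with `run_a` (trial frame), `data_run_a`, `fits_run_a`,
#'   `run_b`, `data_run_b`, `fits_run_b` (only when more than one model or
#'   both-run fitting requested), `pe_report` (when available),
#'   `agents_used`, `excluded`.
#' @export
end_to_end_experiment <- function(agents, grid = design_grid(), seed = 1,
                                  models = "modified_hyperboloid",
                                  design_model = "modified_hyperboloid",
                                  n_starts = 20, min_rate = 0.05,
                                  fit_run_b = length(models) > 1) {
  if (!design_model %in% models)
    stop("design_model must be among the fitted models")
  run_a <- generate_run_a(grid)
  set.seed(seed)
  stage_seeds <- matrix(sample.int(.Machine$integer.max, 4 * length(agents)),
                        ncol = 4)
  data_a <- list(); fits_a <- list(); run_b <- list()
  data_b <- list(); fits_b <- list()
  excluded <- character(0)
  for (i in seq_along(agents)) {
    ag <- agents[[i]]
    da <- simulate_choices(ag, run_a, seed = stage_seeds[i, 1])
    disc_rate <- 1 - mean(da$choice)  # discounted = delayed choice
    if (disc_rate < min_rate || disc_rate > 1 - min_rate) {
      excluded <- c(excluded, ag$label)
      next
    }
    fa <- if (length(models) == 1L)
      stats::setNames(list(suppressWarnings(
        fit_mle(models, da, n_starts = n_starts,
                seed = stage_seeds[i, 2]))), models)
    else fit_all_models(da, models = models, n_starts = n_starts,
                        seed = stage_seeds[i, 2])
    rb <- generate_run_b(fa[[design_model]], grid)
    db <- simulate_choices(ag, rb, seed = stage_seeds[i, 3])
    id <- ag$label
    data_a[[id]] <- da; fits_a[[id]] <- fa
    run_b[[id]] <- rb; data_b[[id]] <- db
    if (fit_run_b) {
      fits_b[[id]] <- if (length(models) == 1L)
        stats::setNames(list(suppressWarnings(
          fit_mle(models, db, n_starts = n_starts,
                  seed = stage_seeds[i, 4]))), models)
      else fit_all_models(db, models = models, n_starts = n_starts,
                          seed = stage_seeds[i, 4])
    }
  }
  pe <- NULL
  if (length(data_b) > 0) {
    pe <- if (fit_run_b)
      cross_run_pe(fits_a, data_b, fits_b, data_a)
    else cross_run_pe(fits_a, data_b)
  }
  list(run_a = run_a, data_run_a = data_a, fits_run_a = fits_a,
       run_b = run_b, data_run_b = data_b,
       fits_run_b = if (fit_run_b) fits_b else NULL,
       pe_report = pe, agents_used = names(data_a), excluded = excluded)
}

#' Observed immediate-choice frequencies per induction condition
#'
#' @param experiment Result of [end_to_end_experiment()].
#' @return Data frame with columns `participant`, `target_p`, `observed`.
#' @export
condition_frequencies <- function(experiment) {
  rows <- lapply(names(experiment$data_run_b), function(id) {
    db <- experiment$data_run_b[[id]]
    ag <- stats::aggregate(choice ~ target_p, data = db, FUN = mean)
    data.frame(participant = id, target_p = ag$target_p,
               observed = ag$choice)
  })
  do.call(rbind, rows)
}
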