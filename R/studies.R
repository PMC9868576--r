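# Canned simulation studies of the adaptive protocol's core claims:
# induction fidelity, parameter recovery and model selection. Each runs
# the full pipeline on synthetic agents and summarises the evidence the
# protocol rests on.

# Clamp-free validation regime: discounting steep enough and sensitivity
# high enough that every target probability is attainable within the
# reward and delay grid, so induced frequencies can be compared to the
# targets without clamping bias. See the methods vignette.
induction_ranges <- function() {
  list(kappa = c(0.02, 0.2), s = c(0.8, 1), beta = c(0.8, 1.6))
}

#' Induction-fidelity study
#'
#' Simulates the full two-run protocol on `n_agents` synthetic agents
#' drawn from a clamp-free parameter regime, then compares the observed
#' per-condition immediate-choice frequencies with the nine induced
#' targets and regresses observed on induced frequencies.
#'
#' @param n_agents Number of synthetic agents (default 50).
#' @param seed Master seed.
#' @param n_starts Optimiser starts per fit.
#' @param oracle_design If `TRUE`, skip the run-A fitting stage and
#'   generate each agent's run B from its true parameters. This isolates
#'   the design apparatus (inversion, clamping, Bernoulli sampling) from
#'   parameter-estimation noise; deviations then reflect sampling noise
#'   only.
#' @return List: `freq` (participant x condition frequencies),
#'   `condition_means` (per-target mean observed frequency and deviation),
#'   `regression` (group-level offset/slope), `max_abs_dev`,
#'   `n_clamped_trials`, `experiment` (`NULL` for the oracle variant).
#' @export
study_induction <- function(n_agents = 50, seed = 1, n_starts = 20,
                            oracle_design = FALSE) {
  pop <- sample_population(n_agents, ranges = induction_ranges(),
                           seed = seed)
  if (oracle_design) {
    set.seed(seed + 1)
    choice_seeds <- sample.int(.Machine$integer.max, n_agents)
    ex <- NULL
    run_bs <- lapply(pop, function(ag) generate_run_b(ag$params))
    freq <- do.call(rbind, lapply(seq_along(pop), function(i) {
      db <- simulate_choices(pop[[i]], run_bs[[i]],
                             seed = choice_seeds[i])
      ag <- stats::aggregate(choice ~ target_p, data = db, FUN = mean)
      data.frame(participant = pop[[i]]$label, target_p = ag$target_p,
                 observed = ag$choice)
    }))
    n_clamped <- sum(vapply(run_bs, function(rb) sum(rb$adjusted),
                            numeric(1)))
  } else {
    ex <- end_to_end_experiment(pop, seed = seed + 1, n_starts = n_starts)
    freq <- condition_frequencies(ex)
    n_clamped <- sum(vapply(ex$run_b, function(rb) sum(rb$adjusted),
                            numeric(1)))
  }
  means <- stats::aggregate(observed ~ target_p, data = freq, FUN = mean)
  means$deviation <- means$observed - means$target_p
  reg <- induction_regression(freq)
  list(freq = freq, condition_means = means, regression = reg$group,
       max_abs_dev = max(abs(means$deviation)),
       slope = reg$group$estimate[reg$group$term == "slope"],
       offset = reg$group$estimate[reg$group$term == "offset"],
       n_clamped_trials = n_clamped, experiment = ex)
}

#' Parameter-recovery study
#'
#' Simulates `n_agents` agents on the 100-trial inference run, refits the
#' modified hyperboloid by multi-start MLE and correlates true with
#' recovered quantities. The discount factor at a reference delay is the
#' quantity of interest: it is typically recovered far more reliably than
#' `kappa` alone because of the kappa-s trade-off.
#'
#' @param n_agents Number of agents (default 200).
#' @param seed Master seed.
#' @param ref_delay Delay (days) for the discount factor (default 90).
#' @param n_starts Optimiser starts per fit.
#' @return List: `estimates` (true/recovered per agent), `r_factor`,
#'   `r_kappa`, `bias_factor`, `rmse_factor`.
#' @export
study_recovery <- function(n_agents = 200, seed = 1, ref_delay = 90,
                           n_starts = 20) {
  pop <- sample_population(n_agents, seed = seed)
  run_a <- generate_run_a()
  set.seed(seed + 1)
  sub_seeds <- matrix(sample.int(.Machine$integer.max, 2 * n_agents),
                      ncol = 2)
  rows <- lapply(seq_along(pop), function(i) {
    ag <- pop[[i]]
    d <- simulate_choices(ag, run_a, seed = sub_seeds[i, 1])
    fit <- suppressWarnings(
      fit_mle("modified_hyperboloid", d, n_starts = n_starts,
              seed = sub_seeds[i, 2]))
    data.frame(
      agent = ag$label,
      kappa_true = ag$params$kappa, kappa_hat = fit$params$kappa,
      s_true = ag$params$s, s_hat = fit$params$s,
      beta_true = ag$params$beta, beta_hat = fit$params$beta,
      factor_true = discount_factor(ag$params, ref_delay),
      factor_hat = discount_factor(fit$params, ref_delay))
  })
  est <- do.call(rbind, rows)
  list(estimates = est,
       r_factor = stats::cor(est$factor_true, est$factor_hat),
       r_kappa = stats::cor(est$kappa_true, est$kappa_hat),
       bias_factor = mean(est$factor_hat - est$factor_true),
       rmse_factor = sqrt(mean((est$factor_hat - est$factor_true)^2)))
}

#' Model-selection study
#'
#' Simulates agents from the modified hyperboloid, runs the two-run
#' protocol fitting the whole zoo on both runs, and compares models by
#' out-of-sample cross-validated deviance and by in-sample AIC. Selection
#' accuracy is the fraction of agents for which a criterion picks the
#' generating model (ties within `tolerance` counted as hits).
#'
#' @param n_agents Number of agents (default 50).
#' @param seed Master seed.
#' @param n_starts Optimiser starts per fit.
#' @param tolerance Tie tolerance for best-model counting (default 0.01).
#' @return List: `mean_pe` (per model, direction A to B), `best_model_pe`,
#'   `accuracy_pe`, `accuracy_aic`, `counts_pe`, `pe_report`.
#' @export
study_model_selection <- function(n_agents = 50, seed = 1, n_starts = 20,
                                  tolerance = 0.01) {
  pop <- sample_population(n_agents, seed = seed)
  ex <- end_to_end_experiment(pop, seed = seed + 1,
                              models = model_names(),
                              n_starts = n_starts, fit_run_b = TRUE)
  pe <- ex$pe_report$pe
  pe_ab <- pe[pe$direction == "A_to_B", ]
  mean_pe <- stats::aggregate(deviance ~ model, data = pe_ab, FUN = mean)
  aic_a <- ex$pe_report$aic
  aic_a <- aic_a[aic_a$run == "A", ]
  true_model <- "modified_hyperboloid"
  hit <- function(scores, models) {
    best <- models[scores <= min(scores) + tolerance]
    true_model %in% best
  }
  ids <- unique(pe_ab$participant)
  acc_pe <- mean(vapply(ids, function(id) {
    sub <- pe_ab[pe_ab$participant == id, ]
    hit(sub$deviance, sub$model)
  }, logical(1)))
  acc_aic <- mean(vapply(ids, function(id) {
    sub <- aic_a[aic_a$participant == id, ]
    hit(sub$aic, sub$model)
  }, logical(1)))
  list(mean_pe = mean_pe,
       best_model_pe = mean_pe$model[which.min(mean_pe$deviance)],
       accuracy_pe = acc_pe, accuracy_aic = acc_aic,
       counts_pe = count_best_models(pe_ab, tolerance = tolerance),
       pe_report = ex$pe_report)
}
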