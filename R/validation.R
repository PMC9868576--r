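# Out-of-sample prediction error (binomial deviance), cross-run CV,
# best-model counting, induction regression, behavioural-homogeneity
# F-tests and test-retest reliability.

#' Mean binomial deviance between observed choices and predictions
#'
#' Per-trial deviance `2 * {y log(y / mu) + (1 - y) log((1 - y)/(1 - mu))}`
#' averaged over trials, with the `0 log 0 = 0` convention and predictions
#' truncated to `[1e-10, 1 - 1e-10]` to avoid infinities. For binary `y`
#' this is `-2 log(mu)` when `y = 1` and `-2 log(1 - mu)` when `y = 0`,
#' per trial. Non-negative; zero (up to truncation) iff every prediction
#' matches its outcome.
#'
#' @param y Binary outcomes (0/1).
#' @param mu_hat Predicted immediate-choice probabilities, same length.
#' @return Mean per-trial deviance (scalar, `>= 0`).
#' @export
binomial_deviance <- function(y, mu_hat) {
  if (length(y) != length(mu_hat))
    stop("y and mu_hat must have equal length")
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1)")
  mu <- pmin(pmax(mu_hat, 1e-10), 1 - 1e-10)
  mean(ifelse(y == 1, -2 * log(mu), -2 * log1p(-mu)))
}

#' Cross-run prediction error report
#'
#' For each participant and model, computes the out-of-sample binomial
#' deviance in both cross-validation directions: run-B choices predicted
#' by run-A fits ("PE (run B)") and vice versa. Run-B PEs are additionally
#' decomposed by target-probability condition. Participants missing either
#' run are skipped with a message.
#'
#' @param fits_run_a,fits_run_b Named lists (per participant) of named
#'   lists (per model) of `fit_result`s, as returned by [fit_all_models()].
#' @param data_run_a,data_run_b Named lists (per participant) of choice
#'   data frames; run-B frames need a `target_p` column for the
#'   per-condition decomposition.
#' @return List of class `pe_report`: `pe` (data frame: participant,
#'   model, direction, deviance, n_trials) and `pe_condition` (data frame:
#'   participant, model, target_p, deviance, n_trials), plus `aic`
#'   (participant, model, run, aic).
#' @export
cross_run_pe <- function(fits_run_a, data_run_b, fits_run_b = NULL,
                         data_run_a = NULL) {
  participants <- names(fits_run_a)
  pe <- list(); pe_cond <- list(); aic_rows <- list()
  for (id in participants) {
    if (is.null(data_run_b[[id]]) ||
        (!is.null(fits_run_b) && is.null(fits_run_b[[id]]))) {
      message("participant ", id, " missing a run; skipped")
      next
    }
    db <- data_run_b[[id]]
    for (m in names(fits_run_a[[id]])) {
      fa <- fits_run_a[[id]][[m]]
      if (!inherits(fa, "fit_result")) next
      mu_b <- trial_p_immediate(fa$params, db)
      pe[[length(pe) + 1L]] <- data.frame(
        participant = id, model = m, direction = "A_to_B",
        deviance = binomial_deviance(db$choice, mu_b), n_trials = nrow(db))
      aic_rows[[length(aic_rows) + 1L]] <- data.frame(
        participant = id, model = m, run = "A", aic = aic(fa))
      if (!is.null(db$target_p)) {
        for (tp in sort(unique(db$target_p))) {
          sel <- db$target_p == tp
          pe_cond[[length(pe_cond) + 1L]] <- data.frame(
            participant = id, model = m, target_p = tp,
            deviance = binomial_deviance(db$choice[sel], mu_b[sel]),
            n_trials = sum(sel))
        }
      }
      if (!is.null(fits_run_b) && !is.null(data_run_a)) {
        fb <- fits_run_b[[id]][[m]]
        da <- data_run_a[[id]]
        if (inherits(fb, "fit_result") && !is.null(da)) {
          mu_a <- trial_p_immediate(fb$params, da)
          pe[[length(pe) + 1L]] <- data.frame(
            participant = id, model = m, direction = "B_to_A",
            deviance = binomial_deviance(da$choice, mu_a),
            n_trials = nrow(da))
          aic_rows[[length(aic_rows) + 1L]] <- data.frame(
            participant = id, model = m, run = "B", aic = aic(fb))
        }
      }
    }
  }
  structure(list(pe = do.call(rbind, pe),
                 pe_condition = do.call(rbind, pe_cond),
                 aic = do.call(rbind, aic_rows)),
            class = "pe_report")
}

#' Count participants best described by each model
#'
#' A model is counted for a participant when its prediction error lies
#' within `tolerance` of that participant's minimum; near-ties are counted
#' multiply, so the counts can sum to more than the number of
#' participants.
#'
#' @param pe Data frame with columns `participant`, `model` and a score
#'   column (`deviance` by default).
#' @param tolerance Tie tolerance on the PE scale (default 0.01).
#' @param score Name of the score column.
#' @return Named integer vector of counts per model.
#' @export
count_best_models <- function(pe, tolerance = 0.01, score = "deviance") {
  stopifnot(all(c("participant", "model", score) %in% names(pe)))
  counts <- stats::setNames(integer(length(unique(pe$model))),
                            unique(pe$model))
  for (id in unique(pe$participant)) {
    sub <- pe[pe$participant == id, ]
    best <- sub$model[sub[[score]] <= min(sub[[score]]) + tolerance]
    counts[best] <- counts[best] + 1L
  }
  counts
}

#' Regression of observed on induced choice frequencies
#'
#' Ordinary least squares of the observed immediate-choice frequencies on
#' the induced (target) frequencies, at the group level (condition means
#' across participants regressed on targets) and per participant.
#'
#' @param freq Data frame with columns `participant`, `target_p`,
#'   `observed` (one row per participant x condition).
#' @return List with `group` (data frame: term, estimate, std_error,
#'   t_value, p_value) and `per_participant` (data frame: participant,
#'   offset, slope).
#' @export
induction_regression <- function(freq) {
  stopifnot(all(c("participant", "target_p", "observed") %in% names(freq)))
  if (length(unique(freq$target_p)) < 3)
    stop("need at least 3 distinct conditions")
  if (stats::var(freq$target_p) == 0)
    stop("degenerate (constant) predictor")
  means <- stats::aggregate(observed ~ target_p, data = freq, FUN = mean)
  gm <- stats::lm(observed ~ target_p, data = means)
  sm <- summary(gm)$coefficients
  group <- data.frame(term = c("offset", "slope"),
                      estimate = sm[, 1], std_error = sm[, 2],
                      t_value = sm[, 3], p_value = sm[, 4],
                      row.names = NULL)
  per <- do.call(rbind, lapply(split(freq, freq$participant), function(d) {
    cf <- stats::coef(stats::lm(observed ~ target_p, data = d))
    data.frame(participant = d$participant[1],
               offset = cf[[1]], slope = cf[[2]])
  }))
  rownames(per) <- NULL
  list(group = group, per_participant = per)
}

#' Variance-ratio F-test of behavioural homogeneity
#'
#' Compares the between-participant variance of immediate-choice
#' frequencies in two samples (e.g. an induction run vs. a non-adaptive
#' baseline) with an F-test on the variance ratio with
#' `(n_a - 1, n_b - 1)` degrees of freedom. The default is the two-sided
#' p-value; `alternative = "greater"` tests the one-sided hypothesis that
#' the first sample's variance is larger.
#'
#' @param freqs_a,freqs_b Per-participant frequencies in each sample.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return List with `F`, `df`, `p`.
#' @export
homogeneity_ftest <- function(freqs_a, freqs_b,
                              alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (length(freqs_a) < 2 || length(freqs_b) < 2)
    stop("need at least 2 participants per group")
  vb <- stats::var(freqs_b)
  if (vb == 0) stop("zero variance in denominator group")
  f <- stats::var(freqs_a) / vb
  df <- c(length(freqs_a) - 1L, length(freqs_b) - 1L)
  p1 <- stats::pf(f, df[1], df[2], lower.tail = FALSE)
  p <- if (alternative == "greater") p1 else min(1, 2 * min(p1, 1 - p1))
  list(F = f, df = df, p = p)
}

# Robust outlier screen: elements farther than 3 scaled median absolute
# deviations (consistency factor 1.4826) from the mean.
.mad_outlier <- function(x, k = 3) {
  abs(x - mean(x)) > k * stats::mad(x)
}

#' Test-retest reliability of fitted quantities across runs
#'
#' Pearson correlation (with p-value) between run-A and run-B estimates of
#' `beta`, `kappa`, `s` and the discount factor evaluated at a reference
#' delay (90 days by default). Before each correlation, pairs in which
#' either element lies more than 3 scaled median absolute deviations from
#' its sample mean are removed to avoid spurious correlations.
#'
#' @param fits_run_a,fits_run_b Named lists (per participant) of
#'   `fit_result`s for the same model on each run.
#' @param ref_delay Delay (days) at which the discount factor is
#'   evaluated.
#' @return Data frame: quantity, r, p, n_used, n_removed.
#' @export
reliability <- function(fits_run_a, fits_run_b, ref_delay = 90) {
  ids <- intersect(names(fits_run_a), names(fits_run_b))
  if (length(ids) < 3) stop("need at least 3 paired fits")
  extract <- function(fits, what) {
    vapply(fits[ids], function(f) {
      switch(what,
             discount_factor = discount_factor(f$params, ref_delay),
             beta = param_beta(f$params),
             if (!is.null(f$params[[what]])) f$params[[what]] else NA_real_)
    }, numeric(1))
  }
  quantities <- c("beta", "kappa", "s", "discount_factor")
  out <- lapply(quantities, function(q) {
    a <- extract(fits_run_a, q); b <- extract(fits_run_b, q)
    keep <- !is.na(a) & !is.na(b)
    a <- a[keep]; b <- b[keep]
    if (length(a) == 0) return(NULL)
    out_a <- .mad_outlier(a); out_b <- .mad_outlier(b)
    keep2 <- !(out_a | out_b)
    if (sum(keep2) < 3)
      stop("fewer than 3 pairs left after outlier removal for ", q)
    ct <- stats::cor.test(a[keep2], b[keep2], method = "pearson")
    data.frame(quantity = q, r = unname(ct$estimate), p = ct$p.value,
               n_used = sum(keep2), n_removed = sum(!keep2))
  })
  do.call(rbind, out)
}
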