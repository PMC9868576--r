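test_that("binomial deviance matches hand arithmetic and truncation", {
  expect_equal(binomial_deviance(c(1, 0), c(1, 0)), 0, tolerance = 1e-8)
  expect_equal(binomial_deviance(1, 0.5), 2 * log(2))
  expect_equal(binomial_deviance(1, 0), 2 * log(1e10))
  expect_error(binomial_deviance(c(1, 0), 0.5), "equal length")
  expect_error(binomial_deviance(2, 0.5), "binary")
  set.seed(41)
  y <- rbinom(50, 1, 0.5); mu <- runif(50)
  expect_gte(binomial_deviance(y, mu), 0)
})

test_that("per-condition deviances aggregate to the overall deviance", {
  set.seed(42)
  tp <- rep(seq(0.1, 0.9, 0.1), each = 25)
  y <- rbinom(length(tp), 1, tp); mu <- pmin(pmax(tp + rnorm(length(tp), 0, 0.05), 0.01), 0.99)
  overall <- binomial_deviance(y, mu)
  per <- vapply(unique(tp), function(t)
    binomial_deviance(y[tp == t], mu[tp == t]), numeric(1))
  n <- vapply(unique(tp), function(t) sum(tp == t), numeric(1))
  expect_equal(sum(per * n) / sum(n), overall)
})

test_that("cross-run PE prefers the generating model over a rigid control", {
  # one low-sensitivity agent: forcing beta = 1 must predict worse
  p <- mh_params(kappa = 0.03, s = 0.9, beta = 0.1)
  da <- simulated_data(p, seed = 51)
  fa <- fit_all_models(da, models = c("modified_hyperboloid", "control"),
                       n_starts = 8, seed = 6)
  rb <- generate_run_b(fa$modified_hyperboloid)
  db <- simulate_choices(agent_spec(p, 52), rb)
  rep <- cross_run_pe(list(a1 = fa), list(a1 = db))
  pe <- rep$pe
  expect_lt(pe$deviance[pe$model == "modified_hyperboloid"],
            pe$deviance[pe$model == "control"])
  # per-condition rows exist for all 9 targets and partition the total
  pc <- rep$pe_condition[rep$pe_condition$model == "modified_hyperboloid", ]
  expect_equal(nrow(pc), 9)
  expect_equal(sum(pc$deviance * pc$n_trials) / sum(pc$n_trials),
               pe$deviance[pe$model == "modified_hyperboloid"])
})

test_that("best-model counting applies the tie tolerance multiply", {
  pe <- data.frame(participant = rep(c("p1", "p2"), each = 3),
                   model = rep(c("A", "B", "C"), 2),
                   deviance = c(0.50, 0.505, 0.60, 0.4, 0.6, 0.6))
  counts <- count_best_models(pe, tolerance = 0.01)
  expect_equal(counts[["A"]], 2L)
  expect_equal(counts[["B"]], 1L)
  expect_equal(counts[["C"]], 0L)
  expect_gte(sum(counts), length(unique(pe$participant)))
  all_tied <- data.frame(participant = "p", model = c("A", "B"),
                         deviance = c(0.3, 0.3))
  expect_equal(sum(count_best_models(all_tied)), 2L)
})

test_that("induction regression recovers exact linear relations", {
  targets <- seq(0.1, 0.9, 0.1)
  freq <- data.frame(participant = "p1", target_p = targets,
                     observed = targets)
  res <- suppressWarnings(induction_regression(freq))
  expect_equal(res$group$estimate, c(0, 1), tolerance = 1e-12)
  lin <- data.frame(participant = "p1", target_p = targets,
                    observed = 0.07 + 0.84 * targets)
  res2 <- suppressWarnings(induction_regression(lin))
  expect_equal(res2$group$estimate, c(0.07, 0.84), tolerance = 1e-12)
  expect_equal(res2$per_participant$slope, 0.84, tolerance = 1e-12)
  expect_error(induction_regression(
    data.frame(participant = "p", target_p = 0.5, observed = 0.5)),
    "3 distinct")
})

test_that("variance-ratio F-test reproduces analytic p-values", {
  x <- rnorm(20); y <- x
  expect_equal(homogeneity_ftest(x, y)$F, 1)
  # two-sided p for a known variance ratio and df
  set.seed(43)
  a <- rnorm(49); b <- rnorm(50)
  ft <- homogeneity_ftest(a, b)
  expect_equal(ft$df, c(48L, 49L))
  vt <- var.test(a, b)
  expect_equal(ft$p, vt$p.value, tolerance = 1e-12)
  # doubling one group's values quadruples the ratio
  ft2 <- homogeneity_ftest(2 * a, b)
  expect_equal(ft2$F, 4 * ft$F)
  expect_error(homogeneity_ftest(a, rep(1, 10)), "zero variance")
})

test_that("reliability screens scaled-MAD outliers before correlating", {
  set.seed(44)
  kappas <- seq(0.01, 0.1, length.out = 10)
  betas <- seq(0.1, 1, length.out = 10)
  ss <- seq(0.5, 1, length.out = 10)
  make_fit <- function(kappa, beta, s) {
    structure(list(params = mh_params(kappa, s, beta),
                   neg_log_lik = 1, n_params = 3,
                   model = "modified_hyperboloid"),
              class = "fit_result")
  }
  fa <- Map(make_fit, kappas, betas, ss)
  # run B replicates run A except one wild kappa outlier
  kb <- kappas; kb[10] <- 0.5
  fb <- Map(make_fit, kb, betas, ss)
  names(fa) <- names(fb) <- paste0("p", 1:10)
  rel <- reliability(fa, fb)
  expect_setequal(rel$quantity, c("beta", "kappa", "s", "discount_factor"))
  krow <- rel[rel$quantity == "kappa", ]
  expect_equal(krow$n_removed, 1)
  expect_equal(krow$r, 1, tolerance = 1e-9)
  # without removal the outlier depresses the correlation
  expect_lt(cor(kappas, kb), krow$r)
})
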