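test_that("discounted values match hand-evaluated cases", {
  p <- mh_params(kappa = 0.05, s = 1, beta = 0.3)
  expect_equal(discount_value(p, 50, 90), 50 / 5.5)
  expect_equal(discount_factor(p, 90), 1 / 5.5)
  # s = 1 collapses the hyperboloid family onto the hyperbolic model
  hb <- param_vector("hyperboloid", kappa = 0.05, s = 1, beta = 0.3)
  hy <- param_vector("hyperbolic", kappa = 0.05, beta = 0.3)
  expect_equal(discount_value(hb, 50, 90), 50 / 5.5)
  expect_equal(discount_value(hb, 50, 90), discount_value(hy, 50, 90))
  # zero discounting rate leaves the reward untouched at any delay
  p0 <- mh_params(kappa = 0, s = 0.5)
  expect_equal(discount_value(p0, 50, 365), 50)
  expect_equal(discount_factor(p0, 180), 1)
})

test_that("every zoo model satisfies the value-function laws", {
  set.seed(101)
  delays <- c(0, 1, 7, 30, 90, 180, 365)
  for (nm in model_names()) {
    spec <- model_spec(nm)
    for (rep in 1:5) {
      u <- runif(length(spec$param_names))
      vals <- spec$lower + u * (pmin(spec$upper, 5) - spec$lower)
      pv <- do.call(param_vector,
                    c(list(spec), as.list(setNames(vals, spec$param_names))))
      v <- discount_value(pv, 50, delays)
      expect_equal(v[1], 50, info = nm)                 # delay 0 = reward
      expect_true(all(diff(v) <= 1e-12), info = nm)     # non-increasing
      expect_true(all(v >= 0 & v <= 50 + 1e-12), info = nm)
      # degree-1 homogeneity in reward
      expect_equal(discount_value(pv, 3 * 17, 90),
                   3 * discount_value(pv, 17, 90), info = nm)
    }
  }
})

test_that("out-of-bounds parameters are rejected by name", {
  expect_error(param_vector("modified_hyperboloid",
                            kappa = -1, s = 0.5, beta = 0.3), "kappa")
  expect_error(param_vector("modified_hyperboloid",
                            kappa = 1, s = 2, beta = 0.3), "'s'")
  expect_error(param_vector("modified_hyperboloid",
                            kappa = 1, s = 0.5, beta = 5), "beta")
  expect_error(param_vector("control", kappa = 1, s = 0.5, beta = 1),
               "unknown parameter")
})

test_that("response model hits indifference, limits and symmetry", {
  expect_equal(p_immediate(0.7, 5, 5), 0.5)
  expect_equal(p_immediate(0.3, 10, 9), 1 / (1 + exp(-0.3)))
  expect_equal(p_immediate(1, 0, 1e6), 0, tolerance = 1e-12)
  expect_error(p_immediate(0, 1, 2), "beta")
  set.seed(7)
  for (i in 1:20) {
    a <- runif(1, 0, 100); b <- runif(1, 0, 100); bet <- runif(1, 0.01, 2)
    expect_equal(p_immediate(bet, a, b) + p_immediate(bet, b, a), 1)
  }
})

test_that("log-likelihood sums per-trial log choice probabilities", {
  p <- mh_params(kappa = 0, s = 1, beta = 0.5)
  # kappa = 0: v_del = r_del, so r_imm = r_del puts trials at indifference
  ind <- data.frame(r_imm = 10, r_del = 10, delay_days = 30,
                    choice = rep(c(0, 1), 5))
  expect_equal(log_likelihood(p, ind), 10 * log(0.5))
  # two trials with value difference -1 at beta = 0.3, choices (imm, del)
  p2 <- mh_params(kappa = 0, s = 1, beta = 0.3)
  d2 <- data.frame(r_imm = c(10, 10), r_del = c(9, 9),
                   delay_days = 0, choice = c(1, 0))
  pi <- 1 / (1 + exp(-0.3))
  expect_equal(log_likelihood(p2, d2), log(pi) + log(1 - pi))
  expect_error(log_likelihood(p, ind[0, ]), "empty")
})

test_that("likelihood over a beta grid peaks at the generating beta", {
  p <- mh_params(kappa = 0.02, s = 0.9, beta = 0.4)
  trials <- generate_run_b(p)
  d <- simulate_choices(agent_spec(p, 99),
                        trials[rep(seq_len(nrow(trials)), 45), ])  # T ~ 1e4
  betas <- seq(0.1, 1.2, by = 0.05)
  ll <- vapply(betas, function(b)
    log_likelihood(mh_params(kappa = 0.02, s = 0.9, beta = b), d),
    numeric(1))
  expect_lt(abs(betas[which.max(ll)] - 0.4), 0.1)
})
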