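test_that("reward inversion matches hand evaluation and round-trips", {
  p <- mh_params(kappa = 0.05, s = 1, beta = 0.3)
  # p = 0.5: the log-odds term vanishes
  expect_equal(solve_immediate_reward(p, 50, 90, 0.5), 50 / 5.5)
  expect_equal(solve_immediate_reward(p, 50, 90, 0.7),
               50 / 5.5 + log(0.7 / 0.3) / 0.3)
  expect_error(solve_immediate_reward(p, 50, 90, 1), "0 < p < 1")
  set.seed(31)
  for (i in 1:1000) {
    pv <- mh_params(kappa = exp(runif(1, log(1e-3), log(1))),
                    s = runif(1, 0.1, 1), beta = runif(1, 0.05, 2))
    r_del <- runif(1, 5, 100); D <- sample(1:365, 1)
    tp <- runif(1, 0.05, 0.95)
    r_imm <- solve_immediate_reward(pv, r_del, D, tp)
    back <- p_immediate(pv$beta, r_imm, discount_value(pv, r_del, D))
    expect_lt(abs(back - tp), 1e-10)
  }
})

test_that("clamping obeys the penny rules and flags adjustments", {
  # steep discounter at a long delay: low targets need negative rewards
  p <- mh_params(kappa = 1000, s = 1, beta = 2)
  cl <- apply_clamping(-3.2, 50, 365, p, 0.1)
  expect_true(cl$adjusted)
  expect_gte(cl$r_imm, 0.01)
  expect_lte(cl$r_imm, 49.99)
  # no discounting: r_imm = r_del resolves to the penny reduction
  p0 <- mh_params(kappa = 0, s = 1, beta = 0.3)
  cl0 <- apply_clamping(50, 50, 90, p0, 0.5)
  expect_equal(cl0$r_imm, 49.99)
  expect_true(cl0$adjusted)
  # valid input passes through untouched
  cl1 <- apply_clamping(20, 50, 90, p, 0.5)
  expect_identical(cl1, list(r_imm = 20, delay = 90, adjusted = FALSE))
})

test_that("delay adjustment stays inside [1, 365] and re-solves the target", {
  # moderately steep: some low targets at short delays are rescued by a
  # shorter delay rather than the penny rule
  p <- mh_params(kappa = 0.3, s = 1, beta = 0.1)
  rb <- generate_run_b(p)
  expect_true(all(rb$delay_days >= 1 & rb$delay_days <= 365))
  expect_true(all(rb$r_imm >= 0.01 - 1e-9))
  expect_true(all(rb$r_imm <= rb$r_del - 0.01 + 1e-9))
  # any trial whose delay changed but reward was not penny-clamped still
  # induces its target exactly
  moved <- rb$adjusted & rb$r_imm > 0.011 & rb$r_imm < rb$r_del - 0.011
  expect_true(all(abs(rb$predicted_p[moved] - rb$target_p[moved]) < 1e-9))
})

test_that("run A has the full factorial layout at indifference", {
  ra <- generate_run_a()
  expect_equal(nrow(ra), 100)
  expect_equal(sort(unique(ra$delay_days)), c(7, 30, 90, 180, 365))
  expect_equal(sort(unique(ra$r_del)), c(5, 10, 20, 50, 100))
  expect_equal(length(unique(ra$rep_param_set)), 4)
  # spot value: kappa = 0.05, s = 1 at D = 90, r_del = 50
  row <- ra[ra$rep_param_set == 3 & ra$delay_days == 90 & ra$r_del == 50, ]
  expect_equal(row$r_imm, 50 / 5.5, tolerance = 1e-12)
  # zero-discounting representatives would tie the two rewards; the grid
  # generator must penny-reduce them
  g0 <- design_grid(representative_params = list(c(kappa = 0, s = 1)))
  ra0 <- generate_run_a(g0)
  expect_equal(nrow(ra0), 25)
  expect_true(all(ra0$r_imm == ra0$r_del - 0.01))
  expect_true(all(ra0$adjusted))
})

test_that("run B covers 9 target levels with 25 trials each", {
  p <- mh_params(kappa = 0.01, s = 0.8, beta = 0.3)
  rb <- generate_run_b(p)
  expect_equal(nrow(rb), 225)
  expect_equal(as.vector(table(rb$target_p)), rep(25L, 9))
  # unadjusted trials always hit their targets
  expect_true(all(abs(rb$predicted_p[!rb$adjusted] -
                        rb$target_p[!rb$adjusted]) < 1e-9))
  # a sensitive agent whose discount factors stay well inside (0, 1)
  # across the delay range needs no clamping at all
  pc <- mh_params(kappa = 0.3, s = 0.3, beta = 2)
  rbc <- generate_run_b(pc)
  expect_equal(sum(rbc$adjusted), 0)
  expect_true(all(abs(rbc$predicted_p - rbc$target_p) < 1e-9))
  # extreme discounter: clamping kicks in but bounds always hold
  pex <- mh_params(kappa = 1000, s = 1, beta = 2)
  rbex <- generate_run_b(pex)
  expect_gt(sum(rbex$adjusted), 0)
  expect_true(all(rbex$r_imm >= 0.01 - 1e-9 &
                    rbex$r_imm <= rbex$r_del - 0.01 + 1e-9))
})
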