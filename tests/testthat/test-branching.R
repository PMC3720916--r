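test_that("constant-P1 pmf matches brute-force lineage-tree enumeration", {
  # frozen values from the enumeration oracle at p = 0.5: 0.5, 0.125, 0.0625
  f <- pmf_constant(0.5, 3)
  expect_equal(f, c(0.5, 0.125, 0.0625))
  for (p in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    expect_equal(pmf_constant(p, 7),
                 oracle_pmf(7, function(g) p), tolerance = 1e-12)
  }
})

test_that("immediate death forces a 1-cell colony", {
  expect_equal(pmf_constant(1, 5), c(1, 0, 0, 0, 0))
  expect_equal(pmf_schedule(p1_schedule(1), 4), c(1, 0, 0, 0))
})

test_that("death probabilities outside [0,1] are rejected", {
  expect_error(pmf_constant(-0.1, 5), "\\[0, 1\\]")
  expect_error(pmf_constant(1.2, 5), "\\[0, 1\\]")
  expect_error(p1_schedule(numeric(0)), "empty")
  expect_error(p1_schedule(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("schedule pmf reproduces hand-computed generation-dependent values", {
  # two 3-leaf trees under P1 = (0.2, 0.4, 0.5): 0.8 * 2 * 0.4 * (0.6 * 0.25)
  f <- pmf_schedule(p1_schedule(c(0.2, 0.4, 0.5), g_max = 2), 3)
  expect_equal(f, c(0.2, 0.128, 0.096))
})

test_that("schedule pmf agrees with the enumeration oracle on random schedules", {
  set.seed(401)
  for (rep in 1:8) {
    probs <- runif(6, 0.05, 0.8)
    sch <- p1_schedule(probs, g_max = 5)
    expect_equal(pmf_schedule(sch, 7), oracle_pmf(7, schedule_fun(probs)),
                 tolerance = 1e-10)
  }
})

test_that("constant schedules collapse to the Catalan closed form", {
  for (p in seq(0.1, 0.9, by = 0.1)) {
    sch <- p1_schedule(p, g_max = 16)
    expect_equal(pmf_schedule(sch, 10), pmf_constant(p, 10), tolerance = 1e-9)
  }
})

test_that("truncated-horizon pmf loses exactly the still-proliferative mass", {
  sch <- p1_schedule(0.5, g_max = 6)
  f_tr <- pmf_schedule(sch, 12, tail = "truncate")
  f_full <- pmf_constant(0.5, 12)
  expect_true(all(f_tr <= f_full + 1e-12))
  # sizes reachable only by shallow trees are unaffected: n = 1, 2 need
  # depth <= 1, 2 << horizon
  expect_equal(f_tr[1:2], f_full[1:2], tolerance = 1e-12)
  # the truncated total never exceeds the extinction probability
  expect_lt(sum(f_tr), 1)
})

test_that("total abortive mass plus survivor mass is a probability", {
  set.seed(402)
  for (rep in 1:10) {
    probs <- runif(8, 0, 1)
    sch <- p1_schedule(probs, g_max = 7)
    f <- pmf_schedule(sch, 60)
    expect_true(all(f >= 0))
    expect_lte(sum(f) + survivor_mass(sch), 1 + 1e-9)
  }
})

test_that("survivor mass matches the Galton-Watson extinction closed form", {
  expect_equal(survivor_mass(p1_schedule(1)), 0)
  expect_equal(survivor_mass(p1_schedule(0)), 1)
  # subcritical proliferation: extinction certain
  expect_lt(survivor_mass(p1_schedule(0.6, g_max = 30)), 1e-3)
  # supercritical: survivor mass = 1 - p/(1-p)
  expect_equal(survivor_mass(p1_schedule(0.25)), 1 - 1 / 3, tolerance = 1e-12)
})

test_that("abortive mass converges to min(1, p/(1-p)) at a deep horizon", {
  for (p in c(0.4, 0.5, 0.6)) {
    f <- pmf_schedule(p1_schedule(p, g_max = 30), 1e6)
    expect_equal(sum(f), min(1, p / (1 - p)), tolerance = 1e-3)
  }
})

test_that("1-cell frequency inversion from the 2-cell class solves the cubic", {
  expect_equal(estimate_f1_from_f2(0)$f1, 0)
  est <- estimate_f1_from_f2(0.125)
  expect_equal(est$p, 0.5, tolerance = 1e-9)
  expect_equal(est$f1, est$p)
  # the two roots bracket the maximizer and are both reported
  expect_equal(length(est$roots), 2L)
  expect_lt(est$roots[1], 2 / 3)
  expect_gt(est$roots[2], 2 / 3)
  expect_equal((1 - est$roots[2]) * est$roots[2]^2, 0.125, tolerance = 1e-9)
  # at the maximum of (1-p)p^2 both roots coincide at 2/3
  expect_equal(estimate_f1_from_f2(4 / 27)$p, 2 / 3, tolerance = 1e-9)
  expect_equal(estimate_f1_from_f2(0.125, hint = "larger")$p, est$roots[2])
  expect_error(estimate_f1_from_f2(0.16), "no root")
  expect_error(estimate_f1_from_f2(-0.01), "non-negative")
})

test_that("mock examination: log-frequency is linear with a steep 1-to-2-cell drop", {
  for (p in seq(0.3, 0.7, by = 0.1)) {
    f <- pmf_constant(p, 15)
    d <- colony_size_distribution("mock", 1:15, 100 * f)
    fit_tail <- fit_size_distribution(
      colony_size_distribution("mock", 2:15, 100 * f[-1]), "log_linear")
    # near-linear for mid-range P1; weakest at the critical p = 0.5, where
    # the size law is the pure power n^(-3/2)
    expect_gte(fit_tail$r2, 0.92)
    # the n >= 2 line extrapolated back to n = 1 underestimates f1
    expect_gt(f[1], predict(fit_tail, 1) / 100)
    # on log-log axes the 1-cell point falls in line; log-linear axes it does not
    r2_loglog <- fit_size_distribution(d, "log_log")$r2
    r2_loglin <- fit_size_distribution(d, "log_linear")$r2
    expect_gt(r2_loglog, r2_loglin)
  }
})
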