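test_that("pmf matches closed forms for P(0) and the full-plating recursion", {
  # P(0) closed forms
  expect_equal(lc_pmf(1, 1, 0), exp(-1), tolerance = 1e-12)
  expect_equal(lc_pmf(1, 0.5, 0), 0.5, tolerance = 1e-9)
  for (m in c(0.3, 1, 2.7)) {
    for (eps in c(0.1, 0.37, 0.5, 0.8, 1)) {
      p0 <- if (eps == 1) exp(-m) else exp(m * eps * log(eps) / (1 - eps))
      expect_equal(lc_pmf(m, eps, 0), p0, tolerance = 1e-9)
    }
  }
  # full-plating values: P(1) = m/2 * e^-m
  p <- lc_pmf(1, 1, 5)
  expect_equal(p[1], exp(-1), tolerance = 1e-12)
  expect_equal(p[2], exp(-1) / 2, tolerance = 1e-12)
  # no mutations: all mass at zero
  expect_equal(lc_pmf(0, 0.7, 4), c(1, 0, 0, 0, 0))
})

test_that("pmf agrees with the contour-integral oracle and is a proper pmf", {
  cases <- expand.grid(m = c(0.5, 1, 2), eps = c(0.2, 0.5, 0.9, 1))
  for (i in seq_len(nrow(cases))) {
    m <- cases$m[i]
    eps <- cases$eps[i]
    p <- lc_pmf(m, eps, 120)
    expect_true(all(p >= 0))
    expect_lte(sum(p), 1 + 1e-12)
    expect_equal(p, oracle_lc_pmf(m, eps, 120), tolerance = 1e-9)
  }
  # normalization: partial sums approach 1 as k_max grows
  expect_gt(sum(lc_pmf(1, 1, 5000)), 0.999)
  expect_gt(sum(lc_pmf(1, 0.3, 5000)), 0.999)
})

test_that("pmf rejects invalid domains", {
  expect_error(lc_pmf(-1, 0.5, 10), "non-negative")
  expect_error(lc_pmf(1, 0, 10), "epsilon")
  expect_error(lc_pmf(1, 1.2, 10), "epsilon")
})

test_that("experiment constructor enforces its invariants", {
  expect_error(fluctuation_experiment(c(0, 1), n_total_cells = -1), "Nt")
  expect_error(fluctuation_experiment(c(0, 1), 1e8, plating_fraction = 0),
               "epsilon")
  expect_error(fluctuation_experiment(c(0, 1.5), 1e8), "integer")
  expect_error(fluctuation_experiment(c(5, 1), 1e8,
                                      censored_high = c(TRUE, FALSE)),
               "censored")
  # all cultures censored under exclusion -> nothing usable
  expect_error(fluctuation_experiment(c(NA, NA), 1e8,
                                      censored_high = c(TRUE, TRUE)),
               "usable")
  e <- fluctuation_experiment(c(0, NA, 3), 1e8,
                              censored_high = c(FALSE, TRUE, FALSE))
  expect_equal(e$counts, c(0L, 3L))
  expect_equal(e$n_censored, 1L)
})

test_that("log-likelihood equals the sum of per-culture log pmf values", {
  e <- fluctuation_experiment(c(0, 0, 0), 1e8, 0.6)
  expect_equal(lc_loglik(0, e), 0)
  e1 <- fluctuation_experiment(0, 1e8, 1)
  expect_equal(lc_loglik(1, e1), -1, tolerance = 1e-12)
  e2 <- fluctuation_experiment(c(0, 2, 1, 0), 1e8, 0.4)
  expect_equal(lc_loglik(0.8, e2), oracle_loglik(0.8, c(0, 2, 1, 0), 0.4),
               tolerance = 1e-9)
  # censored cultures contribute the upper tail beyond the ceiling
  ec <- fluctuation_experiment(c(1, NA), 1e8, 1,
                               censored_high = c(FALSE, TRUE),
                               censor_mode = "ceiling", ceiling = 4)
  p <- lc_pmf(0.9, 1, 3)
  expect_equal(lc_loglik(0.9, ec), log(p[2]) + log(1 - sum(p)),
               tolerance = 1e-9)
})

test_that("MLE matches the grid-search oracle and handles the zero boundary", {
  # boundary: all-zero counts
  e0 <- fluctuation_experiment(rep(0, 10), 1e8, 0.5)
  f0 <- estimate_rate(e0)
  expect_equal(f0$m_hat, 0)
  expect_equal(f0$ci95_m[1], 0)
  expect_gt(f0$ci95_m[2], 0)
  # the upper limit satisfies the deviance equation at the boundary
  expect_equal(2 * (0 - lc_loglik(f0$ci95_m[2], e0)), qchisq(0.95, 1),
               tolerance = 1e-6)

  fixtures <- list(
    list(counts = c(0, 0, 1), eps = 1),
    list(counts = c(3, 0, 1, 0, 2), eps = 0.7),
    list(counts = c(0, 5, 2, 0, 0, 1, 9), eps = 0.4)
  )
  for (fx in fixtures) {
    e <- fluctuation_experiment(fx$counts, 1e8, fx$eps)
    f <- estimate_rate(e)
    expect_equal(f$m_hat, oracle_grid_mle(fx$counts, fx$eps),
                 tolerance = 1e-4)
    expect_equal(f$mu_hat, f$m_hat / 1e8)
    expect_true(f$ci95_m[1] <= f$m_hat && f$m_hat <= f$ci95_m[2])
    # profile limits sit on the deviance cutoff
    for (b in f$ci95_m) {
      expect_equal(2 * (f$loglik_at_mle - lc_loglik(b, e)), qchisq(0.95, 1),
                   tolerance = 1e-5)
    }
  }
})

test_that("rate comparison of an experiment with itself is exactly null", {
  e <- fluctuation_experiment(c(0, 3, 1, 0, 7, 2), 1e8, 0.8)
  cmp <- compare_rates(e, e)
  expect_identical(cmp$ratio, 1)
  expect_identical(cmp$lrt_statistic, 0)
  expect_identical(cmp$p_value, 1)
  expect_true(cmp$ci95_ratio[1] < 1 && 1 < cmp$ci95_ratio[2])
})

test_that("rate comparison detects a real rate difference", {
  set.seed(5150)
  base <- list(Nt = 1e8, epsilon = 1, n_cultures = 40, gene_weights = c(g = 1))
  a <- simulate_fluctuation_experiment(
    c(base, list(mu = 4e-8, seed = 91)))
  b <- simulate_fluctuation_experiment(
    c(base, list(mu = 0.5e-8, seed = 92)))
  cmp <- compare_rates(a$experiment, b$experiment)
  expect_lt(cmp$p_value, 0.001)
  expect_gt(cmp$ratio, 1)
  expect_true(cmp$ci95_ratio[1] > 1)
})
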