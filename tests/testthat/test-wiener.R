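# Wiener first-passage machinery: closed-form oracles, density series,
# likelihood, and the Euler first-passage simulator.

test_that("choice probability matches the gambler's-ruin closed form", {
  # driftless symmetric start
  expect_equal(choice_probability(2, 0.5, 0), 0.5, tolerance = 1e-12)
  expect_equal(choice_probability(0.7, 0.5, 0), 0.5, tolerance = 1e-12)
  # closed form 1/(1 + exp(-alpha*delta)) at beta = 0.5
  expect_equal(choice_probability(2, 0.5, 1), 1 / (1 + exp(-2)),
               tolerance = 1e-10)
  # general-beta closed form
  p_lower <- function(a, b, d) (exp(-2 * d * a * b) - exp(-2 * d * a)) /
    (1 - exp(-2 * d * a))
  for (a in c(1, 2)) for (b in c(0.3, 0.7)) for (d in c(-1.5, 0.8))
    expect_equal(choice_probability(a, b, d), 1 - p_lower(a, b, d),
                 tolerance = 1e-10)
  # reflection symmetry at beta = 0.5
  for (d in c(0.2, 1, 3))
    expect_equal(choice_probability(2, 0.5, d),
                 1 - choice_probability(2, 0.5, -d), tolerance = 1e-12)
  # continuity at delta -> 0: limit equals beta
  expect_equal(choice_probability(2, 0.3, 1e-12), 0.3, tolerance = 1e-9)
  expect_error(choice_probability(2, 0.5, NaN), "finite")
  expect_error(choice_probability(-1, 0.5, 1), "alpha")
})

test_that("mean decision time matches closed forms and is monotone in |drift|", {
  expect_equal(mean_decision_time(2, 0.5, 0), 1, tolerance = 1e-10)
  expect_equal(mean_decision_time(1, 0.5, 2), 0.25 * tanh(1),
               tolerance = 1e-10)
  # driftless closed form z*(alpha - z)
  expect_equal(mean_decision_time(1.5, 0.4, 0), (0.4 * 1.5) * (1.5 - 0.4 * 1.5),
               tolerance = 1e-10)
  # continuity across the small-drift series switch (|2*delta*alpha| = 1e-5)
  expect_equal(mean_decision_time(2, 0.4, 2.4e-6),
               mean_decision_time(2, 0.4, 2.6e-6), tolerance = 1e-6)
  # strictly decreasing in |delta| for fixed alpha, beta = 0.5
  mdts <- vapply(c(0, 0.5, 1, 2, 4), function(d) mean_decision_time(2, 0.5, d),
                 numeric(1))
  expect_true(all(diff(mdts) < 0))
  expect_error(mean_decision_time(2, 0.5, Inf), "finite")
})

test_that("first-passage densities vanish before tau and integrate to one", {
  expect_identical(dwiener(0.3, 2, 0.5, 1, 0.3), 0)
  expect_identical(dwiener(0.1, 2, 0.5, 1, 0.3), 0)
  expect_true(all(dwiener(seq(0.31, 3, by = 0.01), 2, 0.5, 1, 0.3) >= 0))
  # total absorption probability is 1 over a 3x3 grid, both boundaries
  for (a in c(1, 1.5, 2)) for (d in c(0.5, 1.5, 2.5)) {
    total <- integrate(function(t)
      dwiener(t, a, 0.5, d, 0.3, "upper") + dwiener(t, a, 0.5, d, 0.3, "lower"),
      0.3, Inf, rel.tol = 1e-9)$value
    expect_equal(total, 1, tolerance = 1e-6)
  }
  # each boundary integrates to its absorption probability
  up <- integrate(function(t) dwiener(t, 2, 0.5, 1, 0, "upper"),
                  0, Inf, rel.tol = 1e-9)$value
  expect_equal(up, choice_probability(2, 0.5, 1), tolerance = 1e-6)
})

test_that("small-time and large-time series agree at the switch point", {
  # scan each (alpha, delta) for the automatic switch and compare forced
  # expansions there and on either side
  for (a in c(0.8, 1.5, 2.5)) for (d in c(0.3, 1, 2.5)) {
    ts <- seq(0.01, 6, by = 0.01)
    small <- dwiener(ts, a, 0.5, d, 0, "upper", expansion = "small")
    large <- dwiener(ts, a, 0.5, d, 0, "upper", expansion = "large")
    expect_lt(max(abs(small - large)), 1e-9)
  }
})

test_that("log-likelihood is the sum of log densities with documented edges", {
  expect_identical(wiener_loglik(numeric(0), character(0), 2, 0.5, 1, 0.3), 0)
  expect_equal(wiener_loglik(0.8, "upper", 2, 0.5, 1, 0.3),
               log(dwiener(0.8, 2, 0.5, 1, 0.3, "upper")))
  expect_identical(wiener_loglik(0.2, "upper", 2, 0.5, 1, 0.3), -Inf)
  # likelihood peaks near the generating drift on average
  set.seed(7)
  wins <- vapply(1:50, function(i) {
    sim <- rwiener(100, 2, 0.5, 1, 0.3, seed = 1000 + i)
    ll <- function(d) wiener_loglik(sim$rt, sim$boundary, 2, 0.5, d, 0.3)
    ll(1) > ll(0) && ll(1) > ll(2)
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("simulator is seed-deterministic and matches analytic moments", {
  s1 <- rwiener(500, 2, 0.5, 1, 0.3, seed = 99)
  s2 <- rwiener(500, 2, 0.5, 1, 0.3, seed = 99)
  expect_identical(s1, s2)
  s3 <- rwiener(500, 2, 0.5, 1, 0.3, seed = 100)
  expect_false(identical(s1, s3))
  expect_error(rwiener(0, 2, 0.5, 1, 0.3), "count")

  # 3x3 grid of (alpha, delta): empirical choice fraction and mean RT match
  # the closed forms within Monte-Carlo error
  n <- 6000
  k <- 0
  for (a in c(1, 1.5, 2)) for (d in c(0.5, 1.5, 2.5)) {
    k <- k + 1
    sim <- rwiener(n, a, 0.5, d, 0.2, seed = 7000 + k)
    p <- choice_probability(a, 0.5, d)
    se_p <- sqrt(p * (1 - p) / n)
    expect_lt(abs(mean(sim$boundary == "upper") - p), 3.5 * se_p + 0.002)
    m <- 0.2 + mean_decision_time(a, 0.5, d)
    se_m <- sd(sim$rt) / sqrt(n)
    expect_lt(abs(mean(sim$rt) - m), 3.5 * se_m + 0.01 * m)
  }
})

test_that("simulated upper-boundary RTs follow the analytic conditional law", {
  sim <- cache_get("sim_1e5", rwiener(1e5, 2, 0.5, 1, 0.3, seed = 12345))
  rt_up <- sort(sim$rt[sim$boundary == "upper"])
  p_up <- choice_probability(2, 0.5, 1)
  # conditional CDF by cumulative trapezoid of the analytic density
  grid <- seq(0.3, max(rt_up) + 0.1, length.out = 4000)
  dens <- dwiener(grid, 2, 0.5, 1, 0.3, "upper")
  cdf <- cumsum(c(0, (dens[-1] + dens[-length(dens)]) / 2 * diff(grid))) / p_up
  Fhat <- approx(grid, pmin(cdf, 1), xout = rt_up, rule = 2)$y
  n <- length(rt_up)
  ks <- max(abs(seq_len(n) / n - Fhat), abs((seq_len(n) - 1) / n - Fhat))
  expect_lt(ks, 0.01)
})

test_that("drift-marginal density agrees with numerical integration", {
  d_marg <- wienerhdm:::dwiener_marginal(0.8, 2, 1.2, 0.5, 0.3, 0, "upper")
  d_num <- integrate(function(v)
    sapply(v, function(vi) dwiener(0.8, 2, 0.5, vi, 0.3, "upper")) *
      dnorm(v, 1.2, 0.5), -5, 7, rel.tol = 1e-12)$value
  expect_equal(d_marg, d_num, tolerance = 1e-9)
  # eta = 0 reduces to the plain density
  expect_equal(wienerhdm:::dwiener_marginal(0.8, 2, 1.2, 0, 0.3, 0, "lower"),
               dwiener(0.8, 2, 0.5, 1.2, 0.3, "lower"), tolerance = 1e-12)
  # Gauss-Hermite nondecision integral close to a dense numerical one
  gh7 <- wienerhdm:::dwiener_marginal(0.8, 2, 1.2, 0.5, 0.45, 0.05, "upper",
                                      gh_points = 7)
  num <- integrate(function(tt)
    sapply(tt, function(ti)
      wienerhdm:::dwiener_marginal(0.8, 2, 1.2, 0.5, ti, 0, "upper")) *
      dnorm(tt, 0.45, 0.05), 0.2, 0.7, rel.tol = 1e-10)$value
  expect_equal(gh7, num, tolerance = 1e-3)
})
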