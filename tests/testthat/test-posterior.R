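# Posterior readouts: contrasts arithmetic on controlled draws, HDI
# consistency, the posterior-predictive quantile check.

test_that("condition summary reproduces constant draws exactly", {
  fit <- fake_fit(drift = list("scrambled:positive" = 2.65),
                  ndt = list("happy:negative" = 0.49))
  tab <- condition_summary(fit)
  expect_equal(nrow(tab), 8)
  expect_equal(tab$face, rep(napt_conditions()$face, length.out = 8))
  r1 <- tab[tab$label == "scrambled:positive", ]
  expect_equal(r1$drift_mean, 2.65)
  expect_equal(c(r1$drift_lo, r1$drift_hi), c(2.65, 2.65))
  r2 <- tab[tab$label == "happy:negative", ]
  expect_equal(r2$ndt_mean, 0.49)
  # the convergence gate refuses unconverged fits unless overridden
  fit$rhat[3] <- 1.5
  expect_error(condition_summary(fit), "convergence gate")
  expect_silent(condition_summary(fit, check_rhat = FALSE))
})

test_that("valence differences have the documented sign and symmetry", {
  fit <- fake_fit(drift = list("scrambled:positive" = 2.65,
                               "scrambled:negative" = 2.40))
  vd <- valence_difference(fit, "scrambled", "drift")
  expect_equal(vd$mean, 2.40 - 2.65)      # negative minus positive
  expect_true(vd$significant)
  # identical draws -> zero contrast, [0, 0], not significant
  vd0 <- valence_difference(fit, "angry", "drift")
  expect_equal(vd0$mean, 0)
  expect_equal(vd0$hdi, c(0, 0))
  expect_false(vd0$significant)
  expect_error(valence_difference(fit, "smiling", "drift"), "face")
  # antisymmetry draw-by-draw against the pairwise difference
  pw_ab <- pairwise_difference(fit, c("scrambled", "negative"),
                               c("scrambled", "positive"), "drift")
  pw_ba <- pairwise_difference(fit, c("scrambled", "positive"),
                               c("scrambled", "negative"), "drift")
  expect_equal(pw_ab$draws, -pw_ba$draws)
  expect_equal(vd$draws, pw_ab$draws)
})

test_that("identity contrast equals its defining linear combination", {
  fit <- fake_fit(drift = list(
    "scrambled:positive" = 2.65, "scrambled:negative" = 2.40,
    "neutral:positive" = 2.5, "neutral:negative" = 2.6,
    "happy:positive" = 2.5, "happy:negative" = 2.6,
    "angry:positive" = 2.5, "angry:negative" = 2.6))
  ic <- identity_contrast(fit)
  expect_equal(ic$mean, 0.25 - (-0.1))    # 0.35
  expect_true(ic$significant)
  # all equal -> exactly zero
  ic0 <- identity_contrast(fake_fit())
  expect_equal(ic0$mean, 0)
  expect_false(ic0$significant)
  # linearity against valence_difference outputs, draw by draw
  sf <- small_fit()
  ic2 <- identity_contrast(sf$fit)
  vd <- lapply(c("scrambled", "angry", "neutral", "happy"), function(f)
    valence_difference(sf$fit, f, "drift")$draws)
  recon <- -vd[[1]] + (vd[[2]] + vd[[3]] + vd[[4]]) / 3
  expect_equal(ic2$draws, recon)
  # significance flag always equals the HDI-excludes-zero rule
  h <- hdi(ic2$draws)
  expect_identical(ic2$significant, h[1] > 0 || h[2] < 0)
})

test_that("pairwise differences cover arbitrary cells", {
  fit <- fake_fit(ndt = list("happy:negative" = 0.49,
                             "angry:negative" = 0.47))
  pw <- pairwise_difference(fit, c("happy", "negative"),
                            c("angry", "negative"), "nondecision")
  expect_equal(pw$mean, 0.02)
  expect_warning(
    pairwise_difference(fit, c("happy", "negative"), c("happy", "negative")),
    "identical")
  # full sweep over all condition pairs runs clean on a real fit
  sf <- small_fit()
  cells <- split(napt_conditions()[, c("face", "valence")], 1:8)
  for (i in 1:7) for (j in (i + 1):8) {
    res <- pairwise_difference(sf$fit, unlist(cells[[i]]), unlist(cells[[j]]),
                               "drift")
    expect_true(is.finite(res$mean))
  }
})

test_that("posterior-predictive quantiles track the generating process", {
  # data simulated from fixed known parameters, checked against a posterior
  # concentrated at those parameters: near-perfect quantile agreement
  tr <- napt_truth(2, "null", sigma_nu = 0, sigma_theta = 0, sigma_alpha = 0,
                   eta = 0, chi = 0, seed = 19)
  des <- napt_design(2, trials_per_condition = 120, seed = 19)
  dat <- simulate_napt(tr, des, napt_nuisance(0, 0, 0, 0), seed = 19)
  labels <- napt_conditions()$label
  P <- 2
  par_names <- wienerhdm:::hdm_par_names(1:2, labels)
  draws <- array(0, dim = c(2, 30, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  draws[, , 1:8] <- 2.6; draws[, , 9:16] <- 0.46
  draws[, , "mu_alpha"] <- 2; draws[, , "sigma_alpha"] <- 0.01
  draws[, , "eta"] <- 1e-6; draws[, , "chi"] <- 1e-6
  for (p in 1:2) {
    draws[, , paste0("alpha[", p, "]")] <- 2
    for (l in labels) {
      draws[, , paste0("nu[", p, ",", l, "]")] <- 2.6
      draws[, , paste0("theta[", p, ",", l, "]")] <- 0.46
    }
  }
  fit <- structure(list(draws = draws, par_names = par_names,
                        participants = 1:2, conditions = napt_conditions(),
                        model = build_hdm(dat),
                        config = hdm_config(chains = 2, burn_in = 10,
                                            draws = 30),
                        rhat = setNames(rep(1, length(par_names)), par_names)),
                   class = "hdm")
  ppc <- ppc_quantile_check(fit, dat, n_draws = 10, seed = 2)
  expect_true(all(ppc$r > 0.99))
  # degenerate constant empirical quantiles raise an explicit error
  dat2 <- dat
  dat2$rt_ms[dat2$face_prime == "happy" & dat2$word_valence == "negative"] <- 900
  expect_error(ppc_quantile_check(fit, dat2, n_draws = 5, seed = 2),
               "constant")
})

test_that("a fitted model reproduces its own data's RT quantiles", {
  sf <- small_fit()
  ppc <- ppc_quantile_check(sf$fit, sf$study$data, n_draws = 15, seed = 3)
  expect_true(all(ppc$r >= 0.9))
  expect_equal(nrow(ppc), 8)
})
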