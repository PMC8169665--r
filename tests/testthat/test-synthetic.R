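# Synthetic-data generator: design counts, truth hierarchy, trial
# simulation, nuisance injection.

test_that("design skeleton reproduces the study's trial counts", {
  d <- napt_design(1, seed = 1)
  expect_equal(nrow(d), 320)
  expect_true(all(table(d$face_prime, d$word_valence) == 40))
  expect_true(all(table(d$block) == 80))
  # each block balanced across the 8 conditions
  expect_true(all(table(d$block, paste(d$face_prime, d$word_valence)) == 10))
  # two participants double everything
  d2 <- napt_design(2, seed = 1)
  expect_equal(nrow(d2), 640)
  # determinism
  expect_identical(napt_design(2, seed = 3), napt_design(2, seed = 3))
  # unbalanceable specs are refused
  expect_error(napt_design(1, trials_per_condition = 30, n_blocks = 4),
               "balance")
})

test_that("truth tables honour the hierarchy and its degenerate limits", {
  tr <- napt_truth(6, "paper", seed = 2)
  expect_true(all(tr$alpha > 0))
  expect_true(all(tr$theta >= 0))
  expect_identical(napt_truth(6, "paper", seed = 2),
                   napt_truth(6, "paper", seed = 2))
  # zero spreads: every participant identical to the group means
  tr0 <- napt_truth(5, "null", sigma_nu = 0, sigma_theta = 0,
                    sigma_alpha = 0, seed = 3)
  expect_true(all(tr0$alpha == 2))
  expect_true(all(apply(tr0$nu, 2, function(x) length(unique(x))) == 1))
  expect_equal(unname(tr0$nu[1, ]), unname(tr0$mu_nu))
  expect_error(napt_truth(4, sigma_nu = -1), "spread")
  # pattern scenario plants exactly the advertised effects
  trp <- napt_truth(4, "pattern", seed = 1)
  expect_equal(unname(trp$mu_nu["scrambled:positive"] -
                        trp$mu_nu["scrambled:negative"]), 0.4)
  expect_equal(unname(trp$mu_theta["happy:negative"] -
                        trp$mu_theta["happy:positive"]), 0.03)
  expect_equal(unname(trp$mu_theta["angry:negative"] -
                        trp$mu_theta["angry:positive"]), 0)
})

test_that("simulated trials follow the diffusion truth and nuisance config", {
  # zero nuisance: no aware trials, no unknown words, all ratings 3-4
  study <- simulate_napt_study(2, "null", nuisance = napt_nuisance(0, 0, 0, 0),
                               seed = 4)
  expect_true(all(study$data$aware == 0))
  expect_true(all(study$data$knowledge_rating >= 3))
  expect_true(all(study$data$meaning_reversed == 0))
  inj <- attr(study$data, "injected")
  expect_equal(inj$aware, 0)
  expect_equal(inj$contaminant, 0)

  # contaminant count ~ Binomial(n, rate)
  set.seed(9)
  des <- napt_design(2, seed = 9)
  tr <- napt_truth(2, "null", seed = 9)
  sim <- simulate_napt(tr, des, napt_nuisance(0, 0, 0, 0.05), seed = 9)
  n <- nrow(sim)
  inj <- attr(sim, "injected")
  expect_lt(abs(inj$contaminant - n * 0.05), 3 * sqrt(n * 0.05 * 0.95) + 1)
  expect_equal(sum(sim$rt_ms < 200 | sim$rt_ms > 5000), inj$contaminant)

  # accuracy matches the analytic choice probability when eta = chi = 0
  tr0 <- napt_truth(2, "null", sigma_nu = 0, sigma_theta = 0, sigma_alpha = 0,
                    eta = 0, chi = 0, seed = 5)
  des0 <- napt_design(2, trials_per_condition = 1000, n_blocks = 4, seed = 5)
  sim0 <- simulate_napt(tr0, des0, napt_nuisance(0, 0, 0, 0), seed = 5)
  p <- choice_probability(2, 0.5, 2.6)
  acc <- tapply(sim0$choice, paste(sim0$face_prime, sim0$word_valence), mean)
  se <- sqrt(p * (1 - p) / 2000)
  expect_true(all(abs(acc - p) < 3.5 * se + 0.003))
})

test_that("cell mean RTs track the analytic moments across person-cells", {
  study <- cache_get("study_20p",
                     simulate_napt_study(20, "paper",
                                         nuisance = napt_nuisance(0, 0, 0, 0),
                                         seed = 11))
  tr <- study$truth
  d <- study$data
  ci <- wienerhdm:::condition_index(d$face_prime, d$word_valence)
  # analytic cell mean: theta + E[mean decision time] over the trial-level
  # drift distribution N(nu, eta^2) (Gauss-Hermite)
  gh <- wienerhdm:::gauss_hermite_normal(7)
  cell_pred <- function(p, i) {
    drifts <- tr$nu[p, i] + tr$eta * gh$x
    tr$theta[p, i] + sum(gh$w * vapply(drifts, function(v)
      mean_decision_time(tr$alpha[p], 0.5, v), numeric(1)))
  }
  # person-condition level: 40-trial cells carry ~0.045 s of sampling noise
  # against a ~0.09 s spread of true means, which bounds the attainable
  # correlation near 0.9; require agreement within that noise allowance
  emp_pc <- tapply(d$rt_ms / 1000, paste(d$participant_id, ci), mean)
  pred_pc <- vapply(names(emp_pc), function(k) {
    pi <- as.integer(strsplit(k, " ")[[1]])
    cell_pred(pi[1], pi[2])
  }, numeric(1))
  expect_gt(cor(emp_pc, pred_pc), 0.85)
  expect_lt(sd(emp_pc - pred_pc), 0.06)
  # with 4x the trials per cell the noise shrinks and the correlation
  # climbs well past 0.9 -- the shortfall above is sampling noise, not a
  # generator defect
  big <- simulate_napt_study(8, "paper", trials_per_condition = 160,
                             nuisance = napt_nuisance(0, 0, 0, 0), seed = 12)
  trb <- big$truth; db <- big$data
  cib <- wienerhdm:::condition_index(db$face_prime, db$word_valence)
  emp_b <- tapply(db$rt_ms / 1000, paste(db$participant_id, cib), mean)
  pred_b <- vapply(names(emp_b), function(k) {
    pi <- as.integer(strsplit(k, " ")[[1]])
    drifts <- trb$nu[pi[1], pi[2]] + trb$eta * gh$x
    trb$theta[pi[1], pi[2]] + sum(gh$w * vapply(drifts, function(v)
      mean_decision_time(trb$alpha[pi[1]], 0.5, v), numeric(1)))
  }, numeric(1))
  expect_gt(cor(emp_b, pred_b), 0.9)
})

test_that("meaning-reversed words are recoverable by the preprocessing recode", {
  # with only reversal nuisance, recoding restores accuracy-coded choices:
  # the recoded dataset should look like a clean one (high accuracy in the
  # internal condition)
  des <- napt_design(2, seed = 6)
  tr <- napt_truth(2, "null", seed = 6)
  sim <- simulate_napt(tr, des, napt_nuisance(0, 0, 0.5, 0), seed = 6)
  inj <- attr(sim, "injected")
  expect_gt(inj$reversed_word, 0)
  rec <- recode_word_knowledge(sim)
  expect_equal(rec$counts$recoded, sum(sim$meaning_reversed == 1))
  # raw reversed trials look inaccurate; after recode accuracy is uniform
  acc_raw <- mean(sim$choice[sim$meaning_reversed == 1])
  acc_rec <- mean(rec$data$choice)
  expect_lt(acc_raw, 0.2)   # reversed words recorded as errors
  expect_gt(acc_rec, 0.9)
})

test_that("written studies round-trip and record their truth", {
  study <- simulate_napt_study(2, "paper", trials_per_condition = 8,
                               nuisance = napt_nuisance(0, 0, 0, 0), seed = 8)
  dir <- tempfile("napt")
  paths <- write_napt(study, dir, seed = 8)
  expect_true(all(file.exists(paths)))
  back <- read.csv(paths["data"])
  expect_equal(nrow(back), nrow(study$data))
  expect_equal(back$rt_ms, study$data$rt_ms)
  side <- jsonlite::read_json(paths["truth_group"], simplifyVector = TRUE)
  expect_equal(unname(unlist(side$mu_nu)), unname(study$truth$mu_nu))
  expect_equal(side$seed, 8)
})
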