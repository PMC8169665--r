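# Exclusion cascade: individual filters, ordering, audit report,
# idempotence, row conservation.

test_that("aware-trial exclusion removes exactly the flagged trials", {
  tab <- make_trials(100, aware = c(rep(1, 3), rep(0, 97)))
  res <- exclude_aware_trials(tab)
  expect_equal(nrow(res$data), 97)
  expect_equal(res$excluded, 3)
  # zero aware: identity
  tab0 <- make_trials(10)
  expect_identical(exclude_aware_trials(tab0)$data, tab0)
  # all aware: empty table survives downstream with a warning record
  taba <- make_trials(10, aware = 1)
  resa <- exclude_aware_trials(taba)
  expect_equal(nrow(resa$data), 0)
  resp <- exclude_participants(resa$data)
  expect_equal(nrow(resp$data), 0)
  expect_true(length(resp$warnings) > 0)
  expect_error(exclude_aware_trials(make_trials(5)[, -8]), "aware")
})

test_that("participant exclusion applies the accuracy and trial-count rules", {
  # participant 1: 68.4%-style accuracy -> removed; participant 2: fine
  good <- make_full_table(participants = 2, per_cell = 40)
  bad <- make_full_table(participants = 1, per_cell = 40)
  bad$choice <- rep_len(c(rep(0L, 13), rep(1L, 27)), nrow(bad))  # 67.5%
  res <- exclude_participants(rbind(bad, good))
  expect_equal(res$participants$accuracy, 1)
  expect_equal(nrow(res$data), nrow(good))

  # 29 trials in one condition -> removed; exactly 30 everywhere -> retained
  t29 <- make_full_table(participants = 1, per_cell = 30)
  t29 <- t29[-1, ]  # one scrambled:positive trial short
  t30 <- make_full_table(participants = 2, per_cell = 30)
  t30$choice <- rep_len(c(0L, rep(1L, 19)), nrow(t30))  # 95% accuracy
  res2 <- exclude_participants(rbind(t29, t30))
  expect_equal(res2$participants$insufficient_trials, 1)
  expect_equal(sort(unique(res2$data$participant_id)), 2)
})

test_that("RT filters: strict absolute cutoffs, then per-person log-SD", {
  # absolute rule boundaries: 'faster than 200' and 'slower than 5000' are
  # strict, so 200 and 5000 exactly are retained
  tab <- make_trials(6, rt_ms = c(150, 200, 900, 5000, 5001, 950))
  res <- filter_rt_outliers(tab)
  expect_equal(res$counts$rt_absolute, 2)
  expect_true(all(c(200, 5000) %in% res$data$rt_ms))
  expect_false(any(c(150, 5001) %in% res$data$rt_ms))

  # log-SD fixture: 20 moderate RTs plus one far outlier; by construction
  # only the outlier is more than 2 SD from the mean of log RT
  base <- exp(seq(log(800), log(1100), length.out = 20))
  m0 <- mean(log(base))
  out_rt <- exp(m0 + 0.5)   # far beyond 2 SD of the pooled log sample
  tab2 <- make_trials(21, rt_ms = c(base, out_rt))
  full <- log(tab2$rt_ms)
  z <- abs(full - mean(full)) / sd(full)
  expect_equal(which(z > 2), 21)              # fixture arithmetic
  res2 <- filter_rt_outliers(tab2)
  expect_equal(res2$counts$rt_logsd, 1)
  expect_false(out_rt %in% res2$data$rt_ms)

  # fewer than 3 trials: log-SD stage skipped with a note
  res3 <- filter_rt_outliers(make_trials(2, rt_ms = c(900, 950)))
  expect_equal(res3$counts$rt_logsd, 0)
  expect_match(res3$warnings, "skipped")
})

test_that("word-knowledge recode drops unknown words and flips reversals", {
  tab <- make_trials(4,
                     knowledge_rating = c(1, 4, 3, 2),
                     meaning_reversed = c(0, 1, 0, 0),
                     word_valence = c("positive", "positive", "negative",
                                      "negative"),
                     choice = c(1, 1, 0, 1))
  res <- recode_word_knowledge(tab)
  expect_equal(res$counts$unknown_word, 2)       # ratings 1 and 2 dropped
  expect_equal(res$counts$recoded, 1)
  expect_equal(nrow(res$data), 2)
  flipped <- res$data[res$data$knowledge_rating == 4, ]
  expect_equal(flipped$word_valence, "negative") # was positive, reversed
  expect_equal(flipped$choice, 0L)               # correctness flipped
  expect_equal(flipped$meaning_reversed, 0L)     # flag cleared
  untouched <- res$data[res$data$knowledge_rating == 3, ]
  expect_equal(untouched$word_valence, "negative")
  expect_equal(untouched$choice, 0)
})

test_that("cascade order, per-reason audit, and row conservation hold", {
  # a 150 ms aware trial is counted once, as aware, not as rt_absolute
  tab <- make_full_table(participants = 1:2, per_cell = 35)
  tab$rt_ms[1] <- 150; tab$aware[1] <- 1
  res <- run_preprocessing(tab)
  expect_equal(res$report$trials_excluded$aware, 1)
  expect_equal(res$report$trials_excluded$rt_absolute, 0)

  # injected nuisance counts are recovered exactly when they cannot overlap
  des <- napt_design(3, seed = 21)
  tr <- napt_truth(3, "null", seed = 21)
  aware_only <- simulate_napt(tr, des, napt_nuisance(0.04, 0, 0, 0), seed = 21)
  rep1 <- run_preprocessing(aware_only, preprocess_config(log_sd_mult = Inf))
  expect_equal(rep1$report$trials_excluded$aware,
               attr(aware_only, "injected")$aware)

  contam_only <- simulate_napt(tr, des, napt_nuisance(0, 0, 0, 0.04), seed = 22)
  rep2 <- run_preprocessing(contam_only, preprocess_config(log_sd_mult = Inf))
  expect_equal(rep2$report$trials_excluded$rt_absolute,
               attr(contam_only, "injected")$contaminant)

  # conservation: input rows = output rows + distinct excluded rows
  mixed <- simulate_napt(tr, des, napt_nuisance(0.03, 0.05, 0.05, 0.03),
                         seed = 23)
  rep3 <- run_preprocessing(mixed)
  expect_equal(rep3$report$n_input,
               rep3$report$n_output + rep3$report$distinct_excluded)
  expect_equal(rep3$report$distinct_excluded,
               sum(unlist(rep3$report$trials_excluded)))
})

test_that("zero-nuisance data incur no nuisance-driven exclusions", {
  study <- simulate_napt_study(3, "null", nuisance = napt_nuisance(0, 0, 0, 0),
                               seed = 31)
  res <- run_preprocessing(study$data)
  te <- res$report$trials_excluded
  expect_equal(te$aware, 0)
  expect_equal(te$participant_removed, 0)
  expect_equal(te$rt_absolute, 0)
  expect_equal(te$unknown_word, 0)
  # the 2-SD log filter trims its intrinsic share (~4.6% under normality)
  expect_lt(te$rt_logsd / res$report$n_input, 0.10)
  # and can be disabled outright
  res0 <- run_preprocessing(study$data, preprocess_config(log_sd_mult = Inf))
  expect_equal(res0$report$distinct_excluded, 0)
})

test_that("the cascade is idempotent on its own output", {
  des <- napt_design(3, seed = 41)
  tr <- napt_truth(3, "paper", seed = 41)
  raw <- simulate_napt(tr, des, napt_nuisance(0.03, 0.03, 0.03, 0.03),
                       seed = 41)
  first <- run_preprocessing(raw)
  second <- run_preprocessing(first$data)
  expect_equal(second$report$distinct_excluded, 0)
  expect_equal(second$report$trials_recoded, 0)
  expect_identical(second$data, first$data)
})
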