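# Synthetic priming datasets with known ground truth. The generator mirrors
# the study design the package targets: a 4 (face prime) x 2 (word valence)
# within-subject design with 40 trials per condition, presented in 4 blocks
# of 80 trials, each block balanced across the 8 conditions. Responses are
# accuracy-coded: choice = 1 means the word was categorised into its correct
# valence (the diffusion's upper boundary).

#' Trial skeleton for the priming design
#'
#' Builds the per-participant trial list: `trials_per_condition` rows for
#' each of the 8 face-by-valence cells, distributed evenly over
#' `n_blocks` blocks (each block balanced across the 8 conditions) and
#' shuffled within block. Word identities are drawn from fixed pools of 20
#' words per valence.
#'
#' @param n_participants number of participants.
#' @param trials_per_condition trials per face-by-valence cell (default 40).
#' @param n_blocks number of blocks (default 4).
#' @param seed integer seed for the within-block shuffles.
#' @return data.frame with columns `participant_id`, `block`, `trial`,
#'   `face_prime`, `word_valence`, `word_id`.
#' @examples
#' d <- napt_design(1, seed = 1)
#' nrow(d)                    # 320 trials
#' table(d$face_prime, d$word_valence)  # 40 per cell
#' @export
napt_design <- function(n_participants, trials_per_condition = 40,
                        n_blocks = 4, seed = NULL) {
  if (n_participants < 1) stop("need at least 1 participant", call. = FALSE)
  if (trials_per_condition %% n_blocks != 0)
    stop("`trials_per_condition` must be divisible by `n_blocks` ",
         "to balance each block across the 8 conditions", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  conds <- napt_conditions()
  per_block <- trials_per_condition / n_blocks
  pool <- list(positive = sprintf("pos%02d", 1:20),
               negative = sprintf("neg%02d", 1:20))
  one_block <- conds[rep(seq_len(8), each = per_block), c("face", "valence")]
  out <- vector("list", n_participants * n_blocks)
  k <- 0
  for (p in seq_len(n_participants)) {
    for (b in seq_len(n_blocks)) {
      blk <- one_block[sample.int(nrow(one_block)), ]
      blk$word_id <- vapply(blk$valence,
                            function(v) sample(pool[[v]], 1), character(1))
      k <- k + 1
      out[[k]] <- data.frame(participant_id = p, block = b,
                             trial = seq_len(nrow(blk)),
                             face_prime = blk$face,
                             word_valence = blk$valence,
                             word_id = blk$word_id)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Ground-truth parameter table for a synthetic study
#'
#' Draws person- and condition-level diffusion parameters from the model
#' hierarchy: person boundary `alpha_p ~ N(mu_alpha, sigma_alpha^2)` (> 0,
#' resampled), person-condition drift `nu_pi ~ N(mu_nu[i], sigma_nu^2)` and
#' nondecision `theta_pi ~ N(mu_theta[i], sigma_theta^2)` (>= 0, resampled).
#' Built-in scenarios:
#' \describe{
#'   \item{`paper`}{condition means at the scale of the reference study's
#'     posterior estimates (drifts ~2.4--2.8, nondecision ~0.45--0.49 s).}
#'   \item{`null`}{all conditions share one drift (2.6) and one
#'     nondecision time (0.46 s).}
#'   \item{`pattern`}{the null scenario plus the effects of interest: a
#'     positive-vs-negative drift gap of +0.4 for the scrambled prime only,
#'     and a negative-vs-positive nondecision gap of +0.03 s for the happy
#'     and neutral primes only.}
#' }
#'
#' @param n_participants number of participants.
#' @param scenario one of `"paper"`, `"null"`, `"pattern"`.
#' @param mu_nu,mu_theta optional length-8 condition means (canonical
#'   order, see [napt_conditions()]) overriding the scenario.
#' @param sigma_nu,sigma_theta between-person SDs of drift / nondecision.
#' @param mu_alpha,sigma_alpha group mean/SD of boundary separation.
#' @param eta,chi trial-level SDs of drift / nondecision.
#' @param seed integer seed.
#' @return object of class `napt_truth`: list with the group-level settings
#'   and the person-level draws (`alpha` vector, `nu`/`theta` P x 8
#'   matrices with condition labels as column names).
#' @export
napt_truth <- function(n_participants,
                       scenario = c("paper", "null", "pattern"),
                       mu_nu = NULL, mu_theta = NULL,
                       sigma_nu = 0.3, sigma_theta = 0.02,
                       mu_alpha = 2, sigma_alpha = 0.3,
                       eta = 0.5, chi = 0.05, seed = NULL) {
  scenario <- match.arg(scenario)
  if (any(c(sigma_nu, sigma_theta, sigma_alpha, eta, chi) < 0))
    stop("spread parameters must be >= 0", call. = FALSE)
  if (mu_alpha <= 0) stop("`mu_alpha` must be > 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  labels <- napt_conditions()$label
  defaults <- switch(scenario,
    paper = list(
      nu = c(2.65, 2.40, 2.51, 2.68, 2.79, 2.82, 2.54, 2.64),
      th = c(0.46, 0.46, 0.45, 0.48, 0.46, 0.49, 0.46, 0.47)),
    null = list(nu = rep(2.6, 8), th = rep(0.46, 8)),
    pattern = list(
      nu = c(2.80, 2.40, rep(2.6, 6)),
      th = c(0.46, 0.46, 0.445, 0.475, 0.445, 0.475, 0.46, 0.46)))
  if (is.null(mu_nu)) mu_nu <- defaults$nu
  if (is.null(mu_theta)) mu_theta <- defaults$th
  stopifnot(length(mu_nu) == 8, length(mu_theta) == 8)
  if (any(mu_theta < 0)) stop("`mu_theta` must be >= 0", call. = FALSE)
  names(mu_nu) <- names(mu_theta) <- labels
  P <- n_participants
  rtnorm <- function(n, mean, sd, lower) {
    x <- rnorm(n, mean, sd)
    while (any(bad <- x < lower)) x[bad] <- rnorm(sum(bad), mean[bad], sd)
    x
  }
  alpha <- rtnorm(P, rep(mu_alpha, P), sigma_alpha, 1e-6)
  nu <- matrix(rnorm(P * 8, rep(mu_nu, each = P), sigma_nu), P, 8,
               dimnames = list(NULL, labels))
  th_raw <- rtnorm(P * 8, rep(mu_theta, each = P), sigma_theta, 0)
  theta <- matrix(th_raw, P, 8, dimnames = list(NULL, labels))
  structure(list(scenario = scenario, n_participants = P,
                 mu_nu = mu_nu, mu_theta = mu_theta,
                 sigma_nu = sigma_nu, sigma_theta = sigma_theta,
                 mu_alpha = mu_alpha, sigma_alpha = sigma_alpha,
                 eta = eta, chi = chi,
                 alpha = alpha, nu = nu, theta = theta),
            class = "napt_truth")
}

#' Nuisance process configuration for the synthetic generator
#'
#' Controls the contamination the preprocessing cascade is meant to remove:
#' prime-aware trials, words unknown to (or understood oppositely by) a
#' participant, and response-time contaminants replaced by uniform draws in
#' an implausibly fast or slow range.
#'
#' @param awareness_rate per-trial probability of a prime-aware trial.
#' @param unknown_word_rate per participant-word probability the word is
#'   unknown (knowledge rating 1 or 2).
#' @param reversed_meaning_rate per participant-word probability the word is
#'   known with reversed meaning.
#' @param contaminant_rate per-trial probability the RT is replaced by a
#'   contaminant.
#' @param contaminant_fast,contaminant_slow ms ranges for fast/slow
#'   contaminants (each used with probability 1/2).
#' @return named list of class `napt_nuisance`.
#' @export
napt_nuisance <- function(awareness_rate = 0.025, unknown_word_rate = 0.02,
                          reversed_meaning_rate = 0.02,
                          contaminant_rate = 0.02,
                          contaminant_fast = c(50, 199),
                          contaminant_slow = c(5001, 8000)) {
  rates <- c(awareness_rate, unknown_word_rate, reversed_meaning_rate,
             contaminant_rate)
  if (any(rates < 0 | rates > 1))
    stop("nuisance rates must be in [0, 1]", call. = FALSE)
  structure(list(awareness_rate = awareness_rate,
                 unknown_word_rate = unknown_word_rate,
                 reversed_meaning_rate = reversed_meaning_rate,
                 contaminant_rate = contaminant_rate,
                 contaminant_fast = contaminant_fast,
                 contaminant_slow = contaminant_slow),
            class = "napt_nuisance")
}

#' Simulate trial data for a design skeleton under known truth
#'
#' Each trial's (choice, rt) pair is generated from the Wiener diffusion
#' with trial-level drift `~ N(nu_pi, eta^2)` and nondecision time
#' `~ N(theta_pi, chi^2)` truncated at 0 (resampled). Choices are accuracy
#' coded. Nuisance processes are then injected: aware flags, unknown and
#' meaning-reversed words (consistent per participant-word), and RT
#' contaminants. For meaning-reversed words the diffusion runs on the
#' participant's internal (opposite) valence and the recorded correctness
#' is relative to the nominal valence, so the preprocessing recode recovers
#' the consistent trial. Injected nuisance counts are attached as
#' `attr(x, "injected")` for auditing.
#'
#' @param truth a [napt_truth()] object covering all participants in
#'   `design`.
#' @param design trial skeleton from [napt_design()].
#' @param nuisance a [napt_nuisance()] configuration.
#' @param seed integer seed.
#' @param dt Euler step of the first-passage simulator (seconds).
#' @return data.frame in the long trial format: `participant_id`, `block`,
#'   `face_prime`, `word_valence`, `word_id`, `choice`, `rt_ms`, `aware`,
#'   `knowledge_rating`, `meaning_reversed`.
#' @export
simulate_napt <- function(truth, design, nuisance = napt_nuisance(),
                          seed = NULL, dt = 1e-4) {
  stopifnot(inherits(truth, "napt_truth"))
  if (!is.null(seed)) set.seed(seed)
  P <- truth$n_participants
  if (max(design$participant_id) > P)
    stop("truth table does not cover all participants in the design",
         call. = FALSE)
  n <- nrow(design)
  ci <- condition_index(design$face_prime, design$word_valence)

  # per participant-word knowledge status (consistent across repetitions)
  words <- unique(design[, c("participant_id", "word_id")])
  u <- runif(nrow(words))
  words$status <- ifelse(u < nuisance$unknown_word_rate, "unknown",
                  ifelse(u < nuisance$unknown_word_rate +
                             nuisance$reversed_meaning_rate, "reversed",
                         "known"))
  words$rating <- ifelse(words$status == "unknown",
                         sample(1:2, nrow(words), replace = TRUE),
                         sample(3:4, nrow(words), replace = TRUE))
  key <- paste(design$participant_id, design$word_id)
  wk <- words[match(key, paste(words$participant_id, words$word_id)), ]

  # condition actually driving the diffusion: reversed words run on the
  # participant's internal (opposite) valence
  flip <- wk$status == "reversed"
  internal_valence <- ifelse(flip,
                             ifelse(design$word_valence == "positive",
                                    "negative", "positive"),
                             design$word_valence)
  ci_int <- condition_index(design$face_prime, internal_valence)

  pc <- cbind(design$participant_id, ci_int)
  mu_trial <- truth$nu[pc]
  th_trial <- truth$theta[pc]
  drift <- rnorm(n, mu_trial, truth$eta)
  tau <- rnorm(n, th_trial, truth$chi)
  while (any(bad <- tau < 0)) tau[bad] <- rnorm(sum(bad), th_trial[bad], truth$chi)
  sim <- rwiener(n, truth$alpha[design$participant_id], 0.5, drift, tau,
                 seed = runif(1) * 2^31, dt = dt)
  correct_internal <- sim$boundary == "upper"
  choice <- as.integer(ifelse(flip, !correct_internal, correct_internal))
  rt_ms <- sim$rt * 1000

  contam <- runif(n) < nuisance$contaminant_rate
  if (any(contam)) {
    fast <- runif(sum(contam)) < 0.5
    lo <- ifelse(fast, nuisance$contaminant_fast[1], nuisance$contaminant_slow[1])
    hi <- ifelse(fast, nuisance$contaminant_fast[2], nuisance$contaminant_slow[2])
    rt_ms[contam] <- runif(sum(contam), lo, hi)
  }
  aware <- as.integer(runif(n) < nuisance$awareness_rate)

  out <- data.frame(participant_id = design$participant_id,
                    block = design$block,
                    face_prime = design$face_prime,
                    word_valence = design$word_valence,
                    word_id = design$word_id,
                    choice = choice,
                    rt_ms = rt_ms,
                    aware = aware,
                    knowledge_rating = wk$rating,
                    meaning_reversed = as.integer(flip))
  attr(out, "injected") <- list(
    aware = sum(aware),
    contaminant = sum(contam),
    unknown_word = sum(wk$status == "unknown"),
    reversed_word = sum(flip))
  out
}

#' One-call synthetic study
#'
#' Convenience wrapper: design skeleton + truth draw + trial simulation
#' with a single seed.
#'
#' @inheritParams napt_design
#' @inheritParams napt_truth
#' @param nuisance a [napt_nuisance()]; use rates of 0 for a clean dataset.
#' @param ... further arguments to [napt_truth()].
#' @return list with `data`, `truth`, `design`.
#' @export
simulate_napt_study <- function(n_participants, scenario = "paper",
                                trials_per_condition = 40, n_blocks = 4,
                                nuisance = napt_nuisance(), seed = 1, ...) {
  set.seed(seed)
  design <- napt_design(n_participants, trials_per_condition, n_blocks)
  truth <- napt_truth(n_participants, scenario = scenario, ...)
  data <- simulate_napt(truth, design, nuisance)
  list(data = data, truth = truth, design = design)
}

#' Write a synthetic study to disk
#'
#' Writes the trial table as CSV plus the ground truth as CSV (person-level
#' parameters) and a JSON sidecar (group-level settings and scenario).
#'
#' @param study list from [simulate_napt_study()].
#' @param dir output directory (created if needed).
#' @param seed seed to record in the sidecar.
#' @return named vector of file paths, invisibly.
#' @export
write_napt <- function(study, dir, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(data = file.path(dir, "trials.csv"),
             truth_person = file.path(dir, "truth_person.csv"),
             truth_group = file.path(dir, "truth_group.json"))
  write.csv(study$data, paths["data"], row.names = FALSE)
  tr <- study$truth
  person <- data.frame(participant_id = seq_len(tr$n_participants),
                       alpha = tr$alpha)
  person <- cbind(person,
                  setNames(as.data.frame(tr$nu), paste0("nu.", colnames(tr$nu))),
                  setNames(as.data.frame(tr$theta), paste0("theta.", colnames(tr$theta))))
  write.csv(person, paths["truth_person"], row.names = FALSE)
  group <- tr[c("scenario", "n_participants", "mu_nu", "mu_theta", "sigma_nu",
                "sigma_theta", "mu_alpha", "sigma_alpha", "eta", "chi")]
  group$seed <- seed
  jsonlite::write_json(group, paths["truth_group"], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
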