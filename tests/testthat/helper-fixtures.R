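# Shared test helpers: schema-complete trial tables, a fake fit object with
# controlled posterior draws, and a cache so expensive fits and simulations
# are built once per test run.

.test_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .test_cache)) {
    assign(key, force(expr), envir = .test_cache)
  }
  get(key, envir = .test_cache)
}

# a minimal schema-complete trial table; vectors are recycled
make_trials <- function(n = 8, participant_id = 1, block = 1,
                        face_prime = "scrambled", word_valence = "positive",
                        word_id = "pos01", choice = 1, rt_ms = 900,
                        aware = 0, knowledge_rating = 4, meaning_reversed = 0) {
  data.frame(participant_id = rep_len(participant_id, n),
             block = rep_len(block, n),
             face_prime = rep_len(face_prime, n),
             word_valence = rep_len(word_valence, n),
             word_id = rep_len(word_id, n),
             choice = rep_len(choice, n),
             rt_ms = rep_len(rt_ms, n),
             aware = rep_len(aware, n),
             knowledge_rating = rep_len(knowledge_rating, n),
             meaning_reversed = rep_len(meaning_reversed, n))
}

# a trial table with all 8 conditions for each participant, `per_cell`
# trials per condition
make_full_table <- function(participants = 1:2, per_cell = 30, rt_ms = 900,
                            choice = 1, aware = 0) {
  conds <- napt_conditions()
  rows <- expand.grid(participant_id = participants,
                      ci = seq_len(8), trial = seq_len(per_cell))
  make_trials(n = nrow(rows),
              participant_id = rows$participant_id,
              face_prime = conds$face[rows$ci],
              word_valence = conds$valence[rows$ci],
              word_id = ifelse(conds$valence[rows$ci] == "positive",
                               "pos01", "neg01"),
              choice = choice, rt_ms = rt_ms, aware = aware)
}

# an "hdm"-classed object whose group-level draws are fully controlled;
# `values` is a named list: label -> vector of draws (recycled to n_draws)
fake_fit <- function(drift = NULL, ndt = NULL, n_draws = 100, chains = 2) {
  labels <- napt_conditions()$label
  participants <- 1:2
  par_names <- wienerhdm:::hdm_par_names(participants, labels)
  draws <- array(0, dim = c(chains, n_draws, length(par_names)),
                 dimnames = list(NULL, NULL, par_names))
  for (lab in labels) {
    dv <- if (!is.null(drift) && lab %in% names(drift)) drift[[lab]] else 2.5
    tv <- if (!is.null(ndt) && lab %in% names(ndt)) ndt[[lab]] else 0.46
    draws[, , paste0("mu_nu[", lab, "]")] <-
      matrix(rep_len(dv, chains * n_draws), chains)
    draws[, , paste0("mu_theta[", lab, "]")] <-
      matrix(rep_len(tv, chains * n_draws), chains)
  }
  structure(list(draws = draws, par_names = par_names,
                 participants = participants,
                 conditions = napt_conditions(),
                 config = hdm_config(chains = chains, burn_in = 10,
                                     draws = n_draws),
                 rhat = setNames(rep(1, length(par_names)), par_names)),
            class = "hdm")
}

# small real fit reused across test files
small_fit <- function() {
  cache_get("small_fit", {
    study <- simulate_napt_study(n_participants = 4, scenario = "paper",
                                 nuisance = napt_nuisance(0, 0, 0, 0),
                                 seed = 42)
    fit <- hdm(study$data, chains = 2, burn_in = 250, draws = 250, seed = 5)
    list(study = study, fit = fit)
  })
}
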