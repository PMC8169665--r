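# Pre-analysis exclusion cascade. Stage order (fixed, logged in the
# report): aware-trial exclusion -> participant exclusion (accuracy and
# trial-count rules, both computed on unaware trials before any RT
# filtering) -> absolute RT cutoffs -> per-participant +/-2 SD filter on
# log RT -> word-knowledge recode/drop. Each trial is excluded at most
# once, attributed to the first rule it fails.

trial_schema <- c("participant_id", "block", "face_prime", "word_valence",
                  "word_id", "choice", "rt_ms", "aware", "knowledge_rating",
                  "meaning_reversed")

check_trial_table <- function(data, cols = trial_schema) {
  miss <- setdiff(cols, names(data))
  if (length(miss))
    stop("trial table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}

#' Exclude prime-aware trials
#'
#' Removes every trial on which the participant reported perceiving the
#' masked prime.
#'
#' @param data trial table with an `aware` column (0/1).
#' @return list with `data` (aware trials removed) and `excluded` (count).
#' @export
exclude_aware_trials <- function(data) {
  check_trial_table(data, c("aware"))
  keep <- data$aware == 0
  list(data = data[keep, , drop = FALSE], excluded = sum(!keep))
}

#' Exclude participants by accuracy and trial-count rules
#'
#' Removes participants whose overall categorisation accuracy is below
#' `min_accuracy` (default 90%) or who retain fewer than
#' `min_trials_per_condition` (default 30, inclusive) unaware trials in any
#' of the 8 conditions. Intended to run after [exclude_aware_trials()] and
#' before RT filtering, so both rules are evaluated on unaware trials.
#'
#' @param data trial table (post aware-trial exclusion).
#' @param min_accuracy minimum proportion correct, inclusive lower bound
#'   `>= min_accuracy` retains.
#' @param min_trials_per_condition minimum retained trials per condition
#'   (inclusive).
#' @param vetted participant ids already vetted by a previous pass; they
#'   are retained without re-evaluation. Later filter stages remove
#'   trials, so re-applying the trial-count rule to an already-cleaned
#'   table would otherwise expel participants a second pass; the vetted
#'   list travels with [run_preprocessing()] output to keep the cascade
#'   idempotent.
#' @return list with `data`, `participants` (list of excluded ids by
#'   reason: `accuracy`, `insufficient_trials`) and `excluded_trials`
#'   (rows removed with those participants).
#' @export
exclude_participants <- function(data, min_accuracy = 0.90,
                                 min_trials_per_condition = 30,
                                 vetted = NULL) {
  check_trial_table(data, c("participant_id", "face_prime", "word_valence",
                            "choice"))
  if (nrow(data) == 0)
    return(list(data = data, participants = list(accuracy = c(),
                                                 insufficient_trials = c()),
                excluded_trials = 0L,
                warnings = "empty table passed to participant exclusion"))
  ids <- unique(data$participant_id)
  acc <- tapply(data$choice, data$participant_id, mean)
  bad_acc <- names(acc)[acc < min_accuracy]
  cell_n <- table(data$participant_id,
                  paste(data$face_prime, data$word_valence))
  # a participant must have every one of the 8 cells at or above threshold
  full <- matrix(0L, length(ids), 8,
                 dimnames = list(as.character(ids), napt_conditions()$label))
  colnames(cell_n) <- sub(" ", ":", colnames(cell_n))
  common <- intersect(colnames(full), colnames(cell_n))
  full[rownames(cell_n), common] <- cell_n[, common]
  bad_n <- rownames(full)[apply(full, 1, min) < min_trials_per_condition]
  bad_acc <- setdiff(bad_acc, as.character(vetted))
  bad_n <- setdiff(bad_n, as.character(vetted))
  drop_ids <- union(bad_acc, bad_n)
  keep <- !(as.character(data$participant_id) %in% drop_ids)
  cast <- function(x) if (is.numeric(data$participant_id)) as.numeric(x) else x
  list(data = data[keep, , drop = FALSE],
       participants = list(accuracy = cast(bad_acc),
                           insufficient_trials = cast(bad_n)),
       excluded_trials = sum(!keep))
}

#' Filter response-time outliers
#'
#' Two-stage filter: absolute cutoffs first (remove trials faster than
#' `rt_min` ms or slower than `rt_max` ms; both strict, so boundary values
#' are retained), then a per-participant filter removing trials whose
#' log-transformed RT is more than `sd_mult` standard deviations (strict)
#' from that participant's mean log RT, computed over the trials that
#' survived the absolute cutoffs. Participants with fewer than 3 surviving
#' trials have no defined SD; the log-SD stage is skipped for them and a
#' note is recorded.
#'
#' @param data trial table with `rt_ms`.
#' @param rt_min,rt_max absolute cutoffs in ms (strict inequalities).
#' @param sd_mult SD multiplier of the log-RT filter.
#' @param log_stats optional table on which to compute each participant's
#'   mean/SD of log RT (defaults to the absolute-cutoff survivors; pass a
#'   larger table to include e.g. aware trials in the estimate).
#' @param bounds optional per-participant log-RT bounds (as returned in the
#'   result's `bounds` element) to reuse instead of recomputing. Because
#'   trimming shrinks the SD, recomputing bounds on already-filtered data
#'   would remove further trials on every pass; reusing the stored bounds
#'   makes the filter idempotent.
#' @return list with `data`, `counts` (list: `rt_absolute`, `rt_logsd`),
#'   `bounds` (data.frame `participant_id`, `lo`, `hi` on the log scale)
#'   and `warnings` (character).
#' @export
filter_rt_outliers <- function(data, rt_min = 200, rt_max = 5000,
                               sd_mult = 2, log_stats = NULL, bounds = NULL) {
  check_trial_table(data, c("participant_id", "rt_ms"))
  abs_keep <- data$rt_ms >= rt_min & data$rt_ms <= rt_max
  n_abs <- sum(!abs_keep)
  d <- data[abs_keep, , drop = FALSE]
  stats_tab <- if (is.null(log_stats)) d else
    log_stats[log_stats$rt_ms >= rt_min & log_stats$rt_ms <= rt_max, ,
              drop = FALSE]
  warnings <- character()
  keep <- rep(TRUE, nrow(d))
  ids <- unique(d$participant_id)
  out_bounds <- data.frame(participant_id = ids, lo = -Inf, hi = Inf)
  for (j in seq_along(ids)) {
    id <- ids[j]
    sel <- d$participant_id == id
    stored <- if (!is.null(bounds)) bounds[bounds$participant_id == id, ] else
      NULL
    if (!is.null(stored) && nrow(stored) == 1) {
      lo <- stored$lo; hi <- stored$hi
    } else {
      ref <- stats_tab$rt_ms[stats_tab$participant_id == id]
      if (length(ref) < 3) {
        warnings <- c(warnings, paste0(
          "participant ", id, ": fewer than 3 trials, log-SD filter skipped"))
        next
      }
      lm_ <- mean(log(ref)); ls_ <- sd(log(ref))
      lo <- lm_ - sd_mult * ls_; hi <- lm_ + sd_mult * ls_
    }
    out_bounds$lo[j] <- lo; out_bounds$hi[j] <- hi
    lrt <- log(d$rt_ms[sel])
    keep[sel] <- lrt >= lo & lrt <= hi
  }
  list(data = d[keep, , drop = FALSE],
       counts = list(rt_absolute = n_abs, rt_logsd = sum(!keep)),
       bounds = out_bounds,
       warnings = warnings)
}

#' Drop unknown words and recode meaning-reversed words
#'
#' Trials whose target word the participant rated 1 or 2 (does not know the
#' meaning) are removed. Trials with a known word (`knowledge_rating` 3 or
#' 4) whose meaning the participant had reversed keep the trial but flip
#' `word_valence` to the participant's internal association and flip the
#' correctness coding of `choice` accordingly; the `meaning_reversed` flag
#' is then cleared so the recode is idempotent.
#'
#' @param data trial table with `knowledge_rating` and `meaning_reversed`.
#' @return list with `data` and `counts` (list: `unknown_word` removed,
#'   `recoded` flipped).
#' @export
recode_word_knowledge <- function(data) {
  check_trial_table(data, c("knowledge_rating", "meaning_reversed",
                            "word_valence", "choice"))
  drop <- data$knowledge_rating %in% c(1, 2)
  d <- data[!drop, , drop = FALSE]
  flip <- d$meaning_reversed == 1
  if (any(flip)) {
    d$word_valence[flip] <- ifelse(d$word_valence[flip] == "positive",
                                   "negative", "positive")
    d$choice[flip] <- 1L - d$choice[flip]
    d$meaning_reversed[flip] <- 0L
  }
  list(data = d, counts = list(unknown_word = sum(drop), recoded = sum(flip)))
}

#' Run the full pre-analysis exclusion cascade
#'
#' Applies, in order: aware-trial exclusion, participant exclusion
#' (accuracy < `min_accuracy` or fewer than `min_trials_per_condition`
#' unaware trials in any condition), absolute RT cutoffs, the
#' per-participant log-RT SD filter, and the word-knowledge recode/drop.
#' Emits a complete audit report; each excluded trial is attributed to the
#' first rule it failed.
#'
#' @param data raw trial table (see [simulate_napt()] for the schema).
#' @param config list of thresholds; defaults are [preprocess_config()].
#' @return list of class `napt_preprocess` with `data` (the cleaned table)
#'   and `report` (class `exclusion_report`).
#' @export
run_preprocessing <- function(data, config = preprocess_config()) {
  check_trial_table(data)
  config <- modifyList(preprocess_config(), config)
  n_input <- nrow(data)

  s1 <- exclude_aware_trials(data)
  s2 <- exclude_participants(s1$data, config$min_accuracy,
                             config$min_trials_per_condition,
                             vetted = attr(data, "vetted_participants"))
  log_stats <- if (config$logsd_include_aware) {
    keep_ids <- unique(s2$data$participant_id)
    data[data$participant_id %in% keep_ids, , drop = FALSE]
  } else NULL
  s3 <- filter_rt_outliers(s2$data, config$rt_min_ms, config$rt_max_ms,
                           config$log_sd_mult, log_stats = log_stats,
                           bounds = attr(data, "logsd_bounds"))
  s4 <- recode_word_knowledge(s3$data)
  # preprocessing decisions travel with the cleaned table so a second pass
  # through the cascade reuses them instead of re-deciding (idempotence):
  # the log-RT bounds, and the participants already vetted (later stages
  # remove trials, which would otherwise re-trip the trial-count rule)
  attr(s4$data, "logsd_bounds") <- s3$bounds
  attr(s4$data, "vetted_participants") <- unique(s4$data$participant_id)

  trials_excluded <- list(aware = s1$excluded,
                          participant_removed = s2$excluded_trials,
                          rt_absolute = s3$counts$rt_absolute,
                          rt_logsd = s3$counts$rt_logsd,
                          unknown_word = s4$counts$unknown_word)
  distinct <- n_input - nrow(s4$data)
  report <- structure(list(
    n_input = n_input,
    n_output = nrow(s4$data),
    participants_excluded = s2$participants,
    trials_excluded = trials_excluded,
    trials_recoded = s4$counts$recoded,
    distinct_excluded = distinct,
    fraction_excluded = if (n_input > 0) distinct / n_input else 0,
    fractions = lapply(trials_excluded,
                       function(k) if (n_input > 0) k / n_input else 0),
    warnings = c(s2$warnings, s3$warnings),
    config = config), class = "exclusion_report")
  structure(list(data = s4$data, report = report), class = "napt_preprocess")
}

#' Default preprocessing thresholds
#'
#' The reference analysis values: 90% minimum accuracy, at least 30 unaware
#' trials per condition, RT window (200, 5000) ms, +/-2 SD log-RT filter
#' computed per participant on unaware trials.
#'
#' @param ... named overrides.
#' @return named list.
#' @export
preprocess_config <- function(...) {
  cfg <- list(min_accuracy = 0.90, min_trials_per_condition = 30,
              rt_min_ms = 200, rt_max_ms = 5000, log_sd_mult = 2,
              logsd_include_aware = FALSE)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop("unknown preprocessing option: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(dots)] <- dots
  }
  cfg
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Pre-analysis exclusion report\n")
  cat(sprintf("  input trials: %d   retained: %d   excluded: %d (%.1f%%)\n",
              x$n_input, x$n_output, x$distinct_excluded,
              100 * x$fraction_excluded))
  cat("  trials excluded by reason:\n")
  for (r in names(x$trials_excluded))
    cat(sprintf("    %-20s %d (%.1f%%)\n", r, x$trials_excluded[[r]],
                100 * x$fractions[[r]]))
  pe <- x$participants_excluded
  cat(sprintf("  participants excluded: accuracy %d, insufficient trials %d\n",
              length(pe$accuracy), length(pe$insufficient_trials)))
  if (x$trials_recoded > 0)
    cat(sprintf("  trials recoded (meaning reversed): %d\n", x$trials_recoded))
  if (length(x$warnings))
    cat("  notes:\n", paste0("    ", x$warnings, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.napt_preprocess <- function(x, ...) {
  print(x$report)
  invisible(x)
}

#' Write an exclusion report as JSON
#'
#' @param report an `exclusion_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
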