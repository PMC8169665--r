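# Descriptive summaries and the tidy export for the (external) generalized
# mixed-model RT analysis.

#' Per-condition RT and accuracy table
#'
#' Mean RT (ms), SD of RT (ms, same unit as the mean), accuracy and trial
#' count for each of the 8 face-by-valence conditions. Empty cells keep
#' their row with `n_trials = 0` and `NA` statistics. The result is
#' invariant to the row order of the input.
#'
#' @param data cleaned trial table.
#' @return data.frame with columns `face`, `valence`, `mean_rt_ms`,
#'   `sd_rt_ms`, `accuracy`, `n_trials`.
#' @export
rt_accuracy_table <- function(data) {
  check_trial_table(data, c("face_prime", "word_valence", "choice", "rt_ms"))
  conds <- napt_conditions()
  rows <- lapply(seq_len(8), function(i) {
    sel <- data$face_prime == conds$face[i] &
      data$word_valence == conds$valence[i]
    n <- sum(sel)
    data.frame(face = conds$face[i], valence = conds$valence[i],
               mean_rt_ms = if (n > 0) mean(data$rt_ms[sel]) else NA_real_,
               sd_rt_ms = if (n > 1) sd(data$rt_ms[sel]) else NA_real_,
               accuracy = if (n > 0) mean(data$choice[sel]) else NA_real_,
               n_trials = n)
  })
  do.call(rbind, rows)
}

#' Convert a within-subject standardised effect size to Cohen's f
#'
#' Standard repeated-measures conversion `f = d_z / 2`, returned at full
#' precision (rounding belongs to the report layer).
#'
#' @param d_z standardised within-subject effect size(s).
#' @return Cohen's f, same length as `d_z`.
#' @examples
#' dz_to_cohens_f(c(0.58, 0.51))  # 0.29, 0.255
#' @export
dz_to_cohens_f <- function(d_z) {
  if (!all(is.finite(d_z))) stop("`d_z` must be finite", call. = FALSE)
  d_z / 2
}

#' Export a tidy table for the mixed-model RT analysis
#'
#' Writes the cleaned trials as a CSV with columns `reaction_time`
#' (seconds), `face`, `valence`, `person` -- the layout expected by an
#' inverse-Gaussian GLMM of the form
#' `reaction_time ~ face + valence + face:valence + (1 | person)`.
#' No statistics are computed.
#'
#' @param data cleaned trial table.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
export_glmm_table <- function(data, path) {
  check_trial_table(data, c("participant_id", "face_prime", "word_valence",
                            "rt_ms"))
  out <- data.frame(reaction_time = data$rt_ms / 1000,
                    face = data$face_prime,
                    valence = data$word_valence,
                    person = data$participant_id)
  tryCatch(write.csv(out, path, row.names = FALSE),
           error = function(e) stop("cannot write GLMM table to ", path,
                                    ": ", conditionMessage(e), call. = FALSE))
  invisible(path)
}
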