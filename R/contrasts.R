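# Posterior readouts: condition summaries, valence differences per face,
# the facial-identity contrast, pairwise condition differences, and the
# posterior-predictive RT-quantile check. Decisions use the 95% HDI rule:
# a contrast is flagged when its HDI excludes 0. No multiplicity
# correction is applied (matching the reference analysis); the number of
# contrasts evaluated is up to the caller to track.

group_draws <- function(fit, parameter, face, valence) {
  parameter <- match.arg(parameter, c("drift", "nondecision"))
  base <- if (parameter == "drift") "mu_nu" else "mu_theta"
  if (!face %in% napt_faces) stop("unknown face label: ", face, call. = FALSE)
  if (!valence %in% napt_valences)
    stop("unknown valence label: ", valence, call. = FALSE)
  hdm_par_draws(fit, paste0(base, "[", face, ":", valence, "]"))
}

new_contrast <- function(name, draws, mass = 0.95) {
  if (length(unique(draws)) == 1L) {
    interval <- rep(draws[1], 2)
  } else {
    interval <- hdi(draws, mass)
  }
  structure(list(name = name, draws = draws, mean = mean(draws),
                 hdi = interval, mass = mass,
                 significant = interval[1] > 0 || interval[2] < 0),
            class = "hdm_contrast")
}

#' @export
print.hdm_contrast <- function(x, ...) {
  cat(sprintf("%s\n  posterior mean %.4f, %d%% HDI [%.4f, %.4f]%s\n",
              x$name, x$mean, round(100 * x$mass), x$hdi[1], x$hdi[2],
              if (x$significant) "  (HDI excludes 0)" else ""))
  invisible(x)
}

check_convergence <- function(fit, check_rhat) {
  if (!check_rhat) return(invisible(TRUE))
  thr <- fit$config$rhat_threshold
  bad <- fit$rhat[fit$rhat >= thr]
  if (length(bad))
    stop("convergence gate failed: ", length(bad), " parameter(s) with ",
         "split R-hat >= ", thr, " (worst: ",
         names(bad)[which.max(bad)], " = ", round(max(bad), 3),
         "); rerun with more draws or pass check_rhat = FALSE to override",
         call. = FALSE)
  invisible(TRUE)
}

#' Posterior condition summaries
#'
#' Per-condition posterior mean and 95% HDI of the condition-level mean
#' drift rate and mean nondecision time -- the 4 faces x 2 valences
#' summary table of the analysis.
#'
#' @param fit fitted [hdm()] object.
#' @param mass HDI mass.
#' @param check_rhat refuse to summarise when any split R-hat exceeds the
#'   configured threshold (override with `FALSE`).
#' @return data.frame with one row per condition: `face`, `valence`,
#'   `label`, `drift_mean`, `drift_lo`, `drift_hi`, `ndt_mean`, `ndt_lo`,
#'   `ndt_hi`.
#' @export
condition_summary <- function(fit, mass = 0.95, check_rhat = TRUE) {
  stopifnot(inherits(fit, "hdm"))
  check_convergence(fit, check_rhat)
  conds <- napt_conditions()
  rows <- lapply(seq_len(8), function(i) {
    dn <- group_draws(fit, "drift", conds$face[i], conds$valence[i])
    dt <- group_draws(fit, "nondecision", conds$face[i], conds$valence[i])
    hn <- if (length(unique(dn)) > 1) hdi(dn, mass) else rep(dn[1], 2)
    ht <- if (length(unique(dt)) > 1) hdi(dt, mass) else rep(dt[1], 2)
    data.frame(face = conds$face[i], valence = conds$valence[i],
               label = conds$label[i],
               drift_mean = mean(dn), drift_lo = hn[1], drift_hi = hn[2],
               ndt_mean = mean(dt), ndt_lo = ht[1], ndt_hi = ht[2])
  })
  do.call(rbind, rows)
}

#' Valence difference for one face prime
#'
#' Posterior contrast of negative-word minus positive-word condition means
#' for the given face prime, for the drift rate or the nondecision time,
#' with its 95% HDI and the HDI-excludes-zero flag.
#'
#' @param fit fitted [hdm()] object.
#' @param face one of `"scrambled"`, `"neutral"`, `"happy"`, `"angry"`.
#' @param parameter `"drift"` or `"nondecision"`.
#' @param mass HDI mass.
#' @return an `hdm_contrast` object.
#' @export
valence_difference <- function(fit, face, parameter = c("drift", "nondecision"),
                               mass = 0.95) {
  parameter <- match.arg(parameter)
  draws <- group_draws(fit, parameter, face, "negative") -
    group_draws(fit, parameter, face, "positive")
  new_contrast(sprintf("%s (negative - positive), %s face", parameter, face),
               draws, mass)
}

#' Facial-identity contrast on the drift-rate change
#'
#' The "drift rate change" of a face is its positive-word minus
#' negative-word mean drift. This contrast compares the scrambled prime's
#' change against the average change of the three intact faces (angry,
#' neutral, happy), per posterior draw:
#' `change(scrambled) - mean(change(angry), change(neutral), change(happy))`.
#'
#' @inheritParams valence_difference
#' @return an `hdm_contrast` object.
#' @export
identity_contrast <- function(fit, mass = 0.95) {
  change <- function(face)
    group_draws(fit, "drift", face, "positive") -
      group_draws(fit, "drift", face, "negative")
  draws <- change("scrambled") -
    (change("angry") + change("neutral") + change("happy")) / 3
  new_contrast("drift change: scrambled - mean(intact faces)", draws, mass)
}

#' Pairwise condition difference
#'
#' Posterior contrast `cell_a - cell_b` of the condition-level mean drift
#' or nondecision time between any two face-by-valence cells.
#'
#' @param fit fitted [hdm()] object.
#' @param cell_a,cell_b length-2 character vectors `c(face, valence)`.
#' @param parameter `"drift"` or `"nondecision"`.
#' @param mass HDI mass.
#' @return an `hdm_contrast` object.
#' @export
pairwise_difference <- function(fit, cell_a, cell_b,
                                parameter = c("drift", "nondecision"),
                                mass = 0.95) {
  parameter <- match.arg(parameter)
  if (identical(cell_a, cell_b))
    warning("identical cells requested; contrast is exactly zero")
  draws <- group_draws(fit, parameter, cell_a[1], cell_a[2]) -
    group_draws(fit, parameter, cell_b[1], cell_b[2])
  new_contrast(sprintf("%s: %s:%s - %s:%s", parameter,
                       cell_a[1], cell_a[2], cell_b[1], cell_b[2]),
               draws, mass)
}

#' Posterior-predictive RT-quantile check
#'
#' For each condition, compares the empirical RT quantiles (pooled over
#' participants) with the model's posterior-predictive quantiles: replicate
#' datasets are simulated from randomly selected posterior draws (including
#' trial-level variability), their pooled quantiles averaged, and the
#' Pearson correlation with the empirical quantiles reported per condition.
#'
#' @param fit fitted [hdm()] object.
#' @param data the cleaned trial table the model was fitted to.
#' @param probs quantile probabilities (default deciles 10--90%).
#' @param n_draws posterior draws to simulate from.
#' @param seed integer seed for draw selection and simulation.
#' @param min_trials cells with fewer trials are skipped with a warning.
#' @return data.frame with `face`, `valence`, `r`, `n_trials`; skipped
#'   cells have `r = NA`.
#' @export
ppc_quantile_check <- function(fit, data, probs = c(0.1, 0.3, 0.5, 0.7, 0.9),
                               n_draws = 20, seed = 1, min_trials = 10) {
  stopifnot(inherits(fit, "hdm"))
  check_trial_table(data, c("participant_id", "face_prime", "word_valence",
                            "rt_ms"))
  reps <- simulate.hdm(fit, nsim = n_draws, seed = seed)
  conds <- napt_conditions()
  out <- conds[, c("face", "valence")]
  out$r <- NA_real_
  out$n_trials <- 0L
  for (i in seq_len(8)) {
    sel <- data$face_prime == conds$face[i] &
      data$word_valence == conds$valence[i]
    out$n_trials[i] <- sum(sel)
    if (sum(sel) < min_trials) {
      warning("condition ", conds$label[i], " has fewer than ", min_trials,
              " trials; skipped")
      next
    }
    emp <- quantile(data$rt_ms[sel] / 1000, probs, names = FALSE)
    if (sd(emp) == 0)
      stop("empirical RT quantiles are constant in condition ",
           conds$label[i], "; correlation undefined", call. = FALSE)
    pred <- rowMeans(vapply(reps, function(r) {
      rsel <- r$face_prime == conds$face[i] &
        r$word_valence == conds$valence[i]
      quantile(r$rt_ms[rsel] / 1000, probs, names = FALSE)
    }, numeric(length(probs))))
    out$r[i] <- cor(emp, pred)
  }
  out
}
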