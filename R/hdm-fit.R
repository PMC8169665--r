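# Hierarchical diffusion model: model building, initialisation, sampling.
#
# The model (beta fixed at 0.5, diffusion coefficient s = 1):
#   trial drift        delta_pij ~ N(nu_pi, eta^2)        (marginalised)
#   trial nondecision  tau_pij   ~ N(theta_pi, chi^2)>=0  (marginalised)
#   person-condition   nu_pi     ~ N(mu_nu[i], sigma_nu^2)
#                      theta_pi  ~ N(mu_theta[i], sigma_theta^2), >= 0
#   person boundary    alpha_p   ~ N(mu_alpha, sigma_alpha^2), > 0
# with accuracy coding: the upper boundary is the correct valence
# categorisation.

#' Prior hyperparameters for the hierarchical diffusion model
#'
#' Weakly informative defaults: condition-level mean drifts `mu_nu[i] ~
#' N(0, 5^2)`; mean nondecision times `mu_theta[i] ~ N(0.3, 0.5^2)` kept
#' nonnegative; group boundary `mu_alpha ~ N(2, 1)` kept positive; all
#' spread parameters (between-person SDs and the trial-level SDs `eta`,
#' `chi`) half-Normal(0, 1). Any element can be overridden.
#'
#' @param ... named overrides of the default hyperparameters.
#' @return named list of prior hyperparameters.
#' @export
hdm_priors <- function(...) {
  p <- list(mu_nu_mean = 0, mu_nu_sd = 5,
            mu_theta_mean = 0.3, mu_theta_sd = 0.5,
            mu_alpha_mean = 2, mu_alpha_sd = 1,
            sigma_nu_scale = 1, sigma_theta_scale = 1, sigma_alpha_scale = 1,
            eta_scale = 1, chi_scale = 1)
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) stop("unknown prior component: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    p[names(dots)] <- dots
  }
  p
}

#' Sampler configuration for the hierarchical diffusion model
#'
#' Defaults follow the reference analysis settings: 3 chains, a burn-in of
#' 2000 sweeps (during which proposal scales adapt) and 2000 retained draws
#' per chain, with an R-hat acceptance threshold of 1.1.
#'
#' @param chains number of chains (>= 2).
#' @param burn_in discarded sweeps per chain.
#' @param draws retained draws per chain.
#' @param thin keep every `thin`-th sweep after burn-in.
#' @param adapt sweeps with proposal adaptation (defaults to `burn_in`).
#' @param seed integer seed; chains use fixed offsets from it.
#' @param gh_points Gauss--Hermite nodes for the nondecision integral
#'   (1, 3, 5 or 7).
#' @param eps truncation error bound of the first-passage density series.
#' @param rhat_threshold convergence gate used by reporting functions.
#' @param fix_eta,fix_chi optional numeric values at which to fix the
#'   trial-level drift / nondecision SDs instead of sampling them.
#' @return named list of class `hdm_config`.
#' @export
hdm_config <- function(chains = 3, burn_in = 2000, draws = 2000, thin = 1,
                       adapt = NULL, seed = 1, gh_points = 5, eps = 1e-7,
                       rhat_threshold = 1.1, fix_eta = NULL, fix_chi = NULL) {
  if (chains < 2) stop("need at least 2 chains", call. = FALSE)
  if (draws < 1) stop("need at least 1 retained draw", call. = FALSE)
  if (is.null(adapt)) adapt <- burn_in
  adapt <- min(adapt, burn_in)
  structure(list(chains = as.integer(chains), burn_in = as.integer(burn_in),
                 draws = as.integer(draws), thin = as.integer(thin),
                 adapt = as.integer(adapt), seed = as.integer(seed),
                 gh_points = gh_points, eps = eps,
                 rhat_threshold = rhat_threshold,
                 fix_eta = fix_eta, fix_chi = fix_chi),
            class = "hdm_config")
}

hdm_par_names <- function(participants, labels) {
  P <- length(participants)
  c(paste0("mu_nu[", labels, "]"),
    paste0("mu_theta[", labels, "]"),
    "sigma_nu", "sigma_theta", "mu_alpha", "sigma_alpha", "eta", "chi",
    paste0("alpha[", participants, "]"),
    paste0("nu[", rep(participants, each = 8), ",", rep(labels, P), "]"),
    paste0("theta[", rep(participants, each = 8), ",", rep(labels, P), "]"))
}

#' Build the hierarchical diffusion model for a cleaned trial table
#'
#' Validates the table, indexes trials by participant and condition, and
#' returns the model specification: data blocks, the parameter list in
#' sampling order, and an R-level log-posterior function (the audited
#' definition of the sampler's target; the compiled sampler evaluates the
#' same quantity).
#'
#' @param data cleaned trial table with columns `participant_id`,
#'   `face_prime`, `word_valence`, `choice` (1 = correct), `rt_ms`.
#' @param priors prior list from [hdm_priors()].
#' @param gh_points,eps numerical settings, see [hdm_config()].
#' @return object of class `hdm_model`.
#' @export
build_hdm <- function(data, priors = hdm_priors(), gh_points = 5, eps = 1e-7) {
  need <- c("participant_id", "face_prime", "word_valence", "choice", "rt_ms")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(data) == 0) stop("empty trial table", call. = FALSE)
  if (any(data$rt_ms <= 0)) stop("all rt_ms must be > 0", call. = FALSE)
  participants <- sort(unique(data$participant_id))
  if (length(participants) < 2)
    stop("hierarchical model needs at least 2 participants", call. = FALSE)
  conds <- napt_conditions()
  ci <- condition_index(data$face_prime, data$word_valence)
  if (length(unique(ci)) < 8)
    stop("all 8 face-by-valence conditions must be represented", call. = FALSE)
  trials <- data.frame(
    rt = data$rt_ms / 1000,
    upper = as.integer(data$choice == 1),
    pidx = match(data$participant_id, participants) - 1L,
    cidx = as.integer(ci) - 1L)
  P <- length(participants)
  par_names <- hdm_par_names(participants, conds$label)
  model <- list(trials = trials, participants = participants,
                conditions = conds, P = P, npar = length(par_names),
                par_names = par_names, priors = priors,
                gh_points = gh_points, eps = eps)
  model$log_posterior <- function(par) hdm_log_posterior(model, par)
  class(model) <- "hdm_model"
  model
}

hdm_gh <- function(gh_points, fix_chi) {
  if (!is.null(fix_chi) && fix_chi == 0) list(x = 0, w = 1)
  else gauss_hermite_normal(gh_points)
}

# R-level log posterior (up to a constant): data likelihood with trial-level
# parameters marginalised, hierarchy densities, priors. Used to audit the
# compiled sampler's target.
hdm_log_posterior <- function(model, par) {
  stopifnot(length(par) == model$npar)
  P <- model$P
  mu_nu <- par[1:8]; mu_theta <- par[9:16]
  sigma_nu <- par[17]; sigma_theta <- par[18]
  mu_alpha <- par[19]; sigma_alpha <- par[20]
  eta <- par[21]; chi <- par[22]
  alpha <- par[22 + seq_len(P)]
  nu <- matrix(par[22 + P + seq_len(8 * P)], nrow = P, byrow = TRUE)
  theta <- matrix(par[22 + 9 * P + seq_len(8 * P)], nrow = P, byrow = TRUE)
  if (any(alpha <= 0) || any(theta < 0) || any(mu_theta < 0) || mu_alpha <= 0 ||
      sigma_nu <= 0 || sigma_theta <= 0 || sigma_alpha <= 0 ||
      eta < 0 || chi < 0) return(-Inf)
  pr <- model$priors
  gh <- hdm_gh(model$gh_points, if (chi == 0) 0 else NULL)
  ll <- 0
  tr <- model$trials
  for (p in seq_len(P)) for (i in 1:8) {
    sel <- tr$pidx == p - 1L & tr$cidx == i - 1L
    if (!any(sel)) next
    d <- .dwiener_marg_cpp(tr$rt[sel], alpha[p], nu[p, i], eta,
                           theta[p, i], chi, tr$upper[sel] == 1L,
                           gh$x, gh$w, model$eps)
    ll <- ll + sum(log(pmax(d, 1e-300)))
  }
  hier <- sum(dnorm(nu, rep(mu_nu, each = P), sigma_nu, log = TRUE)) +
    sum(dnorm(theta, rep(mu_theta, each = P), sigma_theta, log = TRUE)) +
    sum(dnorm(alpha, mu_alpha, sigma_alpha, log = TRUE))
  prior <- sum(dnorm(mu_nu, pr$mu_nu_mean, pr$mu_nu_sd, log = TRUE)) +
    sum(dnorm(mu_theta, pr$mu_theta_mean, pr$mu_theta_sd, log = TRUE)) +
    dnorm(mu_alpha, pr$mu_alpha_mean, pr$mu_alpha_sd, log = TRUE) -
    sigma_nu^2 / (2 * pr$sigma_nu_scale^2) -
    sigma_theta^2 / (2 * pr$sigma_theta_scale^2) -
    sigma_alpha^2 / (2 * pr$sigma_alpha_scale^2) -
    eta^2 / (2 * pr$eta_scale^2) - chi^2 / (2 * pr$chi_scale^2)
  ll + hier + prior
}

# Method-of-moments initial values, overdispersed per chain. Nondecision
# inits stay safely below each cell's fastest response; drifts come from
# cell accuracy through the analytic choice probability (logit(acc)/alpha).
hdm_init <- function(model, chain, config) {
  tr <- model$trials
  P <- model$P
  alpha0 <- 1.8
  nu0 <- matrix(2, P, 8); theta0 <- matrix(0.35, P, 8)
  tau_p <- numeric(P)
  for (p in seq_len(P)) {
    rt_p <- tr$rt[tr$pidx == p - 1L]
    tau_p[p] <- 0.85 * quantile(rt_p, 0.05, names = FALSE)
    for (i in 1:8) {
      sel <- tr$pidx == p - 1L & tr$cidx == i - 1L
      if (!any(sel)) { theta0[p, i] <- tau_p[p]; next }
      acc <- mean(tr$upper[sel])
      nu0[p, i] <- qlogis(min(max(acc, 0.6), 0.99)) / alpha0
      theta0[p, i] <- min(tau_p[p], 0.9 * min(tr$rt[sel]))
    }
  }
  jit <- function(n, s) rnorm(n, 0, s)
  nu0 <- nu0 + jit(length(nu0), 0.2)
  min_rt_cell <- matrix(Inf, P, 8)
  for (p in seq_len(P)) for (i in 1:8) {
    sel <- tr$pidx == p - 1L & tr$cidx == i - 1L
    if (any(sel)) min_rt_cell[p, i] <- min(tr$rt[sel])
  }
  theta0 <- pmin(pmax(theta0 + jit(length(theta0), 0.015), 0.02),
                 0.9 * pmin(min_rt_cell, 10))
  alpha_v <- pmax(alpha0 + jit(P, 0.25), 0.6)
  eta0 <- if (!is.null(config$fix_eta)) config$fix_eta else 0.4 * exp(jit(1, 0.2))
  chi0 <- if (!is.null(config$fix_chi)) config$fix_chi else 0.03 * exp(jit(1, 0.2))
  c(colMeans(nu0),                                            # mu_nu
    colMeans(theta0),                                         # mu_theta
    max(sd(rowMeans(nu0)), 0.2), 0.03,                        # sigma_nu, sigma_theta
    mean(alpha_v), 0.3,                                       # mu_alpha, sigma_alpha
    eta0, chi0,
    alpha_v, as.numeric(t(nu0)), as.numeric(t(theta0)))
}

#' Sample the posterior of a built hierarchical diffusion model
#'
#' Runs independent adaptive Metropolis-within-Gibbs chains from
#' overdispersed method-of-moments initial values, discards the burn-in and
#' returns the retained draws with split-chain R-hat diagnostics. Results
#' are reproducible from `config$seed`.
#'
#' @param model an `hdm_model` from [build_hdm()].
#' @param config an [hdm_config()].
#' @param init optional list of initial parameter vectors, one per chain.
#' @return fitted object of class `hdm`; see [hdm()].
#' @export
sample_posterior <- function(model, config = hdm_config(), init = NULL) {
  stopifnot(inherits(model, "hdm_model"))
  gh <- hdm_gh(config$gh_points, config$fix_chi)
  control <- list(gh_x = gh$x, gh_w = gh$w, eps = model$eps,
                  fix_eta = !is.null(config$fix_eta),
                  fix_chi = !is.null(config$fix_chi),
                  burn_in = config$burn_in, adapt = config$adapt,
                  draws = config$draws, thin = config$thin)
  tr <- model$trials
  t0 <- Sys.time()
  draws <- array(NA_real_,
                 dim = c(config$chains, config$draws, model$npar),
                 dimnames = list(NULL, NULL, model$par_names))
  accept <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + 7919L * ch)
    ini <- if (is.null(init)) hdm_init(model, ch, config) else init[[ch]]
    res <- .hdm_chain_cpp(tr$rt, tr$upper, tr$pidx, tr$cidx,
                          model$P, 8L, ini, model$priors, control)
    draws[ch, , ] <- res$draws
    accept[[ch]] <- res$accept
  }
  if (any(!is.finite(draws)))
    stop("sampler produced non-finite draws", call. = FALSE)
  fit <- structure(list(
    draws = draws, par_names = model$par_names,
    participants = model$participants, conditions = model$conditions,
    model = model, config = config,
    accept = accept,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "hdm")
  fit$rhat <- rhat(fit)
  fit
}

#' Fit the hierarchical diffusion model to a cleaned trial table
#'
#' One-call interface: builds the model with [build_hdm()] and samples its
#' posterior with [sample_posterior()]. Condition-level mean drift and mean
#' nondecision time, person-level boundary separation and person-condition
#' parameters are estimated; the starting point is fixed at 0.5 (unbiased)
#' and trial-level drift/nondecision variability is marginalised out of the
#' likelihood.
#'
#' @inheritParams build_hdm
#' @param ... passed to [hdm_config()] (`chains`, `burn_in`, `draws`,
#'   `seed`, ...).
#' @return an object of class `hdm` with components `draws` (chains x
#'   draws x parameters array), `rhat`, `participants`, `conditions`,
#'   `config`; supports `print()`, `summary()`, `coef()`, `plot()` and
#'   `simulate()`.
#' @examples
#' \donttest{
#' study <- simulate_napt_study(n_participants = 4, seed = 1)
#' fit <- hdm(study$data, chains = 2, burn_in = 100, draws = 100, seed = 1)
#' summary(fit, check_rhat = FALSE)
#' }
#' @export
hdm <- function(data, priors = hdm_priors(), ...) {
  config <- hdm_config(...)
  model <- build_hdm(data, priors = priors,
                     gh_points = config$gh_points, eps = config$eps)
  sample_posterior(model, config)
}

# pooled draws (chains stacked) for one named parameter
hdm_par_draws <- function(fit, par) {
  j <- match(par, fit$par_names)
  if (is.na(j)) stop("unknown parameter: ", par, call. = FALSE)
  as.numeric(fit$draws[, , j])
}

group_par_names <- function(fit) {
  fit$par_names[c(1:22)]
}

#' @export
print.hdm <- function(x, ...) {
  cat("Hierarchical diffusion model fit\n")
  cat(sprintf("  participants: %d   trials: %d\n",
              length(x$participants), nrow(x$model$trials)))
  cat(sprintf("  chains: %d   retained draws/chain: %d   burn-in: %d\n",
              x$config$chains, x$config$draws, x$config$burn_in))
  cat(sprintf("  max split R-hat: %.3f (threshold %.2f)\n",
              max(x$rhat), x$config$rhat_threshold))
  invisible(x)
}

#' @export
coef.hdm <- function(object, which = c("group", "all"), ...) {
  which <- match.arg(which)
  pars <- if (which == "group") group_par_names(object) else object$par_names
  vapply(pars, function(p) mean(hdm_par_draws(object, p)), numeric(1))
}

#' @export
summary.hdm <- function(object, check_rhat = TRUE, ...) {
  tab <- condition_summary(object, check_rhat = check_rhat)
  out <- list(table = tab, rhat_max = max(object$rhat),
              rhat_threshold = object$config$rhat_threshold,
              n_participants = length(object$participants))
  class(out) <- "summary.hdm"
  out
}

#' @export
print.summary.hdm <- function(x, ...) {
  cat("Posterior condition summaries (mean [95% HDI])\n")
  fmt <- function(m, lo, hi) sprintf("%.3f [%.3f %.3f]", m, lo, hi)
  tab <- data.frame(face = x$table$face, valence = x$table$valence,
                    drift = fmt(x$table$drift_mean, x$table$drift_lo, x$table$drift_hi),
                    nondecision = fmt(x$table$ndt_mean, x$table$ndt_lo, x$table$ndt_hi))
  print(tab, row.names = FALSE)
  cat(sprintf("max split R-hat: %.3f\n", x$rhat_max))
  invisible(x)
}

#' @export
plot.hdm <- function(x, parameter = c("drift", "nondecision"), ...) {
  parameter <- match.arg(parameter)
  tab <- condition_summary(x, check_rhat = FALSE)
  if (parameter == "drift") {
    m <- tab$drift_mean; lo <- tab$drift_lo; hi <- tab$drift_hi
    ylab <- "mean drift rate"
  } else {
    m <- tab$ndt_mean; lo <- tab$ndt_lo; hi <- tab$ndt_hi
    ylab <- "mean nondecision time (s)"
  }
  at <- seq_len(nrow(tab))
  graphics::plot(at, m, ylim = range(lo, hi), pch = 19, xaxt = "n",
                 xlab = "", ylab = ylab, ...)
  graphics::arrows(at, lo, at, hi, angle = 90, code = 3, length = 0.04)
  graphics::axis(1, at = at, labels = tab$label, las = 2, cex.axis = 0.7)
  invisible(tab)
}

#' Posterior-predictive datasets from a fitted model
#'
#' Draws `nsim` parameter vectors from the posterior and simulates one
#' replicate of the observed design from each, including trial-level
#' drift/nondecision variability.
#'
#' @param object fitted `hdm` object.
#' @param nsim number of replicate datasets.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of data.frames with columns `participant_id`, `face_prime`,
#'   `word_valence`, `choice`, `rt_ms`.
#' @export
simulate.hdm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  tr <- object$model$trials
  P <- object$model$P
  labels <- object$conditions$label
  nd <- object$config$chains * object$config$draws
  idx <- sample.int(nd, nsim, replace = nsim > nd)
  flat <- matrix(object$draws, nrow = nd, ncol = object$model$npar)
  colnames(flat) <- object$par_names
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    par <- flat[idx[s], ]
    alpha <- par[paste0("alpha[", object$participants, "]")]
    eta <- par["eta"]; chi <- par["chi"]
    nu <- matrix(par[22 + P + seq_len(8 * P)], nrow = P, byrow = TRUE)
    theta <- matrix(par[22 + 9 * P + seq_len(8 * P)], nrow = P, byrow = TRUE)
    p1 <- tr$pidx + 1L; c1 <- tr$cidx + 1L
    dr <- rnorm(nrow(tr), nu[cbind(p1, c1)], eta)
    ta <- rnorm(nrow(tr), theta[cbind(p1, c1)], chi)
    while (any(bad <- ta < 0))
      ta[bad] <- rnorm(sum(bad), theta[cbind(p1, c1)][bad], chi)
    sim <- rwiener(nrow(tr), alpha[p1], 0.5, dr, ta,
                   seed = runif(1) * 2^31)
    out[[s]] <- data.frame(
      participant_id = object$participants[p1],
      face_prime = object$conditions$face[c1],
      word_valence = object$conditions$valence[c1],
      choice = as.integer(sim$boundary == "upper"),
      rt_ms = sim$rt * 1000)
  }
  out
}

#' Long-format posterior draws
#'
#' @param x fitted `hdm` object.
#' @param ... unused.
#' @return data.frame with columns `chain`, `draw`, `parameter`, `value`.
#' @export
as.data.frame.hdm <- function(x, ...) {
  d <- x$draws
  data.frame(
    chain = rep(seq_len(dim(d)[1]), times = dim(d)[2] * dim(d)[3]),
    draw = rep(rep(seq_len(dim(d)[2]), each = dim(d)[1]), times = dim(d)[3]),
    parameter = rep(dimnames(d)[[3]], each = dim(d)[1] * dim(d)[2]),
    value = as.numeric(d))
}

#' Write posterior draws to CSV
#'
#' @param fit fitted `hdm` object.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_draws <- function(fit, path) {
  write.csv(as.data.frame(fit), path, row.names = FALSE)
  invisible(path)
}
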