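#' @useDynLib wienerhdm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif quantile sd median qlogis integrate setNames
#'   aggregate complete.cases cor qnorm rbinom var
#' @importFrom utils write.csv read.csv head modifyList
NULL

# Parameter convention used throughout: boundary separation `alpha` (> 0,
# evidence units), relative starting point `beta` in (0, 1), drift rate
# `delta` (evidence units per second), nondecision time `tau` (seconds,
# >= 0). The within-trial diffusion coefficient is fixed at s = 1 and is
# never a free parameter.

check_wiener_params <- function(alpha, beta, delta, tau = 0) {
  vals <- c(alpha = alpha, beta = beta, delta = delta, tau = tau)
  if (!all(is.finite(vals)))
    stop("Wiener parameters must be finite", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (beta <= 0 || beta >= 1) stop("`beta` must be in (0, 1)", call. = FALSE)
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  invisible(TRUE)
}

#' Probability of absorption at the upper boundary
#'
#' Analytic (gambler's-ruin) probability that a Wiener diffusion with drift
#' `delta`, boundary separation `alpha` and relative starting point `beta`
#' (diffusion coefficient s = 1) is absorbed at the upper boundary. The
#' drift-free limit is evaluated by its series expansion, so the function is
#' continuous at `delta = 0` where it equals `beta`.
#'
#' @param alpha boundary separation (> 0).
#' @param beta relative starting point in (0, 1).
#' @param delta drift rate.
#' @return probability in \[0, 1\] of hitting the upper boundary.
#' @examples
#' choice_probability(alpha = 2, beta = 0.5, delta = 1)  # 1 / (1 + exp(-2))
#' @export
choice_probability <- function(alpha, beta, delta) {
  check_wiener_params(alpha, beta, delta)
  x <- 2 * delta * alpha
  if (x == 0) return(beta)
  if (x >= 700) return(1)           # expm1(-x) saturates at -1
  if (x <= -700) return(exp(x * (1 - beta)))
  p <- expm1(-x * beta) / expm1(-x)
  min(max(p, 0), 1)
}

#' Expected decision time of a Wiener first passage
#'
#' Mean first-passage time of the decision process (excluding the
#' nondecision time `tau`), from Wald's identity:
#' `E[T] = (alpha * p_upper - alpha * beta) / delta` for `delta != 0` and
#' `alpha^2 * beta * (1 - beta)` in the drift-free limit. Small drifts are
#' evaluated by the series expansion around `delta = 0` to avoid
#' catastrophic cancellation.
#'
#' @inheritParams choice_probability
#' @return expected decision time in seconds.
#' @examples
#' mean_decision_time(alpha = 1, beta = 0.5, delta = 2)  # 0.25 * tanh(1)
#' @export
mean_decision_time <- function(alpha, beta, delta) {
  check_wiener_params(alpha, beta, delta)
  x <- 2 * delta * alpha
  if (abs(x) < 1e-5) {
    # E[T] = a^2 b(1-b) + delta a^3 b(1/3 - b + 2b^2/3) + O(delta^2)
    return(alpha^2 * beta * (1 - beta) +
             delta * alpha^3 * beta * (1 / 3 - beta + 2 * beta^2 / 3))
  }
  p_up <- choice_probability(alpha, beta, delta)
  (alpha * p_up - alpha * beta) / delta
}

#' Wiener first-passage-time density
#'
#' Defective density (per second) of responding at total time `t` at the
#' given boundary, for a Wiener diffusion with the stated parameters. The
#' density is zero for `t <= tau`. Internally the standardised driftless
#' density is evaluated by the small-time or the large-time series
#' expansion, choosing whichever needs fewer terms for a truncation error
#' at most `eps` (well below the 1e-7 accuracy contract at the default).
#' The lower-boundary density uses the standard reflection
#' `(alpha, 1 - beta, -delta)`.
#'
#' @inheritParams choice_probability
#' @param t vector of total response times (seconds).
#' @param tau nondecision time in seconds (>= 0).
#' @param boundary `"upper"` or `"lower"` (recycled along `t`).
#' @param eps truncation error bound for the series.
#' @param expansion `"auto"` picks the cheaper series; `"small"` / `"large"`
#'   force one expansion (used to verify agreement at the switch point).
#' @return vector of density values, same length as `t`.
#' @export
dwiener <- function(t, alpha, beta, delta, tau,
                    boundary = "upper", eps = 1e-10,
                    expansion = c("auto", "small", "large")) {
  check_wiener_params(alpha, beta, delta, tau)
  if (!all(is.finite(t))) stop("`t` must be finite", call. = FALSE)
  expansion <- match.arg(expansion)
  boundary <- rep_len(boundary, length(t))
  if (!all(boundary %in% c("upper", "lower")))
    stop("`boundary` must be \"upper\" or \"lower\"", call. = FALSE)
  method <- match(expansion, c("auto", "small", "large")) - 1L
  .dwiener_cpp(as.numeric(t), alpha, beta, delta, tau,
               boundary == "upper", eps, method)
}

#' Joint log-likelihood of first-passage observations
#'
#' Sum of log Wiener first-passage densities over a set of (rt, boundary)
#' observations. An empty set returns 0 (the neutral element of the sum);
#' any observation with `rt <= tau` has density zero and makes the result
#' `-Inf`.
#'
#' @inheritParams dwiener
#' @param rt vector of response times (seconds, > 0).
#' @param boundary character vector (`"upper"`/`"lower"`), recycled.
#' @return scalar log-likelihood.
#' @export
wiener_loglik <- function(rt, boundary, alpha, beta, delta, tau) {
  if (length(rt) == 0L) return(0)
  if (any(rt <= 0)) stop("all `rt` must be > 0", call. = FALSE)
  d <- dwiener(rt, alpha, beta, delta, tau, boundary = boundary)
  if (any(d <= 0)) return(-Inf)
  sum(log(d))
}

#' Simulate Wiener first-passage trials
#'
#' Draws `n` independent (rt, boundary) pairs by Euler--Maruyama integration
#' of the diffusion path (default step `dt = 1e-4` s), with the
#' Broadie--Glasserman--Kou continuity correction so that the leading-order
#' discrete-monitoring bias in first-passage times cancels. Response time is
#' `tau` plus the first-passage time. Parameters may be vectors (recycled
#' over trials), which is how trial-level drift/nondecision variability is
#' simulated.
#'
#' @inheritParams dwiener
#' @param n number of trials (>= 1).
#' @param seed integer seed for the simulator's own RNG stream; if `NULL`, a
#'   seed is drawn from R's RNG (so `set.seed()` still controls the result).
#' @param dt Euler time step in seconds.
#' @return data.frame with columns `rt` (seconds) and `boundary`
#'   (`"upper"`/`"lower"`).
#' @examples
#' sim <- rwiener(500, alpha = 2, beta = 0.5, delta = 1, tau = 0.3, seed = 1)
#' mean(sim$boundary == "upper")
#' @export
rwiener <- function(n, alpha, beta, delta, tau, seed = NULL, dt = 1e-4) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("`n` must be a single count >= 1", call. = FALSE)
  if (!all(is.finite(alpha)) || !all(is.finite(beta)) ||
      !all(is.finite(delta)) || !all(is.finite(tau)))
    stop("Wiener parameters must be finite", call. = FALSE)
  if (any(alpha <= 0) || any(beta <= 0) || any(beta >= 1) || any(tau < 0))
    stop("invalid Wiener parameters", call. = FALSE)
  if (is.null(seed)) seed <- runif(1) * 2^31
  res <- .rwiener_cpp(as.integer(n), as.numeric(alpha), as.numeric(beta),
                      as.numeric(delta), as.numeric(tau),
                      dt, as.numeric(seed))
  data.frame(rt = res$rt,
             boundary = ifelse(res$upper == 1L, "upper", "lower"))
}

# Gauss-Hermite nodes/weights (probabilists', normalised against the standard
# normal) used to integrate over trial-level nondecision variability.
gauss_hermite_normal <- function(k) {
  h <- switch(as.character(k),
    "1" = list(x = 0, w = 1),
    "3" = list(x = c(-sqrt(3), 0, sqrt(3)), w = c(1, 4, 1) / 6),
    "5" = list(
      x = c(-sqrt(5 + sqrt(10)), -sqrt(5 - sqrt(10)), 0,
            sqrt(5 - sqrt(10)), sqrt(5 + sqrt(10))),
      w = c(0.011257411327720688, 0.2220759220056126, 8 / 15,
            0.2220759220056126, 0.011257411327720688)),
    "7" = list(
      x = c(-3.7504397177257425, -2.3667594107345415, -1.1544053947399682, 0,
            1.1544053947399682, 2.3667594107345415, 3.7504397177257425),
      w = c(0.0005482688559722185, 0.0307571239675865, 0.2401231786050126,
            0.45714285714285713, 0.2401231786050126, 0.0307571239675865,
            0.0005482688559722185)),
    stop("Gauss-Hermite rule available for k in {1, 3, 5, 7}", call. = FALSE))
  h
}

# Marginal trial density used by the hierarchical likelihood: drift
# ~ N(mu, eta^2) integrated analytically, nondecision ~ N(theta, chi^2) by
# Gauss-Hermite quadrature (beta fixed at 0.5). Exposed internally for tests.
dwiener_marginal <- function(t, alpha, mu, eta, theta, chi,
                             boundary = "upper", gh_points = 5, eps = 1e-10) {
  gh <- if (chi > 0) gauss_hermite_normal(gh_points) else list(x = 0, w = 1)
  .dwiener_marg_cpp(as.numeric(t), alpha, mu, eta, theta, chi,
                    rep_len(boundary, length(t)) == "upper",
                    gh$x, gh$w, eps)
}
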