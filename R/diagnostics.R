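#' Highest density interval of a sample
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the `n`
#' sorted draws -- for unimodal posteriors this estimates the highest
#' density interval, the smallest region holding the stated proportion of
#' posterior mass. Ties between equally short windows are broken in favour
#' of the lowest interval.
#'
#' @param x numeric vector of posterior draws (at least 20).
#' @param mass probability mass to cover, in (0, 1).
#' @return numeric vector `c(lower, upper)`.
#' @examples
#' set.seed(1)
#' hdi(rnorm(1e4))  # close to c(-1.96, 1.96)
#' @export
hdi <- function(x, mass = 0.95) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 20) stop("need at least 20 draws for an HDI", call. = FALSE)
  if (!is.finite(mass) || mass <= 0 || mass >= 1)
    stop("`mass` must be in (0, 1)", call. = FALSE)
  x <- sort(x)
  k <- ceiling(mass * n)
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[k:n] - x[1:(n - k + 1)]
  i <- which.min(widths)  # which.min takes the first (lowest) on ties
  c(x[i], x[i + k - 1])
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Gelman--Rubin convergence diagnostic: each chain is split in half and the
#' between- to within-chain variance ratio is formed over the resulting
#' sub-chains. Values near 1 indicate that the chains have mixed; the
#' conventional acceptance threshold is 1.1. Chains with zero within-chain
#' variance return 1 when they agree on the same constant (and `Inf` when
#' they are stuck at different constants).
#'
#' @param x a draws-by-chains matrix, or a fitted [hdm()] object.
#' @param ... unused.
#' @return a scalar for a matrix; a named vector (one entry per model
#'   parameter) for an `hdm` fit.
#' @export
rhat <- function(x, ...) UseMethod("rhat")

#' @rdname rhat
#' @export
rhat.default <- function(x, ...) {
  x <- as.matrix(x)
  if (ncol(x) < 2) stop("R-hat needs at least 2 chains", call. = FALSE)
  if (nrow(x) < 10) stop("R-hat needs at least 10 draws per chain", call. = FALSE)
  n2 <- floor(nrow(x) / 2)
  halves <- cbind(x[seq_len(n2), , drop = FALSE],
                  x[seq(nrow(x) - n2 + 1, nrow(x)), , drop = FALSE])
  m <- ncol(halves); n <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, var)
  W <- mean(vars)
  B <- n * var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @rdname rhat
#' @export
rhat.hdm <- function(x, ...) {
  d <- x$draws  # chains x draws x params
  vapply(seq_len(dim(d)[3]),
         function(j) rhat.default(t(d[, , j, drop = TRUE])),
         numeric(1)) |> setNames(dimnames(d)[[3]])
}

#' @rdname rhat
#' @export
gelman_rubin <- function(x, ...) rhat(x, ...)
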