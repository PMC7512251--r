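# Marginal posterior for a single variance changepoint.
#
# Model: y_t ~ N(0, sigma0^2) for t <= tau, N(0, delta * sigma0^2) for
# t > tau. Integrating the likelihood against an improper uniform prior on
# delta and a Jeffreys prior 1/sigma0 on the base scale leaves a discrete
# posterior over tau that depends on the data only through the left and right
# sums of squares:
#
#   pi(tau | y) ∝ pi(tau) * Gamma((tau+2)/2) * Gamma((N-tau-2)/2)
#                 * S_left(tau)^(-(tau+2)/2) * S_right(tau)^(-(N-tau-2)/2)
#
# which converges for tau >= 1 and N - tau >= 3. Everything is computed in
# log space with lgamma; unnormalized kernels are never exponentiated.

#' Prefix sums of squared amplitudes
#'
#' The sufficient statistics for every posterior in the package: cumulative
#' sums of squared amplitudes. `prefix[t + 1]` is the sum of the first `t`
#' squared samples, so the left and right sums of squares at a candidate cut
#' `t` are `prefix[t + 1]` and `prefix[n + 1] - prefix[t + 1]`.
#'
#' @param x a [seg_signal()] or numeric vector.
#' @return An object of class `square_sums`: list with `prefix` (length
#'   `n + 1`, starting at 0) and `n`.
#' @examples
#' square_sums(c(1, -1, 2))$prefix  # 0 1 2 6
#' @export
square_sums <- function(x) {
  y <- as_samples(x)
  if (length(y) == 0) stop("empty signal")
  if (any(!is.finite(y))) stop("signal samples must be finite")
  structure(list(prefix = c(0, cumsum(y * y)), n = length(y)),
            class = "square_sums")
}

# square_sums restricted to samples lo..hi of a precomputed prefix vector.
square_sums_range <- function(prefix, lo, hi) {
  structure(list(prefix = prefix[lo:(hi + 1)] - prefix[lo], n = hi - lo + 1),
            class = "square_sums")
}

#' Log kernel of the marginal changepoint posterior
#'
#' Evaluates the log of the (unnormalized) marginal posterior of a single
#' variance changepoint at candidate cuts `t`, where `t` is the length of the
#' left segment (samples `1..t` left, `t+1..n` right). Vectorized over `t`.
#'
#' @param ss a [square_sums()] object.
#' @param t integer candidate cut(s), each with `t >= 1` and `n - t >= 3`.
#' @param log_prior log prior mass at each `t` (default uniform, i.e. 0).
#' @return Numeric vector of log kernel values; `-Inf` where a side has zero
#'   sum of squares.
#' @export
log_changepoint_kernel <- function(ss, t, log_prior = 0) {
  stopifnot(inherits(ss, "square_sums"))
  n <- ss$n
  if (any(t < 1 | t > n - 3)) {
    stop("candidate cut outside the support [1, n - 3]")
  }
  s_left <- ss$prefix[t + 1]
  s_right <- ss$prefix[n + 1] - ss$prefix[t + 1]
  out <- rep(-Inf, length(t))
  ok <- s_left > 0 & s_right > 0
  if (any(ok)) {
    tt <- t[ok]
    out[ok] <- log_prior[if (length(log_prior) > 1) ok else 1] +
      lgamma((tt + 2) / 2) + lgamma((n - tt - 2) / 2) -
      ((tt + 2) / 2) * log(s_left[ok]) -
      ((n - tt - 2) / 2) * log(s_right[ok])
  }
  out
}

#' Grid evaluation and MAP estimate of the changepoint posterior
#'
#' Evaluates the marginal changepoint posterior on a grid of equally spaced
#' candidates (`resolution`, `2*resolution`, ...) intersected with the valid
#' support, and locates the maximum-a-posteriori cut. The support excludes
#' `tmin` samples at each edge, where small-sample variance estimates produce
#' spurious posterior peaks.
#'
#' @param x a [seg_signal()], numeric vector, or [square_sums()] object.
#' @param resolution grid stride in samples, a positive integer;
#'   `resolution = 1` evaluates every admissible cut.
#' @param tmin minimum number of samples required on each side of a cut
#'   (default 5, minimum 3).
#' @param log_prior optional function mapping candidate cuts to log prior
#'   values; default is a uniform prior over the support.
#' @return An object of class `changepoint_posterior` with elements `grid`,
#'   `log_kernel`, `log_norm` (log normalizing constant over the grid), `map`
#'   (smallest grid point attaining the maximum) and `n`; or `NULL` when the
#'   support intersected with the grid is empty (segment too short to cut).
#' @examples
#' sig <- simulate_piecewise(piecewise_spec(1000, c(1, 2), n = 2000), seed = 1)
#' post <- changepoint_map(sig)
#' post$map  # close to 1000
#' @export
changepoint_map <- function(x, resolution = 1, tmin = 5, log_prior = NULL) {
  ss <- if (inherits(x, "square_sums")) x else square_sums(x)
  if (resolution < 1 || resolution != round(resolution)) {
    stop("'resolution' must be a positive integer")
  }
  if (tmin < 3) stop("'tmin' must be at least 3")
  n <- ss$n
  lo <- max(tmin, 1)
  hi <- n - max(tmin, 3)
  if (hi < lo) return(NULL)
  first <- resolution * ceiling(lo / resolution)
  if (first > hi) return(NULL)
  grid <- seq.int(first, hi, by = resolution)

  lp <- if (is.null(log_prior)) 0 else log_prior(grid)
  log_kernel <- log_changepoint_kernel(ss, grid, log_prior = lp)
  if (all(!is.finite(log_kernel))) return(NULL)

  structure(list(
    grid = grid,
    log_kernel = log_kernel,
    log_norm = logsumexp(log_kernel),
    map = grid[which.max(log_kernel)],
    n = n
  ), class = "changepoint_posterior")
}

#' Normalized posterior probabilities over the candidate grid
#'
#' @param post a `changepoint_posterior` from [changepoint_map()].
#' @return Data frame with columns `index` and `probability` (summing to 1
#'   over the grid).
#' @export
changepoint_probabilities <- function(post) {
  stopifnot(inherits(post, "changepoint_posterior"))
  data.frame(index = post$grid,
             probability = exp(post$log_kernel - post$log_norm))
}

#' @export
print.changepoint_posterior <- function(x, ...) {
  cat(sprintf("<changepoint_posterior> n = %d, %d candidate cuts, MAP = %d\n",
              x$n, length(x$grid), x$map))
  invisible(x)
}
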