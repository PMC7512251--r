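#' Signal container
#'
#' A minimal container for a single-channel, discretely sampled signal:
#' the amplitude samples (dimensionless) and the sampling rate in Hz.
#' All analysis functions in the package accept either a `seg_signal` or a
#' plain numeric vector.
#'
#' @param samples numeric vector of amplitudes.
#' @param fs sampling rate in Hz (samples per second); must be positive.
#' @return An object of class `seg_signal`: a list with elements `samples`,
#'   `fs` and `n` (number of samples). Duration in seconds is `n / fs`.
#' @examples
#' s <- seg_signal(rnorm(100), fs = 100)
#' s$n / s$fs  # 1 second
#' @export
seg_signal <- function(samples, fs = 1) {
  samples <- as.numeric(samples)
  if (anyNA(samples)) stop("signal samples must not contain NA")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stop("'fs' must be a single positive number")
  }
  structure(list(samples = samples, fs = fs, n = length(samples)),
            class = "seg_signal")
}

#' @export
print.seg_signal <- function(x, ...) {
  cat(sprintf("<seg_signal> %d samples @ %g Hz (%.3f s)\n",
              x$n, x$fs, x$n / x$fs))
  invisible(x)
}

#' @export
length.seg_signal <- function(x) x$n

#' Piecewise-variance signal specification
#'
#' Describes a zero-mean Gaussian signal whose standard deviation is piecewise
#' constant: `boundaries` are the last sample indices (1-based) of each
#' segment except the final one, and `sigmas` the per-segment standard
#' deviations. The defaults describe the five-segment benchmark profile used
#' throughout the package's tests: 20,000 samples with variances
#' 1, 1.1, 1, 1.5, 1 switching at samples 5000, 10,000, 12,000 and 15,000.
#'
#' @param boundaries strictly increasing integer sample indices in `(0, n)`;
#'   samples with index `<= boundaries[i]` and `> boundaries[i-1]` belong to
#'   segment `i`.
#' @param sigmas per-segment standard deviations; must be positive and of
#'   length `length(boundaries) + 1`.
#' @param n total number of samples.
#' @param fs sampling rate in Hz.
#' @return An object of class `piecewise_spec`.
#' @seealso [simulate_piecewise()]
#' @export
piecewise_spec <- function(boundaries = c(5000, 10000, 12000, 15000),
                           sigmas = sqrt(c(1, 1.1, 1, 1.5, 1)),
                           n = 20000, fs = 1) {
  boundaries <- as.numeric(boundaries)
  sigmas <- as.numeric(sigmas)
  if (length(sigmas) != length(boundaries) + 1) {
    stop("length(sigmas) must equal length(boundaries) + 1")
  }
  if (any(sigmas <= 0) || anyNA(sigmas)) stop("all sigmas must be positive")
  if (length(boundaries) > 0) {
    if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
    if (any(boundaries <= 0) || any(boundaries >= n)) {
      stop("boundaries must lie strictly inside (0, n)")
    }
    if (any(boundaries != round(boundaries))) stop("boundaries must be integers")
  }
  if (n < 0) stop("'n' must be non-negative")
  structure(list(boundaries = boundaries, sigmas = sigmas, n = n, fs = fs),
            class = "piecewise_spec")
}

#' @export
print.piecewise_spec <- function(x, ...) {
  cat(sprintf("<piecewise_spec> n = %d, %d segment(s)\n", x$n,
              length(x$sigmas)))
  ends <- c(x$boundaries, x$n)
  starts <- c(1, head(ends, -1) + 1)
  for (i in seq_along(x$sigmas)) {
    cat(sprintf("  [%d, %d]  sd = %g\n", starts[i], ends[i], x$sigmas[i]))
  }
  invisible(x)
}

#' Simulate a piecewise-variance Gaussian signal
#'
#' Draws independent zero-mean Gaussian samples whose standard deviation
#' follows a [piecewise_spec()]. Used both as a benchmark generator for the
#' segmentation algorithm and as a test-signal factory.
#'
#' @param spec a [piecewise_spec()].
#' @param seed optional integer seed; identical `(spec, seed)` pairs give
#'   bit-identical signals.
#' @return A [seg_signal()] of length `spec$n`.
#' @examples
#' sig <- simulate_piecewise(piecewise_spec(500, c(1, 2), n = 1000), seed = 1)
#' var(sig$samples[1:500]); var(sig$samples[501:1000])
#' @export
simulate_piecewise <- function(spec, seed = NULL) {
  if (!inherits(spec, "piecewise_spec")) stop("'spec' must be a piecewise_spec")
  if (!is.null(seed)) set.seed(seed)
  ends <- c(spec$boundaries, spec$n)
  lengths <- diff(c(0, ends))
  samples <- rnorm(spec$n, mean = 0, sd = rep(spec$sigmas, times = lengths))
  seg_signal(samples, fs = spec$fs)
}
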