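# Recursive sequential segmentation: estimate one cut by MAP, test variance
# equality of the two halves with the FBST, recurse on both halves while the
# e-value favoring equal variances stays below alpha.

#' Sequential Bayesian segmentation of a signal
#'
#' Recursively segments a zero-mean signal at variance changes. On each
#' segment of length at least `nmin`, the single-cut marginal posterior is
#' evaluated on a grid of stride `resolution` and its MAP cut splits the
#' segment in two; the Full Bayesian Significance Test then judges whether
#' the two halves share a variance. If the e-value favoring equality is at
#' least `alpha` the segment is left whole; otherwise the cut is kept and
#' both halves are segmented recursively.
#'
#' The FBST always uses the full sufficient statistics of each half;
#' `resolution` coarsens only the candidate-cut grid. Reproducibility: the
#' master `seed` deterministically derives one child seed per FBST call in
#' depth-first order, so a fixed `(signal, config, seed)` triple always gives
#' the same result.
#'
#' @param x a [seg_signal()] or numeric vector.
#' @param fs sampling rate in Hz (used only to report changepoints in
#'   seconds); defaults to the signal's own rate, else 1.
#' @param beta scale of the Laplace prior on the variance ratio. Smaller
#'   values concentrate the prior on "no change" and yield fewer segments;
#'   values around 1 suit short unit-scale arrays, values around `3e-5` suit
#'   minutes-long audio at typical hydrophone rates.
#' @param alpha evidence threshold in (0, 1): split while `ev(H0) < alpha`.
#' @param nmin minimum segment length in samples; segments shorter than this
#'   are never tested (default 1000; for audio, one second of samples is a
#'   natural choice).
#' @param resolution candidate-grid stride in samples (default 1).
#' @param tmin edge margin: minimum samples on each side of a candidate cut.
#'   Defaults to `floor(nmin / 2)`, the widest margin compatible with `nmin`:
#'   candidate cuts leaving fewer samples than this on a side are excluded,
#'   which suppresses the spurious small-sample posterior spikes that
#'   otherwise appear at segment edges and abort the recursion early.
#' @param n_samples,n_burn Metropolis-Hastings sample sizes per FBST call.
#' @param seed master integer seed.
#' @param demean subtract the global sample mean before segmenting (default
#'   `FALSE`; the model assumes zero-mean input).
#' @return An object of class `seqseg_result`: list with `changepoints`
#'   (strictly increasing sample indices; a changepoint `t` means samples
#'   `1..t` end a segment), `evidences` (data frame with the e-value that
#'   licensed each kept cut, in cut order), `n_tests` (total FBST
#'   evaluations), `segments` (data frame of start/end indices tiling
#'   `1..n`), `n`, `fs` and `config`.
#' @examples
#' sig <- simulate_piecewise(piecewise_spec(2000, c(1, 2), n = 4000), seed = 1)
#' res <- seqseg(sig, beta = 1, alpha = 0.01, nmin = 500,
#'               n_samples = 2000, n_burn = 2000, seed = 1)
#' res$changepoints  # close to 2000
#' @export
seqseg <- function(x, fs = NULL, beta = 3e-5, alpha = 0.01, nmin = 1000,
                   resolution = 1, tmin = NULL, n_samples = 10000,
                   n_burn = 10000, seed = NULL, demean = FALSE) {
  fs <- signal_fs(x, fs)
  y <- as_samples(x)
  if (is.null(tmin)) tmin <- max(3, floor(nmin / 2))
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)")
  }
  if (beta <= 0) stop("'beta' must be positive")
  if (nmin < 2 * tmin) stop("'nmin' must be at least 2 * tmin")
  if (demean) y <- y - mean(y)
  n <- length(y)
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)

  prefix <- c(0, cumsum(y * y))
  state <- new.env(parent = emptyenv())
  state$n_tests <- 0L
  state$call_idx <- 0L
  state$cuts <- numeric(0)
  state$evs <- numeric(0)

  recurse <- function(lo, hi) {
    len <- hi - lo + 1
    if (len < nmin) return(integer(0))
    ss <- square_sums_range(prefix, lo, hi)
    post <- changepoint_map(ss, resolution = resolution, tmin = tmin)
    if (is.null(post)) return(integer(0))
    t_local <- post$map
    left <- list(n = t_local, ss = ss$prefix[t_local + 1])
    right <- list(n = len - t_local, ss = ss$prefix[len + 1] - ss$prefix[t_local + 1])
    if (left$ss <= 0 || right$ss <= 0) {
      warning("segment with zero sum of squares treated as unsplittable")
      return(integer(0))
    }
    state$call_idx <- state$call_idx + 1L
    child_seed <- derive_seed(seed, state$call_idx)
    res <- fbst_evidence(left, right, beta, n_samples = n_samples,
                         n_burn = n_burn, seed = child_seed)
    state$n_tests <- state$n_tests + 1L
    if (res$ev_h0 >= alpha) return(integer(0))
    cut_abs <- lo + t_local - 1
    state$cuts <- c(state$cuts, cut_abs)
    state$evs <- c(state$evs, res$ev_h0)
    c(recurse(lo, cut_abs), cut_abs, recurse(cut_abs + 1, hi))
  }

  changepoints <- if (n >= 1) recurse(1, n) else integer(0)
  new_segmentation(changepoints, n = n, fs = fs,
                   evidences = data.frame(changepoint = state$cuts,
                                          ev_h0 = state$evs),
                   n_tests = state$n_tests,
                   method = "seqseg",
                   config = list(beta = beta, alpha = alpha, nmin = nmin,
                                 resolution = resolution, tmin = tmin,
                                 n_samples = n_samples, n_burn = n_burn,
                                 seed = seed, demean = demean))
}

#' Test equality of variances between two signal halves
#'
#' Convenience wrapper around [fbst_evidence()] operating on raw halves, as
#' used by the recursion's stopping rule: computes each half's sufficient
#' statistics and compares the resulting e-value with `alpha`.
#'
#' @param left,right numeric vectors or [seg_signal()]s (nonempty).
#' @param beta Laplace prior scale.
#' @param alpha evidence threshold.
#' @inheritParams mh_sample
#' @return List with `reject_h0` (`TRUE` when `ev_h0 < alpha`, i.e. the
#'   variances are judged different and a split is warranted) and `fbst`
#'   (the full [fbst_evidence()] result). Degenerate halves (zero sum of
#'   squares) return `reject_h0 = FALSE` with a degenerate-marked result.
#' @export
variance_equal_test <- function(left, right, beta, alpha = 0.01,
                                n_samples = 10000, n_burn = 10000,
                                seed = NULL) {
  ls <- segment_stats(left)
  rs <- segment_stats(right)
  if (ls$ss <= 0 || rs$ss <= 0) {
    return(list(reject_h0 = FALSE,
                fbst = structure(list(ev_h0 = NA_real_, degenerate = TRUE),
                                 class = "fbst")))
  }
  res <- fbst_evidence(ls, rs, beta, n_samples = n_samples, n_burn = n_burn,
                       seed = seed)
  list(reject_h0 = res$ev_h0 < alpha, fbst = res)
}

# Shared result container for seqseg and the peak-detection baseline.
new_segmentation <- function(changepoints, n, fs, evidences = NULL,
                             n_tests = 0L, method = "seqseg",
                             config = list()) {
  changepoints <- sort(as.numeric(changepoints))
  if (length(changepoints) > 0 &&
      (any(changepoints < 1) || any(changepoints >= n))) {
    stop("changepoints must lie in [1, n - 1]")
  }
  starts <- c(1, changepoints + 1)
  ends <- c(changepoints, n)
  structure(list(
    changepoints = changepoints,
    evidences = evidences,
    n_tests = n_tests,
    segments = data.frame(start = starts, end = ends),
    n = n, fs = fs, method = method, config = config
  ), class = "seqseg_result")
}

#' @export
print.seqseg_result <- function(x, ...) {
  cat(sprintf("<seqseg_result> method = %s, %d samples, %d segment(s)\n",
              x$method, x$n, nrow(x$segments)))
  if (length(x$changepoints) > 0) {
    cat("  changepoints (samples):", paste(x$changepoints, collapse = ", "),
        "\n")
    if (x$fs != 1) {
      cat("  changepoints (seconds):",
          paste(sprintf("%.3f", x$changepoints / x$fs), collapse = ", "), "\n")
    }
  }
  if (!is.null(x$evidences) && nrow(x$evidences) > 0) {
    cat("  e-values at kept cuts:",
        paste(sprintf("%.4g", x$evidences$ev_h0), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.seqseg_result <- function(x, ...) {
  ev <- rep(NA_real_, length(x$changepoints))
  if (!is.null(x$evidences) && nrow(x$evidences) > 0) {
    m <- match(x$changepoints, x$evidences$changepoint)
    ev <- x$evidences$ev_h0[m]
  }
  data.frame(changepoint_index = x$changepoints,
             changepoint_seconds = x$changepoints / x$fs,
             ev_h0 = ev)
}

#' Plot a segmentation result over the waveform
#'
#' @param x a `seqseg_result`.
#' @param y a [seg_signal()] or numeric vector (the segmented signal).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.seqseg_result <- function(x, y, ...) {
  samples <- as_samples(y)
  tt <- seq_along(samples) / x$fs
  graphics::plot(tt, samples, type = "l", col = "grey40",
                 xlab = if (x$fs == 1) "sample" else "time (s)",
                 ylab = "amplitude", ...)
  graphics::abline(v = x$changepoints / x$fs, col = "red", lty = 2)
  invisible(x)
}

#' Serialize a segmentation result
#'
#' Writes the canonical JSON record (configuration echo plus changepoints in
#' samples and seconds and per-cut e-values) and, optionally, a derived CSV.
#'
#' @param x a `seqseg_result`.
#' @param json_path output path for the JSON record.
#' @param csv_path optional output path for the CSV table.
#' @return `json_path`, invisibly.
#' @export
write_segmentation <- function(x, json_path, csv_path = NULL) {
  stopifnot(inherits(x, "seqseg_result"))
  df <- as.data.frame(x)
  jsonlite::write_json(list(
    method = x$method,
    n = x$n, fs = x$fs,
    config = x$config,
    n_tests = x$n_tests,
    changepoint_index = df$changepoint_index,
    changepoint_seconds = df$changepoint_seconds,
    ev_h0 = df$ev_h0
  ), json_path, auto_unbox = TRUE, digits = NA, null = "null")
  if (!is.null(csv_path)) write.csv(df, csv_path, row.names = FALSE)
  invisible(json_path)
}
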