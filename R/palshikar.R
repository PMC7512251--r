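# Palshikar peak-detection baseline: local spike functions S1/S2/S3 over
# one-sided windows of width k, a global mean + h*sd threshold over the
# positive scores, and a within-window prune keeping the larger score.

#' Local peak scores (Palshikar S-functions)
#'
#' Computes, at each evaluation point `t`, a spike score built from signed
#' differences between `y[t]` and its windowed neighbours (indices `j` with
#' `0 < |t - j| < k`):
#'
#' * `S1`: average of the maximum signed difference to the left and to the
#'   right (`y[t]` minus each side's minimum);
#' * `S2`: average of the mean signed differences to the left and right;
#' * `S3`: average of the signed differences between `y[t]` and each side's
#'   mean. (`S2` and `S3` are algebraically identical for a common window;
#'   both are kept for interface completeness.)
#'
#' Windows at the signal edges are truncated to the available samples; points
#' where a side is entirely missing (the first and last evaluation points)
#' score 0.
#'
#' @param x a [seg_signal()] or numeric vector.
#' @param variant one of `"S1"`, `"S2"`, `"S3"`.
#' @param k window width in samples (neighbours up to `k - 1` away).
#' @param resolution evaluation stride: scores are computed at indices
#'   `resolution, 2*resolution, ...`.
#' @param rectify score the absolute amplitudes `|y|` instead of `y`.
#' @return Data frame with columns `index` and `score`.
#' @examples
#' peak_scores(c(0, 0, 5, 0, 0), "S1", k = 2)$score[3]  # 5
#' @export
peak_scores <- function(x, variant = c("S1", "S2", "S3"), k, resolution = 1,
                        rectify = FALSE) {
  variant <- match.arg(variant)
  y <- as_samples(x)
  n <- length(y)
  if (k < 1 || k != round(k)) stop("'k' must be a positive integer")
  if (k >= n) stop("window width 'k' must be smaller than the signal length")
  if (resolution < 1 || resolution != round(resolution)) {
    stop("'resolution' must be a positive integer")
  }
  if (rectify) y <- abs(y)
  idx <- seq.int(resolution, n, by = resolution)

  if (variant == "S1") {
    mins <- window_min_cpp(y, as.integer(idx), as.integer(k))
    left <- y[idx] - mins$left
    right <- y[idx] - mins$right
  } else {
    cy <- c(0, cumsum(y))
    a_l <- pmax(1, idx - k + 1); b_l <- idx - 1
    a_r <- idx + 1;              b_r <- pmin(n, idx + k - 1)
    cnt_l <- b_l - a_l + 1
    cnt_r <- b_r - a_r + 1
    lmean <- ifelse(cnt_l > 0, (cy[b_l + 1] - cy[a_l]) / cnt_l, NA_real_)
    rmean <- ifelse(cnt_r > 0, (cy[b_r + 1] - cy[a_r]) / cnt_r, NA_real_)
    left <- y[idx] - lmean
    right <- y[idx] - rmean
  }
  score <- (left + right) / 2
  score[is.na(left) | is.na(right)] <- 0
  data.frame(index = idx, score = score)
}

#' Detect peaks by global thresholding of spike scores
#'
#' The full baseline pipeline: (1) compute S-function scores; (2) keep points
#' with positive score; (3) compute the mean `m` and standard deviation `s`
#' of the kept scores; (4) retain points with `score - m > h * s`; (5) prune
#' retained points closer than `k` to each other in a left-to-right sweep,
#' keeping the larger score.
#'
#' @inheritParams peak_scores
#' @param h threshold in standard deviations (> 0).
#' @return Sorted integer vector of peak indices (possibly empty).
#' @examples
#' y <- numeric(200); y[c(50, 150)] <- 10
#' detect_peaks(y, "S1", h = 1, k = 20)  # c(50, 150)
#' @export
detect_peaks <- function(x, variant = c("S1", "S2", "S3"), h, k,
                         resolution = 1, rectify = FALSE) {
  variant <- match.arg(variant)
  if (h <= 0) stop("'h' must be positive")
  sc <- peak_scores(x, variant, k = k, resolution = resolution,
                    rectify = rectify)
  pos <- sc[sc$score > 0, , drop = FALSE]
  if (nrow(pos) == 0) return(integer(0))
  m <- mean(pos$score)
  s <- sd(pos$score)
  if (is.na(s)) s <- 0
  # zero spread: all positive scores are equal, so all pass the threshold
  ret <- if (s == 0) pos else pos[pos$score - m > h * s, , drop = FALSE]
  if (nrow(ret) == 0) return(integer(0))

  # left-to-right prune: among points closer than k, keep the larger score
  keep <- integer(0)
  cur <- 1L
  if (nrow(ret) > 1) {
    for (i in 2:nrow(ret)) {
      if (ret$index[i] - ret$index[cur] < k) {
        if (ret$score[i] > ret$score[cur]) cur <- i
      } else {
        keep <- c(keep, cur)
        cur <- i
      }
    }
  }
  keep <- c(keep, cur)
  sort(as.integer(ret$index[keep]))
}

#' Build a segmentation result from detected peaks
#'
#' Treats each peak as a changepoint (a peak at `p` ends the segment
#' `..., p`), giving `length(peaks) + 1` segments tiling `1..n`. The result
#' reuses the `seqseg_result` container so baseline and Bayesian outputs are
#' directly comparable.
#'
#' @param peaks sorted integer peak indices in `[1, n - 1]`.
#' @param n signal length in samples.
#' @param fs sampling rate in Hz.
#' @param config optional configuration echo stored with the result.
#' @return A `seqseg_result` with empty evidences and `method = "palshikar"`.
#' @export
segments_from_peaks <- function(peaks, n, fs = 1, config = list()) {
  peaks <- as.numeric(peaks)
  if (is.unsorted(peaks, strictly = TRUE)) {
    stop("'peaks' must be strictly increasing")
  }
  if (length(peaks) > 0 && (any(peaks < 1) || any(peaks >= n))) {
    stop("peaks must lie in [1, n - 1]")
  }
  new_segmentation(peaks, n = n, fs = fs, evidences = NULL,
                   n_tests = 0L, method = "palshikar", config = config)
}
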