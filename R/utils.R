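# Internal numeric helpers.

# log(sum(exp(x))) without overflow; -Inf-safe.
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Extract a plain numeric sample vector from a numeric vector or seg_signal.
as_samples <- function(x) {
  if (inherits(x, "seg_signal")) return(x$samples)
  if (!is.numeric(x)) stop("expected a numeric vector or a 'seg_signal' object")
  as.numeric(x)
}

signal_fs <- function(x, fs = NULL) {
  if (!is.null(fs)) return(fs)
  if (inherits(x, "seg_signal")) return(x$fs)
  1
}

# Deterministic child seed for the i-th stochastic sub-task of a master seed.
# Kept below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 100003 * as.numeric(i)) %% 2147483647)
}

# Modal (most frequent) value of an integer vector; smallest wins ties.
modal_value <- function(x) {
  tab <- table(x)
  as.numeric(names(tab)[which.max(tab)])
}
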