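# Independent numerical oracles used across the test suite. All are built
# directly from the model's densities (written out here from scratch), not
# from the package's closed forms, so they can arbitrate correctness.

logsumexp_h <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Marginal changepoint posterior by 2-D Gauss-Legendre quadrature of the
# two-variance Gaussian likelihood times a uniform prior on the variance
# ratio and a Jeffreys prior on the base scale, in (u, v) = (log sigma0,
# log delta) coordinates (Jacobian e^{u+v}). Returns the normalized
# posterior over the support t in [tmin, n - max(tmin, 3)].
quad_changepoint_posterior <- function(y, tmin = 5, n_nodes = 240) {
  n <- length(y)
  support <- max(tmin, 1):(n - max(tmin, 3))
  s_hat <- sqrt(mean(y^2))
  gu <- pracma::gaussLegendre(n_nodes, log(s_hat) - 4, log(s_hat) + 3)
  gv <- pracma::gaussLegendre(n_nodes, -12, 12)
  ww <- outer(gu$w, gv$w)
  log_integral <- vapply(support, function(t) {
    s1 <- sum(y[1:t]^2)
    s2 <- sum(y[(t + 1):n]^2)
    lm <- outer(gu$x, gv$x, function(u, v) {
      -n / 2 * log(2 * pi) - n * u - (n - t) / 2 * v -
        s1 / 2 * exp(-2 * u) - s2 / 2 * exp(-2 * u - v) - u + (u + v)
    })
    m <- max(lm)
    m + log(sum(exp(lm - m) * ww))
  }, numeric(1))
  list(support = support,
       probability = exp(log_integral - logsumexp_h(log_integral)))
}

# Full (sigma0, delta) posterior for two segments on a uniform trapezoid
# grid in log coordinates; written out from the two-segment Gaussian
# likelihood, Laplace(1, beta) prior on delta and Jeffreys prior on sigma0.
# Returns the grid, per-cell posterior masses, and the log density at each
# node. A uniform grid (rather than Gauss-Legendre) keeps partial sums of
# cell masses a valid CDF approximation.
quad_full_grid <- function(n1, ss1, n2, ss2, beta, n_nodes = 1000) {
  s_hat <- sqrt((ss1 + ss2) / (n1 + n2))
  d_hat <- (ss2 / n2) / (ss1 / n1)
  hu <- 0.5 + 30 / sqrt(n1 + n2)
  hv <- 1.5 + 60 / sqrt(min(n1, n2))
  u <- seq(log(s_hat) - hu, log(s_hat) + hu, length.out = n_nodes)
  v <- seq(min(log(d_hat) - hv, -0.5), max(log(d_hat) + hv, 0.5),
           length.out = n_nodes)
  wu <- rep(1, n_nodes); wu[c(1, n_nodes)] <- 0.5
  wv <- wu
  # log posterior density in the original (sigma0, delta) coordinates
  lp <- outer(u, v, function(uu, vv) {
    s <- exp(uu); d <- exp(vv)
    -0.5 * (n1 + n2) * log(2 * pi) - abs(d - 1) / beta - log(beta) -
      (n1 + n2 + 1) * log(s) - 0.5 * n2 * log(d) -
      ss1 / (2 * s^2) - ss2 / (2 * d * s^2)
  })
  # cell masses include the Jacobian e^{u+v}
  lmass <- lp + outer(u, v, `+`) + log(outer(wu, wv))
  m <- max(lmass)
  mass <- exp(lmass - m)
  mass <- mass / sum(mass)
  list(u = u, v = v, log_density = lp, mass = mass)
}

# Exact e-value favoring H0: delta = 1 from the quadrature grid, given the
# log density supremum on the H0 manifold.
quad_ev_h0 <- function(n1, ss1, n2, ss2, beta, sup_logdens, n_nodes = 400) {
  g <- quad_full_grid(n1, ss1, n2, ss2, beta, n_nodes)
  1 - sum(g$mass[g$log_density > sup_logdens])
}

# Posterior mean of delta from the quadrature grid.
quad_delta_mean <- function(n1, ss1, n2, ss2, beta, n_nodes = 400) {
  g <- quad_full_grid(n1, ss1, n2, ss2, beta, n_nodes)
  sum(t(g$mass) * exp(g$v))
}

# Marginal CDF of delta from the quadrature grid, as a function.
quad_delta_cdf <- function(n1, ss1, n2, ss2, beta, n_nodes = 400) {
  g <- quad_full_grid(n1, ss1, n2, ss2, beta, n_nodes)
  pv <- colSums(g$mass)
  # CDF at node i: mass strictly below plus half the node's own cell
  approxfun(exp(g$v), cumsum(pv) - pv / 2, yleft = 0, yright = 1, rule = 2)
}

# Benchmark five-segment profile shared by several tests.
benchmark_signal <- function(seed) {
  simulate_piecewise(piecewise_spec(), seed = seed)
}

modal_count <- function(x) as.integer(names(which.max(table(x))))
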