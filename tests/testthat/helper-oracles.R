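# Independent numerical oracles used by the tests. These deliberately avoid
# the code paths under test (no mvtnorm, no package quadrature helpers):
# everything here reduces to one-dimensional adaptive quadrature of
# textbook formulas, or brute-force enumeration.

# Bivariate orthant probability P(U1 > 0, U2 > 0) for U ~ N(h, unit var,
# corr lam), by conditioning on the first coordinate:
# U1 = h1 + X, U2 = h2 + lam X + sqrt(1-lam^2) Y.
oracle_orthant2 <- function(h1, h2, lam) {
  stats::integrate(function(x) {
    stats::dnorm(x) * stats::pnorm((h2 + lam * x) / sqrt(1 - lam^2))
  }, lower = -h1, upper = Inf, rel.tol = 1e-13, abs.tol = 1e-15)$value
}

# Equicorrelated orthant probability of any dimension via conditional
# independence on the shared factor: with common correlation a >= 0,
# U_i = h_i + sqrt(a) t + sqrt(1-a) Z_i, so
# P(all U_i > 0) = E_t[ prod_i Phi((h_i + sqrt(a) t)/sqrt(1-a)) ].
oracle_orthant_equi <- function(h, a) {
  sa <- sqrt(a); s1 <- sqrt(1 - a)
  stats::integrate(function(t) {
    out <- stats::dnorm(t)
    for (hi in h) out <- out * stats::pnorm((hi + sa * t) / s1)
    out
  }, lower = -9, upper = 9, rel.tol = 1e-13, abs.tol = 1e-15)$value
}

# Third and fourth central cross-moments of an exchangeable DG pool from
# the conditional-independence raw moments E[X1..Xm] = E_t[L(t)^m].
oracle_zeta <- function(mu, a) {
  h <- stats::qnorm(mu)
  E <- function(m) oracle_orthant_equi(rep(h, m), a)
  E(3) - 3 * mu * E(2) + 2 * mu^3
}
oracle_chi <- function(mu, a) {
  h <- stats::qnorm(mu)
  E <- function(m) oracle_orthant_equi(rep(h, m), a)
  E(4) - 4 * mu * E(3) + 6 * mu^2 * E(2) - 3 * mu^4
}

# Theta coordinates by brute-force subset (Moebius) inversion over the full
# 2^n pattern distribution: theta_S = sum_{T subset S} (-1)^{|S|-|T|} log
# P(x_T), with x_T the pattern active exactly on T. For an exchangeable
# distribution P(x_T) = Q(|T|), and theta_S depends only on |S|.
oracle_theta_enum <- function(pmf) {
  n <- pmf$n
  log_q <- pmf$log_p - lchoose(n, 0:n)
  theta <- numeric(n)
  for (k in seq_len(n)) {
    tot <- 0
    for (mask in 0:(2^k - 1)) {             # subsets T of {1..k} as bitmasks
      sz <- sum(bitwAnd(mask, 2^(0:(k - 1))) > 0)
      tot <- tot + (-1)^(k - sz) * log_q[sz + 1]
    }
    theta[k] <- tot
  }
  theta
}

# Average of the product of centered entries over all distinct index
# m-tuples, enumerated explicitly with utils::combn (the slow but obvious
# counterpart of the symmetric-polynomial estimator).
oracle_tuple_average <- function(raster, m) {
  x <- as.matrix(unclass(raster))
  y <- x - mean(x)
  combos <- utils::combn(ncol(y), m)
  vals <- apply(combos, 2, function(idx) {
    mean(apply(y[, idx, drop = FALSE], 1, prod))
  })
  mean(vals)
}

# Shared fixtures for the acceptance tests (computed once per run).
.dg_test_cache <- new.env(parent = emptyenv())

standard_alpha_grid <- c(0.4, 0.45, 0.5, 0.55, 0.6, 0.7, 0.8, 0.9, 0.95)

standard_sweep <- function() {
  if (is.null(.dg_test_cache$sweep))
    .dg_test_cache$sweep <- sweep_cumulants(standard_alpha_grid, n = 50)
  .dg_test_cache$sweep
}

standard_thermo <- function() {
  if (is.null(.dg_test_cache$thermo))
    .dg_test_cache$thermo <- lapply(c(10, 20, 50), function(n)
      thermo_curve(n, h = 0, alpha = 0.8, T_grid = seq(0.5, 2, by = 0.01)))
  .dg_test_cache$thermo
}
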