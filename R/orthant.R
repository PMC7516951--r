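#' Multivariate normal orthant probability
#'
#' Computes \eqn{\Phi_d(h; \Lambda) = P(U_1 > 0, \ldots, U_d > 0)} for a
#' latent Gaussian vector \eqn{U \sim N(h, \Lambda)} with unit variances,
#' the building block that maps latent input statistics to output spiking
#' moments in the dichotomized-Gaussian model. Dimensions 1 to 4 are
#' supported; these are exactly the orders needed for the mean, covariance,
#' third and fourth central cross-moments of the binary outputs.
#'
#' Deterministic algorithms are used throughout (closed form for d = 1 and
#' singular cases, TVPACK for d = 2, 3, a Miwa lattice rule for d = 4), so
#' repeated calls are bitwise reproducible.
#'
#' @param h numeric vector of latent means, length 1 to 4.
#' @param corr correlation matrix matching `length(h)`; may be omitted for
#'   d = 1.
#' @return probability in `[0, 1]`.
#' @examples
#' mvn_orthant(0)                          # 0.5
#' mvn_orthant(c(0, 0), equicorr(2, 0.5))  # 1/4 + asin(0.5)/(2*pi)
#' @export
mvn_orthant <- function(h, corr = NULL) {
  d <- length(h)
  if (d < 1L || d > 4L)
    stop("orthant probabilities are supported for dimensions 1 to 4, got ", d,
         call. = FALSE)
  if (!all(is.finite(h))) stop("'h' must be finite", call. = FALSE)
  if (d == 1L) return(stats::pnorm(h))
  corr <- validate_corr(corr, d)

  off <- corr[upper.tri(corr)]
  if (all(abs(off) < 1e-14)) return(prod(stats::pnorm(h)))
  if (all(abs(off - 1) < 1e-12)) return(stats::pnorm(min(h)))  # comonotone
  if (d == 2L && abs(off + 1) < 1e-12)                         # antithetic pair
    return(max(0, stats::pnorm(h[1]) + stats::pnorm(h[2]) - 1))

  ev_min <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-10)
    stop("correlation matrix is singular or nearly singular; ",
         "orthant quadrature requires a non-degenerate matrix", call. = FALSE)

  alg <- if (d <= 3L) mvtnorm::TVPACK(abseps = 1e-12)
         else mvtnorm::Miwa(steps = 2048)
  p <- mvtnorm::pmvnorm(lower = rep(0, d), upper = rep(Inf, d),
                        mean = h, corr = corr, algorithm = alg)
  min(max(as.numeric(p), 0), 1)
}

#' Equicorrelation matrix
#'
#' @param d dimension.
#' @param a common off-diagonal correlation.
#' @return `d` x `d` correlation matrix with unit diagonal.
#' @export
equicorr <- function(d, a) {
  d <- check_count(d, "d")
  check_scalar(a, "a", -1, 1)
  m <- matrix(a, d, d)
  diag(m) <- 1
  m
}

validate_corr <- function(corr, d) {
  if (is.null(corr)) stop("a correlation matrix is required for d >= 2",
                          call. = FALSE)
  corr <- as.matrix(corr)
  if (!is.numeric(corr) || any(!is.finite(corr)) ||
      nrow(corr) != d || ncol(corr) != d)
    stop(sprintf("'corr' must be a finite %dx%d matrix", d, d), call. = FALSE)
  if (max(abs(corr - t(corr))) > 1e-12)
    stop("'corr' must be symmetric", call. = FALSE)
  if (max(abs(diag(corr) - 1)) > 1e-12)
    stop("'corr' must have unit diagonal", call. = FALSE)
  if (any(abs(corr) > 1 + 1e-12))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  ev_min <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8)
    stop("'corr' is not positive semidefinite (min eigenvalue ",
         signif(ev_min, 3), ")", call. = FALSE)
  corr
}

#' Output firing probability of a dichotomized-Gaussian neuron
#'
#' The mean of the thresholded binary output: \eqn{\mu = \Phi(h)}, where
#' \eqn{h} is the latent Gaussian mean in units of the latent SD and the
#' threshold sits at 0. Saturates to 0/1 in the extreme tails (below about
#' `h = -38` the value underflows to 0 in double precision).
#'
#' @param h latent mean (vectorised).
#' @return firing probability \eqn{\Phi(h)}.
#' @export
output_mean <- function(h) {
  if (!is.numeric(h)) stop("'h' must be numeric", call. = FALSE)
  stats::pnorm(h)
}

#' Output covariance of a pair of dichotomized-Gaussian neurons
#'
#' \eqn{\Sigma_{ij} = \Phi_2(h_i, h_j; \lambda) - \Phi(h_i)\Phi(h_j)}: the
#' central covariance of two binary outputs whose latent inputs have means
#' `hi`, `hj` and correlation `lam`.
#'
#' @param hi,hj latent means.
#' @param lam latent correlation in `[-1, 1]`.
#' @return covariance of the two binary outputs.
#' @export
output_cov <- function(hi, hj, lam) {
  check_scalar(hi, "hi"); check_scalar(hj, "hj")
  check_scalar(lam, "lam", -1, 1)
  if (lam == 0) return(0)
  mvn_orthant(c(hi, hj), equicorr(2, lam)) -
    stats::pnorm(hi) * stats::pnorm(hj)
}

#' Solve for the latent correlation matching a target output covariance
#'
#' Inverts the moment map: finds the latent Gaussian correlation
#' \eqn{\lambda} such that two thresholded units with firing probabilities
#' `mu_i`, `mu_j` have covariance `sigma_ij`. \eqn{\Phi_2} is strictly
#' increasing in its correlation argument, so the root is unique and is
#' bracketed by bisection.
#'
#' @param mu_i,mu_j firing probabilities in (0, 1).
#' @param sigma_ij target output covariance; must lie in the feasible range
#'   (Frechet bounds minus the product of means).
#' @param tol bisection half-interval tolerance on \eqn{\lambda}.
#' @return the latent correlation \eqn{\lambda}.
#' @export
solve_latent_pair <- function(mu_i, mu_j, sigma_ij, tol = 1e-12) {
  check_scalar(mu_i, "mu_i"); check_scalar(mu_j, "mu_j")
  check_scalar(sigma_ij, "sigma_ij")
  if (mu_i <= 0 || mu_i >= 1 || mu_j <= 0 || mu_j >= 1)
    stop("firing probabilities must lie strictly in (0, 1)", call. = FALSE)
  hi <- stats::qnorm(clip_prob(mu_i))
  hj <- stats::qnorm(clip_prob(mu_j))
  lo_cov <- max(0, mu_i + mu_j - 1) - mu_i * mu_j   # lambda = -1
  hi_cov <- min(mu_i, mu_j) - mu_i * mu_j           # lambda = +1
  slack <- 1e-12 + 1e-9 * abs(sigma_ij)
  if (sigma_ij < lo_cov - slack || sigma_ij > hi_cov + slack)
    stop(sprintf(
      "inadmissible covariance %.6g for (mu_i, mu_j) = (%.4g, %.4g); feasible range is [%.6g, %.6g]",
      sigma_ij, mu_i, mu_j, lo_cov, hi_cov), call. = FALSE)
  if (sigma_ij == 0) return(0)
  if (abs(sigma_ij - hi_cov) <= slack) return(1)
  if (abs(sigma_ij - lo_cov) <= slack) return(-1)

  f <- function(lam) output_cov(hi, hj, lam) - sigma_ij
  a <- -1 + 1e-12; b <- 1 - 1e-12
  fa <- f(a)
  if (fa > 0) return(-1)   # target at the lower boundary within quadrature noise
  for (it in seq_len(100L)) {
    m <- (a + b) / 2
    fm <- f(m)
    if (fm <= 0) { a <- m; fa <- fm } else b <- m
    if ((b - a) / 2 < tol) break
  }
  (a + b) / 2
}

#' Solve for the homogeneous latent parameters of a target (mu, rho)
#'
#' For an exchangeable pool, maps target output statistics -- firing
#' probability `mu` and pairwise output correlation coefficient `rho`
#' (so the pair covariance is \eqn{\sigma = \rho\,\mu(1-\mu)}) -- to the
#' latent parameters \eqn{h = \Phi^{-1}(\mu)} and the common latent
#' correlation \eqn{\alpha}.
#'
#' @param n population size (metadata; the map itself is n-free).
#' @param mu target firing probability in (0, 1).
#' @param rho target pairwise correlation coefficient, `>= 0` for an
#'   equicorrelated latent pool.
#' @return a list with components `n`, `h`, `alpha` (class `"dg_latent"`).
#' @export
solve_latent_homogeneous <- function(n, mu, rho) {
  n <- check_count(n, "n")
  check_scalar(mu, "mu")
  check_scalar(rho, "rho", 0, 1)
  h <- stats::qnorm(clip_prob(mu))
  alpha <- solve_latent_pair(mu, mu, rho * mu * (1 - mu))
  structure(list(n = n, h = h, alpha = alpha), class = "dg_latent")
}
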