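#' Asymptotic spike-count density of the homogeneous DG pool
#'
#' In the infinite-population limit the fraction of active neurons
#' \eqn{r = k/n} has the continuous density obtained by pushing the shared
#' drive \eqn{\varepsilon \sim N(0, \alpha)} through
#' \eqn{r = \Phi((\varepsilon + h)/\sqrt{1-\alpha})}. Writing
#' \eqn{u = \Phi^{-1}(r)},
#' \deqn{\log f(r) = \tfrac12 \log\tfrac{1-\alpha}{\alpha}
#'   + \frac{-(1-2\alpha) u^2 + 2\sqrt{1-\alpha}\, h\, u - h^2}{2\alpha}.}
#' This is the exact change-of-variables form; completing the square
#' recovers the familiar Gaussian-in-\eqn{\Phi^{-1}(r)} expression with
#' prefactor \eqn{\exp(h^2 / (2 - 4\alpha))}, but the quadratic form above
#' contains no \eqn{1/(1-2\alpha)} and therefore needs no special branch at
#' the critical correlation \eqn{\alpha = 1/2}, where (for h = 0) the
#' density is exactly uniform. Below \eqn{\alpha = 1/2} the density is
#' unimodal; above it, it diverges at both boundaries: the bimodal UP/DOWN
#' regime.
#'
#' @param h latent mean.
#' @param alpha latent correlation, strictly inside (0, 1).
#' @return object of class `"dg_fr"` with `h`, `alpha` and vectorised
#'   evaluators `log_f(r)` / `f(r)`; equivalently, `u = Phi^{-1}(r)` has the
#'   Gaussian distribution `N(mu_u, sd_u^2)` stored alongside.
#' @examples
#' f <- asymptotic_density(0, 0.5)
#' f$f(c(0.1, 0.5, 0.9))  # uniform: all 1
#' @export
asymptotic_density <- function(h, alpha) {
  check_scalar(h, "h")
  check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1)
    stop("'alpha' must lie strictly inside (0, 1)", call. = FALSE)
  force(h); force(alpha)
  log_f_u <- function(u) {
    0.5 * log((1 - alpha) / alpha) +
      (-(1 - 2 * alpha) * u^2 + 2 * sqrt(1 - alpha) * h * u - h^2) /
        (2 * alpha)
  }
  log_f <- function(r) log_f_u(stats::qnorm(r))
  structure(list(
    h = h, alpha = alpha,
    mu_u = h / sqrt(1 - alpha),            # distribution of u = qnorm(r)
    sd_u = sqrt(alpha / (1 - alpha)),
    log_f_u = log_f_u, log_f = log_f,
    f = function(r) exp(log_f(r))
  ), class = "dg_fr")
}

#' @export
print.dg_fr <- function(x, ...) {
  cat(sprintf("Asymptotic DG spike-count density f(r): h = %.4g, alpha = %.4g\n",
              x$h, x$alpha))
  regime <- if (x$alpha < 0.5) "unimodal (single population state)"
            else if (x$alpha > 0.5) "bimodal (UP/DOWN states)"
            else "critical (alpha = 1/2)"
  cat("  regime:", regime, "\n")
  invisible(x)
}

#' Count the modes of an asymptotic spike-count density
#'
#' Counts local maxima of `f` over a grid in the Gaussian coordinate
#' \eqn{u = \Phi^{-1}(r)} (monotone in `r`, so mode locations are
#' preserved while the boundary singularities are resolved). A boundary
#' counts as a mode when the density increases toward it; because for
#' \eqn{\alpha > 1/2} the divergence at both boundaries may begin beyond
#' any finite grid, positive tail curvature of \eqn{\log f} in `u` at both
#' ends (the exact signature of the U-shaped regime, where \eqn{\log f} is
#' convex) also marks both boundaries as modes. An (essentially) constant
#' density is flagged degenerate.
#'
#' @param fr a `"dg_fr"`, or a numeric vector of density values already
#'   evaluated on an increasing `u` grid (then `u_grid` must be supplied
#'   or is taken as equispaced).
#' @param n_grid number of grid points (>= 201) when `fr` is a `"dg_fr"`.
#' @param u_range grid range in `u`.
#' @return integer mode count, with attribute `degenerate` (logical).
#' @examples
#' modality(asymptotic_density(0, 0.3))  # 1
#' modality(asymptotic_density(0, 0.8))  # 2: UP and DOWN states
#' @export
modality <- function(fr, n_grid = 801, u_range = c(-8, 8)) {
  if (inherits(fr, "dg_fr")) {
    n_grid <- check_count(n_grid, "n_grid", lower = 201L)
    u <- seq(u_range[1], u_range[2], length.out = n_grid)
    lf <- fr$log_f_u(u)
  } else {
    lf <- log(as.numeric(fr))
    if (length(lf) < 3L) stop("need at least 3 grid points", call. = FALSE)
  }
  N <- length(lf)
  rng <- max(lf) - min(lf)
  if (rng < 1e-10)
    return(structure(0L, degenerate = TRUE))
  interior <- sum(lf[2:(N - 1)] > lf[1:(N - 2)] & lf[2:(N - 1)] > lf[3:N])
  left <- lf[1] > lf[2]
  right <- lf[N] > lf[N - 1]
  # positive log-density curvature at both tails => divergent boundaries
  curv_tol <- 1e-10
  d2l <- lf[1] - 2 * lf[2] + lf[3]
  d2r <- lf[N] - 2 * lf[N - 1] + lf[N - 2]
  if (d2l > curv_tol && d2r > curv_tol) { left <- TRUE; right <- TRUE }
  structure(as.integer(interior + left + right), degenerate = FALSE)
}

#' Critical latent correlation of the modality transition
#'
#' Scans [modality()] of the asymptotic density over `alpha` and refines
#' the unimodal-to-bimodal switch by bisection. The transition sits at
#' \eqn{\alpha = 1/2} independently of the latent mean `h` (the partition
#' function of the asymptotic family is discontinuous there).
#'
#' @param h latent mean.
#' @param alpha_range search interval.
#' @param coarse_step coarse scan step.
#' @param tol bisection tolerance on `alpha`.
#' @return the detected threshold correlation.
#' @export
modality_threshold <- function(h, alpha_range = c(0.3, 0.7),
                               coarse_step = 0.05, tol = 1e-4) {
  check_scalar(h, "h")
  grid <- seq(alpha_range[1], alpha_range[2], by = coarse_step)
  nm <- vapply(grid, function(a) as.integer(modality(asymptotic_density(h, a))),
               integer(1))
  bi <- which(nm >= 2L)
  if (length(bi) == 0L || bi[1] == 1L)
    stop("no unimodal-to-bimodal switch inside 'alpha_range'", call. = FALSE)
  lo <- grid[bi[1] - 1L]; hi <- grid[bi[1]]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (as.integer(modality(asymptotic_density(h, mid))) >= 2L) hi <- mid
    else lo <- mid
  }
  (lo + hi) / 2
}

#' Asymptotic population cumulants from f(r)
#'
#' Moments of the limiting active-fraction density: \eqn{\mu = E[r]},
#' exchangeable-pair covariance \eqn{\sigma = Var[r]}, correlation
#' coefficient \eqn{\rho = \sigma/(\mu(1-\mu))}, skewness
#' \eqn{\zeta = E[(r-\mu)^3]} and kurtosis \eqn{\chi = E[(r-\mu)^4]}.
#' Integrals are taken in the Gaussian coordinate \eqn{u = \Phi^{-1}(r)}
#' over `8` standard deviations of its \eqn{N(\mu_u, s_u^2)} law, which
#' removes the boundary singularities of `f` in the bimodal regime.
#'
#' @param h latent mean.
#' @param alpha latent correlation in (0, 1).
#' @param n_nodes Gauss-Legendre node count.
#' @return `"dg_moments"` (with `n = Inf`).
#' @examples
#' asymptotic_cumulants(0, 0.5)  # mu 1/2, rho 1/3, zeta 0, chi 1/80
#' @export
asymptotic_cumulants <- function(h, alpha, n_nodes = 401) {
  fr <- asymptotic_density(h, alpha)
  gl <- gauss_legendre(n_nodes, -8, 8)
  u <- fr$mu_u + fr$sd_u * gl$x          # standardized u-grid
  w <- gl$w * stats::dnorm(gl$x)         # du-measure of u in its own scale
  r <- stats::pnorm(u)
  w <- w / sum(w)                        # renormalize the 8-SD truncation
  mu <- sum(w * r)
  ctr <- r - mu
  sigma <- sum(w * ctr^2)
  structure(list(mu = mu, sigma = sigma,
                 rho = sigma / (mu * (1 - mu)),
                 zeta = sum(w * ctr^3),
                 chi = sum(w * ctr^4),
                 n = Inf),
            class = "dg_moments")
}
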