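#' Third central cross-moment of three dichotomized-Gaussian outputs
#'
#' \deqn{\Sigma_{ijk} = E[X_iX_jX_k] - \mu_i E[X_jX_k] - \mu_j E[X_iX_k]
#'   - \mu_k E[X_iX_j] + 2\mu_i\mu_j\mu_k,}
#' with \eqn{E[X_iX_jX_k] = \Phi_3(h; \Lambda)} and pairwise raw moments
#' \eqn{E[X_aX_b] = \Phi_2(h_a, h_b; \lambda_{ab})}. For an exchangeable
#' pool this is the population skewness coefficient \eqn{\zeta}.
#'
#' @param h3 latent means, length 3.
#' @param Lam3 3x3 latent correlation matrix.
#' @return the third central cross-moment.
#' @export
third_central_moment <- function(h3, Lam3) {
  if (length(h3) != 3L) stop("'h3' must have length 3", call. = FALSE)
  Lam3 <- validate_corr(Lam3, 3L)
  mu <- stats::pnorm(h3)
  E2 <- function(a, b) mvn_orthant(h3[c(a, b)], equicorr(2, Lam3[a, b]))
  E3 <- mvn_orthant(h3, Lam3)
  E3 - mu[1] * E2(2, 3) - mu[2] * E2(1, 3) - mu[3] * E2(1, 2) +
    2 * mu[1] * mu[2] * mu[3]
}

#' Fourth central cross-moment of four dichotomized-Gaussian outputs
#'
#' \deqn{\Sigma_{ijkl} = E[X_iX_jX_kX_l] - \sum_a \mu_a E[\cdot\cdot\cdot]
#'   + \sum_{a<b} \mu_a\mu_b E[\cdot\cdot] - 3\mu_i\mu_j\mu_k\mu_l,}
#' with the quadruple raw moment \eqn{\Phi_4}, the four triple terms
#' \eqn{\Phi_3} and the six pair terms \eqn{\Phi_2}. For an exchangeable
#' pool this is the population kurtosis coefficient \eqn{\chi}.
#'
#' @param h4 latent means, length 4.
#' @param Lam4 4x4 latent correlation matrix.
#' @return the fourth central cross-moment.
#' @export
fourth_central_moment <- function(h4, Lam4) {
  if (length(h4) != 4L) stop("'h4' must have length 4", call. = FALSE)
  Lam4 <- validate_corr(Lam4, 4L)
  mu <- stats::pnorm(h4)
  sub <- function(idx) mvn_orthant(h4[idx], Lam4[idx, idx, drop = FALSE])
  E4 <- mvn_orthant(h4, Lam4)
  trip <- 0
  for (a in 1:4) trip <- trip + mu[a] * sub(setdiff(1:4, a))
  pair <- 0
  pairs <- utils::combn(4, 2)
  for (j in seq_len(ncol(pairs))) {
    ab <- pairs[, j]
    cd <- setdiff(1:4, ab)
    pair <- pair + mu[ab[1]] * mu[ab[2]] * sub(cd)
  }
  E4 - trip + pair - 3 * prod(mu)
}

#' Output moments of a homogeneous DG pool up to fourth order
#'
#' For an exchangeable pool with latent mean `h` and latent correlation
#' `alpha`: firing probability \eqn{\mu = \Phi(h)}, pair covariance
#' \eqn{\sigma}, pairwise correlation coefficient
#' \eqn{\rho = \sigma / (\mu(1-\mu))}, skewness coefficient \eqn{\zeta}
#' (third central cross-moment of any distinct triple) and kurtosis
#' coefficient \eqn{\chi} (fourth central cross-moment of any distinct
#' quadruple). `zeta` and `chi` are raw central cross-moments, not
#' standardized ratios; set `standardized = TRUE` to additionally report
#' \eqn{\zeta / (\mu(1-\mu))^{3/2}} and \eqn{\chi / (\mu(1-\mu))^2}.
#'
#' @param object a `"dg_model"`, or `h` when latent parameters are passed
#'   directly.
#' @param alpha latent correlation when `object` is the latent mean.
#' @param standardized also report standardized skewness/kurtosis.
#' @return object of class `"dg_moments"`.
#' @examples
#' homogeneous_cumulants(dg_model(50, h = 0, alpha = 0.5))
#' @export
homogeneous_cumulants <- function(object, alpha = NULL, standardized = FALSE) {
  if (inherits(object, "dg_model")) {
    h <- object$h; alpha <- object$alpha; n <- object$n
  } else {
    h <- check_scalar(object, "h")
    check_scalar(alpha, "alpha", 0, 1)
    n <- NA_integer_
  }
  mu <- stats::pnorm(h)
  if (alpha == 0) {
    out <- list(mu = mu, sigma = 0, rho = 0, zeta = 0, chi = 0, n = n)
  } else {
    sigma <- output_cov(h, h, alpha)
    rho <- sigma / (mu * (1 - mu))
    zeta <- third_central_moment(rep(h, 3), equicorr(3, alpha))
    chi <- fourth_central_moment(rep(h, 4), equicorr(4, alpha))
    out <- list(mu = mu, sigma = sigma, rho = rho, zeta = zeta, chi = chi,
                n = n)
  }
  if (standardized) {
    v <- mu * (1 - mu)
    out$zeta_std <- out$zeta / v^1.5
    out$chi_std <- out$chi / v^2
  }
  structure(out, class = "dg_moments")
}

#' @export
print.dg_moments <- function(x, ...) {
  cat("DG output moments (homogeneous pool)\n")
  cat(sprintf("  mu = %.6g   sigma = %.6g   rho = %.6g\n",
              x$mu, x$sigma, x$rho))
  cat(sprintf("  zeta (3rd central cross-moment) = %.6g\n", x$zeta))
  cat(sprintf("  chi  (4th central cross-moment) = %.6g\n", x$chi))
  if (!is.null(x$zeta_std))
    cat(sprintf("  standardized: zeta* = %.6g, chi* = %.6g\n",
                x$zeta_std, x$chi_std))
  invisible(x)
}

#' Cumulant curves versus firing rate
#'
#' Evaluates \eqn{\rho(\mu)}, \eqn{\zeta(\mu)} and \eqn{\chi(\mu)} along a
#' firing-rate grid at fixed latent correlation(s), with
#' \eqn{h = \Phi^{-1}(\mu)}. The default 99-point grid on (0.01, 0.99)
#' resolves the features at \eqn{\mu = 0.5}: the maximum of \eqn{\rho}, the
#' sign change of \eqn{\zeta}, and the local minimum of \eqn{\chi} that
#' appears for strong input correlations (\eqn{\alpha > 0.7}).
#'
#' @param alpha latent correlation(s); may be a vector.
#' @param mu_grid firing-rate grid strictly inside (0, 1).
#' @param n population size recorded with the sweep (the per-tuple moments
#'   themselves do not depend on `n`).
#' @return a data frame of class `"dg_sweep"` with columns
#'   `alpha, mu, rho, zeta, chi`.
#' @export
sweep_cumulants <- function(alpha,
                            mu_grid = seq(0.01, 0.99, length.out = 99),
                            n = 50) {
  if (any(mu_grid <= 0) || any(mu_grid >= 1))
    stop("'mu_grid' must lie strictly inside (0, 1)", call. = FALSE)
  n <- check_count(n, "n")
  rows <- lapply(alpha, function(a) {
    check_scalar(a, "alpha", 0, 1)
    h <- stats::qnorm(mu_grid)
    cms <- lapply(h, function(hh) homogeneous_cumulants(hh, a))
    data.frame(alpha = a, mu = mu_grid,
               rho = vapply(cms, `[[`, numeric(1), "rho"),
               zeta = vapply(cms, `[[`, numeric(1), "zeta"),
               chi = vapply(cms, `[[`, numeric(1), "chi"))
  })
  out <- do.call(rbind, rows)
  attr(out, "n") <- n
  class(out) <- c("dg_sweep", class(out))
  out
}

#' Empirical pooled cumulants of a spike raster
#'
#' Exchangeability-averaged sample estimates of the pool statistics from a
#' binary trials x neurons raster: overall firing rate \eqn{\hat\mu},
#' pairwise correlation coefficient \eqn{\hat\rho}, and the third and
#' fourth central cross-moments \eqn{\hat\zeta, \hat\chi} averaged over all
#' distinct index triples/quadruples. The averages over distinct tuples are
#' computed exactly in O(trials x n) through the elementary symmetric
#' polynomials of the centered rows (Newton's identities), which is
#' algebraically identical to enumerating every combination.
#'
#' Standard errors (trial-to-trial) are attached as attribute `"se"`.
#'
#' @param raster binary matrix (trials x neurons) or `"dg_raster"`.
#' @return `"dg_moments"` with attributes `se` and `trials`.
#' @export
empirical_cumulants <- function(raster) {
  x <- unclass(raster)
  attr(x, "params") <- NULL; attr(x, "seed") <- NULL
  x <- as.matrix(x)
  if (!all(x %in% c(0, 1))) stop("raster entries must be 0/1", call. = FALSE)
  trials <- nrow(x); n <- ncol(x)
  if (trials < 2L) stop("at least 2 trials are required", call. = FALSE)
  if (n < 4L) stop("at least 4 neurons are required for the quadruple ",
                   "moment", call. = FALSE)
  col_var <- apply(x, 2, stats::var)
  if (any(col_var == 0))
    warning("raster has constant (all-zero or all-one) columns; ",
            "pairwise correlations involving them are undefined")

  mu_hat <- mean(x)
  y <- x - mu_hat
  p1 <- rowSums(y); p2 <- rowSums(y^2); p3 <- rowSums(y^3); p4 <- rowSums(y^4)
  e2 <- (p1^2 - p2) / 2
  e3 <- (p1^3 - 3 * p1 * p2 + 2 * p3) / 6
  e4 <- (p1^4 - 6 * p1^2 * p2 + 3 * p2^2 + 8 * p1 * p3 - 6 * p4) / 24
  # per-trial averages over distinct pairs / triples / quadruples
  m2 <- e2 / choose(n, 2)
  m3 <- e3 / choose(n, 3)
  m4 <- e4 / choose(n, 4)
  v <- mu_hat * (1 - mu_hat)
  sigma_hat <- mean(m2)
  rho_hat <- if (v > 0) sigma_hat / v else NA_real_
  mu_t <- rowMeans(x)
  se <- c(mu = stats::sd(mu_t),
          rho = if (v > 0) stats::sd(m2) / v else NA_real_,
          zeta = stats::sd(m3),
          chi = stats::sd(m4)) / sqrt(trials)
  structure(list(mu = mu_hat, sigma = sigma_hat, rho = rho_hat,
                 zeta = mean(m3), chi = mean(m4), n = n),
            class = "dg_moments", se = se, trials = trials)
}

#' Feature locations of cumulant curves
#'
#' Extracts, per latent correlation, the firing-rate locations of the
#' characteristic features of the cumulant curves: the maximum of
#' \eqn{\rho(\mu)}, the (unique) zero crossing of \eqn{\zeta(\mu)} with its
#' linearly interpolated root, and the interior local maxima of
#' \eqn{\chi(\mu)} with the location of the local minimum separating them
#' in the bimodal regime.
#'
#' @param sweep a `"dg_sweep"` from [sweep_cumulants()].
#' @param zero_tol values of `zeta` below this magnitude count as exact
#'   zeros.
#' @return data frame, one row per `alpha`, with columns `alpha`,
#'   `rho_argmax`, `rho_increasing_below` (monotone rise up to the argmax),
#'   `zeta_n_signchanges`, `zeta_root` (interpolated), `chi_n_maxima`,
#'   `chi_min_mu` (NA unless the curve has two maxima).
#' @export
sweep_features <- function(sweep, zero_tol = 1e-12) {
  stopifnot(inherits(sweep, "dg_sweep"))
  out <- lapply(split(as.data.frame(sweep), sweep$alpha), function(d) {
    d <- d[order(d$mu), ]
    mu <- d$mu
    i_max <- which.max(d$rho)
    rho_inc <- all(diff(d$rho[seq_len(i_max)]) > 0)

    z <- d$zeta
    z[abs(z) < zero_tol] <- 0
    nz <- which(z != 0)
    s <- sign(z[nz])
    flips <- which(s[-1] != s[-length(s)])
    n_sc <- length(flips)
    root <- NA_real_
    if (n_sc >= 1L) {
      i <- nz[flips[1]]; j <- nz[flips[1] + 1L]
      if (j - i > 1L) root <- mean(mu[(i + 1L):(j - 1L)])  # exact zero(s) between
      else root <- mu[i] + (mu[j] - mu[i]) * z[i] / (z[i] - z[j])
    }

    ch <- d$chi
    m <- length(ch)
    is_max <- ch[2:(m - 1)] > ch[1:(m - 2)] & ch[2:(m - 1)] > ch[3:m]
    peaks <- which(is_max) + 1L
    chi_min <- NA_real_
    if (length(peaks) == 2L) {
      span <- peaks[1]:peaks[2]
      chi_min <- mu[span[which.min(ch[span])]]
    }
    data.frame(alpha = d$alpha[1], rho_argmax = mu[i_max],
               rho_increasing_below = rho_inc,
               zeta_n_signchanges = n_sc, zeta_root = root,
               chi_n_maxima = length(peaks), chi_min_mu = chi_min)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
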