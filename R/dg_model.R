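#' Homogeneous dichotomized-Gaussian population model
#'
#' Constructs the exchangeable dichotomized-Gaussian (DG) model of `n`
#' binary neurons. Each neuron thresholds a latent Gaussian
#' \eqn{u_i = h + \sqrt{1-\alpha}\, v_i + \sqrt{\alpha}\, \varepsilon}
#' at zero (spike iff \eqn{u_i > 0}), where \eqn{v_i} are private and
#' \eqn{\varepsilon} is a shared standard-normal drive, so the latent
#' correlation between any two neurons is \eqn{\alpha}. Although the latent
#' inputs carry only pairwise (Gaussian) structure, the threshold induces
#' correlations of all orders in the spiking outputs.
#'
#' Supply either the latent parameters (`h`, `alpha`) or the target output
#' statistics (`mu`, `rho`); in the latter case the latent parameters are
#' obtained by numerically inverting the moment map.
#'
#' @param n number of neurons (`>= 1`).
#' @param h latent mean, in units of the latent SD.
#' @param alpha common latent pairwise correlation, in `[0, 1)`.
#' @param mu target output firing probability in (0, 1), alternative to `h`.
#' @param rho target pairwise output correlation coefficient (`>= 0`),
#'   alternative to `alpha`.
#' @return an object of class `"dg_model"`: a list with elements `n`, `h`,
#'   `alpha`, `mu`, `sigma`, `rho`.
#' @examples
#' m <- dg_model(n = 50, h = 0, alpha = 0.5)
#' coef(m)
#' m2 <- dg_model(n = 50, mu = 0.5, rho = 1/3)  # inverse parametrisation
#' @export
dg_model <- function(n, h = NULL, alpha = NULL, mu = NULL, rho = NULL) {
  n <- check_count(n, "n")
  from_latent <- !is.null(h) && !is.null(alpha)
  from_output <- !is.null(mu) && !is.null(rho)
  if (from_latent == from_output)
    stop("supply exactly one of (h, alpha) or (mu, rho)", call. = FALSE)
  if (from_output) {
    lat <- solve_latent_homogeneous(n, mu, rho)
    h <- lat$h; alpha <- lat$alpha
  }
  check_scalar(h, "h")
  check_scalar(alpha, "alpha", 0, 1)
  if (alpha >= 1)
    stop("'alpha' must lie in [0, 1); alpha = 1 is a degenerate ",
         "fully-coupled pool", call. = FALSE)
  mu <- stats::pnorm(h)
  sigma <- output_cov(h, h, alpha)
  rho <- if (mu > 0 && mu < 1) sigma / (mu * (1 - mu)) else 0
  structure(list(n = n, h = h, alpha = alpha, mu = mu,
                 sigma = sigma, rho = rho),
            class = "dg_model")
}

#' @export
print.dg_model <- function(x, ...) {
  cat(sprintf("Dichotomized-Gaussian population model (n = %d neurons)\n", x$n))
  cat(sprintf("  latent:  h = %.6g, alpha = %.6g\n", x$h, x$alpha))
  cat(sprintf("  output:  mu = %.6g, sigma = %.6g, rho = %.6g\n",
              x$mu, x$sigma, x$rho))
  invisible(x)
}

#' @export
coef.dg_model <- function(object, ...) {
  c(h = object$h, alpha = object$alpha)
}

#' Summary of a DG model: output moments up to fourth order
#'
#' @param object a `"dg_model"`.
#' @param ... passed to [homogeneous_cumulants()].
#' @return the `"dg_moments"` object for the model (mean, pair covariance,
#'   correlation coefficient, third and fourth central cross-moments).
#' @export
summary.dg_model <- function(object, ...) {
  homogeneous_cumulants(object, ...)
}

#' Simulate spike rasters from a DG model
#'
#' Draws `nsim` i.i.d. time bins. Per bin, one shared drive
#' \eqn{\varepsilon \sim N(0,1)} and `n` private drives
#' \eqn{v_i \sim N(0,1)} are drawn; neuron `i` spikes iff
#' \eqn{h + \sqrt{1-\alpha}\,v_i + \sqrt{\alpha}\,\varepsilon > 0}.
#' The caller's RNG state is left untouched; a given `seed` reproduces the
#' raster exactly.
#'
#' @param object a `"dg_model"`.
#' @param nsim number of trials (time bins).
#' @param seed integer seed; required (no hidden global RNG state).
#' @param ... unused.
#' @return a `nsim` x `n` binary matrix of class `"dg_raster"` with
#'   attributes `params` (the model) and `seed`.
#' @export
simulate.dg_model <- function(object, nsim = 1, seed = NULL, ...) {
  nsim <- check_count(nsim, "nsim")
  if (is.null(seed)) stop("'seed' is required for raster simulation",
                          call. = FALSE)
  n <- object$n; h <- object$h; alpha <- object$alpha
  x <- with_seed(seed, {
    eps <- stats::rnorm(nsim)                      # shared drive, one per trial
    v <- matrix(stats::rnorm(nsim * n), nsim, n)   # private drives
    u <- h + sqrt(1 - alpha) * v + sqrt(alpha) * eps  # eps recycles per column
    matrix(as.integer(u > 0), nsim, n)
  })
  colnames(x) <- paste0("neuron_", seq_len(n) - 1L)
  structure(x, params = object, seed = seed, class = c("dg_raster", class(x)))
}

#' @export
print.dg_raster <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("DG spike raster: %d trials x %d neurons (seed %d)\n",
              nrow(x), ncol(x), attr(x, "seed")))
  if (!is.null(p))
    cat(sprintf("  generated at h = %.4g, alpha = %.4g\n", p$h, p$alpha))
  cat(sprintf("  overall firing rate %.4f\n", mean(x)))
  invisible(x)
}
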