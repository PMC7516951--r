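#' Exact spike-count distribution of the homogeneous DG model
#'
#' Probability of observing `k` simultaneous spikes among `n` neurons.
#' Conditioning on the shared drive \eqn{\varepsilon \sim N(0, \alpha)}
#' makes the neurons independent with conditional firing probability
#' \eqn{L(\varepsilon) = \Phi((\varepsilon + h)/\sqrt{1-\alpha})}, so
#' \deqn{P(k) = \binom{n}{k} \int \phi_\alpha(\varepsilon)
#'   L(\varepsilon)^k (1-L(\varepsilon))^{n-k}\, d\varepsilon.}
#' The integral is evaluated by adaptive quadrature on the standardized
#' shared drive over \eqn{[-8, 8]} SDs (truncation error below 1e-15), with
#' the integrand assembled in the log domain so large `n` does not overflow.
#' `alpha = 0` short-circuits to the Binomial(`n`, \eqn{\Phi(h)}) limit.
#'
#' @param object a `"dg_model"`, or a population size `n` when `h` and
#'   `alpha` are given explicitly.
#' @param h,alpha latent parameters, used when `object` is a plain count.
#' @param rel.tol relative tolerance of the adaptive quadrature.
#' @return an object of class `"dg_pmf"`: list with `n`, `p` (length
#'   `n + 1`, `P(0..n)`), `log_p`, and the generating `h`, `alpha`.
#' @examples
#' pmf <- spike_count_pmf(dg_model(10, h = 0, alpha = 0.5))
#' sum(pmf$p)  # 1
#' @export
spike_count_pmf <- function(object, h = NULL, alpha = NULL, rel.tol = 1e-12) {
  if (inherits(object, "dg_model")) {
    n <- object$n; h <- object$h; alpha <- object$alpha
  } else {
    n <- check_count(object, "n")
    check_scalar(h, "h"); check_scalar(alpha, "alpha", 0, 1)
  }
  if (alpha >= 1) stop("'alpha' must lie in [0, 1)", call. = FALSE)

  k <- 0:n
  if (alpha == 0) {
    log_p <- stats::dbinom(k, n, stats::pnorm(h), log = TRUE)
    p <- exp(log_p)
  } else {
    sa <- sqrt(alpha)
    s1 <- sqrt(1 - alpha)
    lchk <- lchoose(n, k)
    p <- vapply(k, function(kk) {
      stats::integrate(function(t) {
        # t is the standardized shared drive; eps = sqrt(alpha) * t
        lL <- stats::pnorm((sa * t + h) / s1, log.p = TRUE)
        l1mL <- stats::pnorm((sa * t + h) / s1, log.p = TRUE,
                             lower.tail = FALSE)
        exp(lchk[kk + 1] + kk * lL + (n - kk) * l1mL) * stats::dnorm(t)
      }, lower = -8, upper = 8, rel.tol = rel.tol, abs.tol = 1e-14,
      subdivisions = 400L)$value
    }, numeric(1))
    p <- pmax(p, 0)
    log_p <- log(p)
  }
  structure(list(n = n, p = p, log_p = log_p, h = h, alpha = alpha),
            class = "dg_pmf")
}

#' @export
print.dg_pmf <- function(x, ...) {
  cat(sprintf("DG spike-count distribution, n = %d (h = %.4g, alpha = %.4g)\n",
              x$n, x$h, x$alpha))
  mu <- pmf_mean(x) / x$n
  cat(sprintf("  E[k]/n = %.6g, SD[k] = %.6g, sum P = %.15g\n",
              mu, sqrt(pmf_var(x)), sum(x$p)))
  invisible(x)
}

# count mean and variance of a dg_pmf
pmf_mean <- function(pmf) sum((0:pmf$n) * pmf$p)
pmf_var <- function(pmf) sum((0:pmf$n)^2 * pmf$p) - pmf_mean(pmf)^2
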