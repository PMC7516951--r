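#' Theta-coordinates of a homogeneous spike-count distribution
#'
#' Inverts the homogeneous log-linear (information-geometric) expansion.
#' With \eqn{Q(m) = P(m) / \binom{n}{m}} the per-pattern probability of an
#' `m`-spike pattern, the exchangeable log-linear model reads
#' \deqn{\log Q(m) = \sum_{i=1}^{m} \binom{m}{i}\,\theta_i - \psi,}
#' so \eqn{\psi = -\log Q(0)} and the interaction coefficients follow from
#' the triangular alternating finite difference
#' \deqn{\theta_k = \sum_{j=0}^{k} (-1)^{k-j} \binom{k}{j} \log Q(j).}
#' \eqn{\theta_k} quantifies the pure order-`k` interaction among neurons:
#' a product-Bernoulli pool has \eqn{\theta_1 = \log(\mu/(1-\mu))} and all
#' higher orders zero.
#'
#' The alternating sum cancels catastrophically at high orders: a
#' first-order bound on the double-precision error of each \eqn{\theta_k}
#' (machine epsilon times \eqn{\sum_j \binom{k}{j} |\log Q(j)|}) is returned
#' as `err_bound`, and orders whose bound exceeds `reliable_tol` are flagged
#' in `reliable`. For the DG model at n = 50 the first ~20 orders are
#' well-determined; treat higher orders with caution.
#'
#' @param pmf a `"dg_pmf"` (all entries must be strictly positive: the
#'   log-linear model requires full support).
#' @param floor_zero replace zero probabilities by 1e-300 instead of
#'   raising a support error.
#' @param reliable_tol error-bound threshold for the reliability flag.
#' @return object of class `"dg_theta"`: list with `n`, `psi`, `theta`
#'   (length `n`), `err_bound`, `reliable`.
#' @export
theta_from_pmf <- function(pmf, floor_zero = FALSE, reliable_tol = 1e-6) {
  stopifnot(inherits(pmf, "dg_pmf"))
  n <- pmf$n
  log_p <- pmf$log_p
  if (any(!is.finite(log_p))) {
    if (!floor_zero)
      stop("the spike-count distribution has zero entries; the log-linear ",
           "expansion requires full support (use floor_zero = TRUE to ",
           "floor them at 1e-300)", call. = FALSE)
    log_p <- pmax(log_p, log(1e-300))
  }
  log_q <- log_p - lchoose(n, 0:n)
  psi <- -log_q[1]
  theta <- numeric(n)
  err <- numeric(n)
  for (k in seq_len(n)) {
    j <- 0:k
    cf <- choose(k, j) * (-1)^(k - j)
    terms <- cf * log_q[j + 1]
    theta[k] <- sum(terms)
    err[k] <- .Machine$double.eps * sum(abs(terms))
  }
  structure(list(n = n, psi = psi, theta = theta,
                 err_bound = err, reliable = err <= reliable_tol),
            class = "dg_theta")
}

#' @export
print.dg_theta <- function(x, ...) {
  cat(sprintf("Log-linear (theta) expansion, n = %d, psi = %.6g\n",
              x$n, x$psi))
  k <- seq_len(min(6L, x$n))
  cat("  leading orders:\n")
  for (i in k)
    cat(sprintf("   theta_%d = %+.6g%s\n", i, x$theta[i],
                if (x$reliable[i]) "" else "  (unreliable)"))
  if (!all(x$reliable))
    cat(sprintf("  %d of %d orders flagged unreliable (cancellation)\n",
                sum(!x$reliable), x$n))
  invisible(x)
}

#' Spike-count distribution from theta-coordinates
#'
#' Forward direction of the homogeneous log-linear expansion:
#' \eqn{P(m) \propto \binom{n}{m} \exp(\sum_i \binom{m}{i} \theta_i)},
#' normalized over \eqn{m = 0..n}. Computed in the log domain, so any
#' finite `theta` is admissible. Round-trips with [theta_from_pmf()].
#'
#' @param expansion a `"dg_theta"`, or a numeric vector `theta` of length
#'   `n` (\eqn{\psi} is fixed by normalization).
#' @return a `"dg_pmf"`.
#' @export
pmf_from_theta <- function(expansion) {
  theta <- if (inherits(expansion, "dg_theta")) expansion$theta
           else as.numeric(expansion)
  if (any(!is.finite(theta))) stop("'theta' must be finite", call. = FALSE)
  n <- length(theta)
  m <- 0:n
  # logits[m] = lchoose(n, m) + sum_i choose(m, i) theta_i
  inter <- vapply(m, function(mm) {
    if (mm == 0L) 0 else sum(choose(mm, seq_len(mm)) * theta[seq_len(mm)])
  }, numeric(1))
  logits <- lchoose(n, m) + inter
  log_p <- logits - logsumexp(logits)
  structure(list(n = n, p = exp(log_p), log_p = log_p,
                 h = NA_real_, alpha = NA_real_),
            class = "dg_pmf")
}

#' Shannon entropy of the DG population distribution
#'
#' Entropy of the full \eqn{2^n}-pattern distribution, computed through
#' exchangeability from the spike-count distribution:
#' \deqn{H = -\sum_k P(k)\,[\log P(k) - \log \binom{n}{k}].}
#' `level = "count"` instead returns the entropy of the count variable
#' itself, \eqn{-\sum_k P(k) \log P(k)}.
#'
#' @param pmf a `"dg_pmf"`.
#' @param bits report in bits instead of nats.
#' @param level `"pattern"` (default) or `"count"`.
#' @return entropy (nats unless `bits = TRUE`).
#' @export
shannon_entropy <- function(pmf, bits = FALSE, level = c("pattern", "count")) {
  stopifnot(inherits(pmf, "dg_pmf"))
  level <- match.arg(level)
  k <- 0:pmf$n
  p <- pmf$p
  lp <- pmf$log_p
  if (level == "pattern") lp <- lp - lchoose(pmf$n, k)
  ok <- p > 0
  H <- -sum(p[ok] * lp[ok])
  if (bits) H / log(2) else H
}

#' Fisher information of the spike-count distribution w.r.t. firing rate
#'
#' \deqn{I(\mu) = \sum_k P(k; \mu, \alpha)
#'   \left[\partial_\mu \log P(k; \mu, \alpha)\right]^2}
#' at fixed latent correlation \eqn{\alpha}, i.e. the information the
#' population count carries about its own firing rate. The derivative is a
#' central finite difference taken in the latent mean `h` with the step
#' chosen so that the induced firing-rate step is `dmu` (chain rule through
#' \eqn{\mu = \Phi(h)}). For independent neurons (\eqn{\alpha = 0}) this
#' reduces to the binomial value \eqn{n / (\mu(1-\mu))}.
#'
#' Shared variability makes the count *less* informative about the
#' population rate, so under this definition the information decreases with
#' \eqn{\alpha} at matched \eqn{\mu}. The complementary stimulus-decoding
#' view -- how much the count says about the *shared input* \eqn{\varepsilon}
#' driving the pool, averaged over its \eqn{N(0, \alpha)} distribution --
#' instead grows with \eqn{\alpha}; it is available as
#' `about = "common_input"`. See the package vignette for the discussion of
#' the two readings.
#'
#' @param n population size.
#' @param alpha latent correlation in `[0, 1)`.
#' @param mu firing rate, at least 1e-6 away from 0 and 1.
#' @param dmu firing-rate half-step of the finite difference.
#' @param about parameter the information is about: the population firing
#'   rate (`"rate"`, default) or the shared input (`"common_input"`).
#' @return Fisher information (per unit \eqn{\mu^2} for `"rate"`; per unit
#'   shared-input\eqn{^2} for `"common_input"`).
#' @export
fisher_information <- function(n, alpha, mu, dmu = 1e-5,
                               about = c("rate", "common_input")) {
  about <- match.arg(about)
  if (about == "common_input")
    return(fisher_information_input(n, alpha, mu))
  n <- check_count(n, "n")
  check_scalar(alpha, "alpha", 0, 1)
  check_scalar(mu, "mu", 0, 1)
  if (mu < 1e-6 || mu > 1 - 1e-6)
    stop("'mu' must be at least 1e-6 away from {0, 1}", call. = FALSE)
  if (alpha >= 1) stop("'alpha' must lie in [0, 1)", call. = FALSE)
  h <- stats::qnorm(mu)
  dh <- dmu / stats::dnorm(h)
  p0 <- spike_count_pmf(n, h = h, alpha = alpha)
  pp <- spike_count_pmf(n, h = h + dh, alpha = alpha)
  pm <- spike_count_pmf(n, h = h - dh, alpha = alpha)
  dmu_eff <- stats::pnorm(h + dh) - stats::pnorm(h - dh)
  ok <- p0$p > 1e-300 & pp$p > 0 & pm$p > 0
  score <- (pp$log_p[ok] - pm$log_p[ok]) / dmu_eff
  sum(p0$p[ok] * score^2)
}

# Fisher information of the count about the shared input eps:
# k | eps ~ Binomial(n, L(eps)) with L(eps) = Phi((eps + h)/sqrt(1-alpha)),
# I(eps) = n L'(eps)^2 / (L(1-L)), averaged over eps ~ N(0, alpha)
fisher_information_input <- function(n, alpha, mu) {
  n <- check_count(n, "n")
  check_scalar(alpha, "alpha", 0, 1)
  check_scalar(mu, "mu", 1e-6, 1 - 1e-6)
  h <- stats::qnorm(mu)
  s1 <- sqrt(1 - alpha)
  if (alpha == 0) {  # degenerate shared input: conditional information at eps = 0
    L <- stats::pnorm(h / s1)
    return(n * (stats::dnorm(h / s1) / s1)^2 / (L * (1 - L)))
  }
  sa <- sqrt(alpha)
  stats::integrate(function(t) {
    z <- (sa * t + h) / s1
    L <- stats::pnorm(z)
    Lp <- stats::dnorm(z) / s1
    ifelse(L > 0 & L < 1, n * Lp^2 / (L * (1 - L)), 0) * stats::dnorm(t)
  }, lower = -8, upper = 8, rel.tol = 1e-10)$value
}
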