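# integral of g(r) against the asymptotic density, via its exact Gaussian
# representation in u = qnorm(r): u ~ N(mu_u, sd_u^2)
fr_integral <- function(fr, g, nodes = 2001) {
  t <- seq(-8, 8, length.out = nodes)
  u <- fr$mu_u + fr$sd_u * t
  w <- dnorm(t)
  w <- w / sum(w)
  sum(w * g(pnorm(u)))
}

test_that("asymptotic density normalizes to 1 across the parameter range", {
  for (h in c(-0.5, 0, 0.5)) {
    for (a in c(0.1, 0.3, 0.5, 0.8, 0.95)) {
      fr <- asymptotic_density(h, a)
      # direct quadrature of f over (0,1) in u = qnorm(r) coordinates,
      # assembled in the log domain so the boundary growth of f for
      # alpha > 1/2 never meets the Gaussian factor as Inf * 0
      val <- integrate(function(u) exp(fr$log_f_u(u) + dnorm(u, log = TRUE)),
                       fr$mu_u - 8 * fr$sd_u, fr$mu_u + 8 * fr$sd_u,
                       rel.tol = 1e-10)$value
      expect_lt(abs(val - 1), 1e-8)
    }
  }
  expect_error(asymptotic_density(0, 1), "strictly inside")
})

test_that("critical point h = 0, alpha = 1/2: exactly the uniform density", {
  fr <- asymptotic_density(0, 0.5)
  r <- seq(0.01, 0.99, by = 0.01)
  expect_lt(max(abs(fr$f(r) - 1)), 1e-12)
  mom <- asymptotic_cumulants(0, 0.5)
  expect_lt(abs(mom$mu - 1 / 2), 1e-10)
  expect_lt(abs(mom$rho - 1 / 3), 1e-9)
  expect_lt(abs(mom$zeta), 1e-12)
  expect_lt(abs(mom$chi - 1 / 80), 1e-10)
})

test_that("asymptotic cumulants equal direct integrals of f", {
  for (a in c(0.3, 0.8)) {
    fr <- asymptotic_density(0.2, a)
    mom <- asymptotic_cumulants(0.2, a)
    mu <- fr_integral(fr, identity)
    expect_lt(abs(mom$mu - mu), 1e-9)
    expect_lt(abs(mom$sigma - fr_integral(fr, function(r) (r - mu)^2)), 1e-9)
    expect_lt(abs(mom$chi - fr_integral(fr, function(r) (r - mu)^4)), 1e-9)
  }
})

test_that("modality: unimodal below alpha = 1/2, bimodal above, uniform flagged", {
  m1 <- modality(asymptotic_density(0, 0.3))
  expect_equal(as.integer(m1), 1L)
  expect_false(attr(m1, "degenerate"))
  m2 <- modality(asymptotic_density(0, 0.8))
  expect_equal(as.integer(m2), 2L)
  m0 <- modality(asymptotic_density(0, 0.5))
  expect_true(attr(m0, "degenerate"))
  # also from raw density values on a grid
  expect_equal(as.integer(modality(dnorm(seq(-4, 4, 0.01)))), 1L)
  expect_error(modality(c(1, 2)), "at least 3")
})

test_that("modality transition sits at alpha = 1/2 for every latent mean", {
  for (h in c(-0.5, 0, 0.5)) {
    expect_lt(abs(modality_threshold(h) - 0.5), 1e-3)
  }
})

test_that("Monte-Carlo histogram of the active fraction matches f (3 SE)", {
  h <- 0; a <- 0.3
  fr <- asymptotic_density(h, a)
  set.seed(2024)
  N <- 1e6
  r <- pnorm((rnorm(N, sd = sqrt(a)) + h) / sqrt(1 - a))
  breaks <- seq(0, 1, by = 0.05)
  obs <- tabulate(cut(r, breaks, labels = FALSE), nbins = 20) / N
  for (i in seq_len(20)) {
    p <- integrate(fr$f, breaks[i], breaks[i + 1], rel.tol = 1e-10)$value
    expect_lt(abs(obs[i] - p), 3 * sqrt(p * (1 - p) / N) + 1e-12)
  }
})

test_that("tempering at beta = 1 recovers f for every population size", {
  fr <- asymptotic_density(0, 0.8)
  vals <- lapply(c(10, 20, 50), function(n) {
    fb <- tempered_density(fr, n, beta = 1)
    bc <- binder_cumulant(fb)
    c(hdg = entropy_rate(fb), B = bc$B)
  })
  # at beta = 1 the multiplicity term drops out: all n give identical results
  for (i in 2:3) {
    expect_lt(abs(vals[[i]]["hdg"] - vals[[1]]["hdg"]), 1e-12)
    expect_lt(abs(vals[[i]]["B"] - vals[[1]]["B"]), 1e-12)
  }
})

test_that("tempered density is a probability measure; thermo quantities are sane", {
  fr <- asymptotic_density(0, 0.8)
  fb <- tempered_density(fr, 20, beta = 1 / 1.5)
  expect_lt(abs(sum(fb$mass) - 1), 1e-12)
  hdg <- entropy_rate(fb)
  expect_gt(hdg, 0)
  expect_lt(hdg, log(2) + 1e-12)           # per-neuron entropy bound
  expect_gte(specific_heat(fb), 0)
  bc <- binder_cumulant(fb)
  expect_equal(bc$B, 1 - bc$nu4 / (3 * bc$nu2^2), tolerance = 1e-12)
  expect_error(tempered_density(fr, 20, beta = -1), "positive")
})

test_that("exact finite-n tempering at beta = 1 recovers the spike-count pmf", {
  tc <- thermo_curve(12, h = 0, alpha = 0.8, T_grid = 1, exact = TRUE)
  pmf <- spike_count_pmf(12, h = 0, alpha = 0.8)
  k <- 0:12
  eta <- function(r) ifelse(r <= 0 | r >= 1, 0, -r * log(r) - (1 - r) * log(1 - r))
  expect_lt(abs(tc$hdg - sum(pmf$p * eta(k / 12))), 1e-12)
})

test_that("crossing_temperature demands comparable input and finds crossings", {
  curves <- standard_thermo()
  expect_error(crossing_temperature(curves[1]), "at least two")
  expect_error(crossing_temperature(list(curves[[1]], curves[[1]])),
               "identical")
  short <- thermo_curve(10, 0, 0.8, T_grid = seq(0.9, 1.1, by = 0.01))
  expect_error(crossing_temperature(list(curves[[1]], short)), "common")
  ct <- crossing_temperature(curves)
  expect_lt(abs(as.numeric(ct) - 1), 0.01)
  expect_lt(attr(ct, "spread"), 0.01)
})
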