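test_that("dg_model moment map and inverse parametrisation agree", {
  m <- dg_model(50, h = 0.5, alpha = 0.4)
  expect_equal(m$mu, pnorm(0.5))
  expect_equal(m$sigma, output_cov(0.5, 0.5, 0.4), tolerance = 1e-14)
  expect_equal(m$rho, m$sigma / (m$mu * (1 - m$mu)), tolerance = 1e-14)
  expect_equal(unname(coef(m)), c(0.5, 0.4))

  m2 <- dg_model(50, mu = m$mu, rho = m$rho)
  expect_lt(abs(m2$h - m$h), 1e-9)
  expect_lt(abs(m2$alpha - m$alpha), 1e-8)

  expect_error(dg_model(50), "exactly one of")
  expect_error(dg_model(50, h = 0, alpha = 0.4, mu = 0.5, rho = 0.1),
               "exactly one of")
  expect_error(dg_model(50, h = 0, alpha = 1), "alpha")
  expect_error(dg_model(0, h = 0, alpha = 0.4), "n")
})

test_that("summary() returns the model's output moments", {
  m <- dg_model(50, h = 0.2, alpha = 0.6)
  s <- summary(m)
  expect_s3_class(s, "dg_moments")
  expect_equal(s$zeta, third_central_moment(rep(0.2, 3), equicorr(3, 0.6)),
               tolerance = 1e-12)
  expect_equal(s$chi, fourth_central_moment(rep(0.2, 4), equicorr(4, 0.6)),
               tolerance = 1e-12)
})

test_that("simulate() is reproducible, binary and leaves the RNG alone", {
  m <- dg_model(8, h = -0.2, alpha = 0.3)
  set.seed(999); before <- runif(1)
  set.seed(999)
  r1 <- simulate(m, nsim = 40, seed = 7)
  expect_equal(runif(1), before)           # caller RNG untouched
  r2 <- simulate(m, nsim = 40, seed = 7)
  expect_identical(unclass(r1)[, ], unclass(r2)[, ])
  expect_true(all(r1 %in% 0:1))
  expect_equal(dim(r1), c(40L, 8L))
  expect_s3_class(r1, "dg_raster")
  r3 <- simulate(m, nsim = 40, seed = 8)
  expect_false(identical(unclass(r1)[, ], unclass(r3)[, ]))
  expect_error(simulate(m, nsim = 10), "seed")
})

test_that("spike-count distribution: normalization, binomial limit, symmetry", {
  pmf <- spike_count_pmf(50, h = 0.3, alpha = 0.6)
  expect_lt(abs(sum(pmf$p) - 1), 1e-12)
  expect_true(all(pmf$p >= 0))

  # alpha = 0 short-circuits to Binomial(n, Phi(h))
  p0 <- spike_count_pmf(12, h = -0.4, alpha = 0)
  expect_equal(p0$p, dbinom(0:12, 12, pnorm(-0.4)), tolerance = 1e-14)

  # h -> -h flips spikes and silences: P_k(h) = P_{n-k}(-h)
  pa <- spike_count_pmf(15, h = 0.7, alpha = 0.5)
  pb <- spike_count_pmf(15, h = -0.7, alpha = 0.5)
  expect_equal(pa$p, rev(pb$p), tolerance = 1e-12)

  expect_error(spike_count_pmf(10, h = 0, alpha = 1), "alpha")
})

test_that("spike-count moments match the analytic output moments", {
  n <- 30; h <- 0.25; a <- 0.45
  pmf <- spike_count_pmf(n, h = h, alpha = a)
  k <- 0:n
  mu <- pnorm(h)
  sig <- output_cov(h, h, a)
  m1 <- sum(k * pmf$p)
  v <- sum(k^2 * pmf$p) - m1^2
  expect_lt(abs(m1 - n * mu), 1e-10)
  expect_lt(abs(v - (n * mu * (1 - mu) + n * (n - 1) * sig)), 1e-9)
})

test_that("Monte-Carlo raster statistics agree with analytic moments (3 SE)", {
  m <- dg_model(50, h = 0.2, alpha = 0.6)
  r <- simulate(m, nsim = 1e5, seed = 424242)
  est <- empirical_cumulants(r)
  se <- attr(est, "se")
  an <- homogeneous_cumulants(m)
  expect_lt(abs(est$mu - an$mu), 3 * se["mu"])
  expect_lt(abs(est$rho - an$rho), 3 * se["rho"])
  expect_lt(abs(est$zeta - an$zeta), 3 * se["zeta"])
  expect_lt(abs(est$chi - an$chi), 3 * se["chi"])
})

test_that("empirical cumulants equal the brute-force tuple enumeration", {
  m <- dg_model(6, h = -0.3, alpha = 0.5)
  r <- simulate(m, nsim = 60, seed = 11)
  est <- empirical_cumulants(r)
  expect_equal(est$sigma, oracle_tuple_average(r, 2), tolerance = 1e-12)
  expect_equal(est$zeta, oracle_tuple_average(r, 3), tolerance = 1e-12)
  expect_equal(est$chi, oracle_tuple_average(r, 4), tolerance = 1e-12)
})

test_that("empirical cumulants validate their input", {
  expect_error(empirical_cumulants(matrix(0.5, 4, 6)), "0/1")
  expect_error(empirical_cumulants(matrix(0L, 1, 6)), "2 trials")
  expect_error(empirical_cumulants(matrix(0L, 10, 3)), "4 neurons")
  x <- matrix(rbinom(60, 1, 0.5), 10, 6)
  x[, 2] <- 1L                             # constant column
  expect_warning(empirical_cumulants(x), "constant")
})
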