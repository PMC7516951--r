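test_that("theta round trip: pmf_from_theta then theta_from_pmf", {
  theta <- 2 * (-0.55)^(1:10)              # decaying interaction strengths
  pmf <- pmf_from_theta(theta)
  expect_lt(abs(sum(pmf$p) - 1), 1e-14)
  back <- theta_from_pmf(pmf)
  expect_lt(max(abs(back$theta - theta)), 1e-8)
  expect_true(all(back$reliable))
})

test_that("theta inversion matches the 2^n subset-enumeration oracle", {
  pmf <- spike_count_pmf(6, h = 0.2, alpha = 0.4)
  th <- theta_from_pmf(pmf)
  expect_lt(max(abs(th$theta - oracle_theta_enum(pmf))), 1e-8)
  expect_equal(th$psi, -(pmf$log_p[1] - lchoose(6, 0)), tolerance = 1e-12)
})

test_that("theta expansion reproduces every pattern log-probability", {
  n <- 6
  pmf <- spike_count_pmf(n, h = -0.3, alpha = 0.55)
  th <- theta_from_pmf(pmf)
  # log Q(m) = sum_i C(m,i) theta_i - psi for every pattern weight m
  log_q <- pmf$log_p - lchoose(n, 0:n)
  for (m in 0:n) {
    pred <- if (m == 0) -th$psi else
      sum(choose(m, seq_len(m)) * th$theta[seq_len(m)]) - th$psi
    expect_lt(abs(pred - log_q[m + 1]), 1e-8)
  }
})

test_that("independent pool: theta_1 is the logit, higher orders vanish", {
  mu <- 0.35
  pmf <- spike_count_pmf(10, h = qnorm(mu), alpha = 0)
  th <- theta_from_pmf(pmf)
  expect_lt(abs(th$theta[1] - log(mu / (1 - mu))), 1e-10)
  expect_lt(max(abs(th$theta[-1])), 1e-8)
})

test_that("theta support handling and reliability flags", {
  p <- c(0.5, 0.5, rep(0, 4))              # zero entries: no full support
  pmf <- structure(list(n = 5L, p = p, log_p = log(p),
                        h = NA_real_, alpha = NA_real_), class = "dg_pmf")
  expect_error(theta_from_pmf(pmf), "full support")
  th <- theta_from_pmf(pmf, floor_zero = TRUE)
  expect_true(all(is.finite(th$theta)))
  expect_true(all(th$err_bound > 0))
  # the cancellation bound grows with the floored |log Q|; with a tight
  # tolerance the affected orders are flagged
  th2 <- theta_from_pmf(pmf, floor_zero = TRUE, reliable_tol = 1e-14)
  expect_true(any(!th2$reliable))
})

test_that("pure pairwise interactions induce nonzero higher-order theta only via thresholding", {
  # DG model at moderate correlation: alternating signs of orders 2..4
  th <- theta_from_pmf(spike_count_pmf(50, h = qnorm(0.3), alpha = 0.6))
  expect_gt(th$theta[2], 0)
  expect_lt(th$theta[3], 0)
  expect_gt(th$theta[4], 0)
  expect_true(all(th$reliable[1:10]))
})

test_that("entropy: binomial limit, units, pattern/count decomposition", {
  n <- 14; mu <- 0.3
  pmf <- spike_count_pmf(n, h = qnorm(mu), alpha = 0)
  hb <- -mu * log(mu) - (1 - mu) * log(1 - mu)
  expect_lt(abs(shannon_entropy(pmf) - n * hb), 1e-10)
  expect_equal(shannon_entropy(pmf, bits = TRUE),
               shannon_entropy(pmf) / log(2), tolerance = 1e-14)
  # H_pattern = H_count + E[log C(n, k)]
  pmf2 <- spike_count_pmf(n, h = 0.2, alpha = 0.5)
  gap <- sum(pmf2$p * lchoose(n, 0:n))
  expect_lt(abs(shannon_entropy(pmf2) -
                  (shannon_entropy(pmf2, level = "count") + gap)), 1e-12)
})

test_that("entropy decreases as the shared-input correlation grows", {
  n <- 50; mu <- 0.3
  H <- vapply(c(0.1, 0.4, 0.9), function(a)
    shannon_entropy(spike_count_pmf(n, h = qnorm(mu), alpha = a)), numeric(1))
  expect_true(all(diff(H) < 0))
})

test_that("Fisher information: binomial limit and monotonicity in alpha", {
  n <- 20; mu <- 0.3
  expect_equal(fisher_information(n, 0, mu), n / (mu * (1 - mu)),
               tolerance = 1e-6)
  # information about the rate decreases with shared variability ...
  I_rate <- vapply(c(0.1, 0.4, 0.9), function(a)
    fisher_information(n, a, mu), numeric(1))
  expect_true(all(diff(I_rate) < 0))
  # ... while information about the shared input increases with it
  I_in <- vapply(c(0.1, 0.4, 0.9), function(a)
    fisher_information(n, a, mu, about = "common_input"), numeric(1))
  expect_true(all(diff(I_in) > 0))
  expect_error(fisher_information(n, 0.4, 1e-9), "away from")
})
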