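test_that("fished fraction and instantaneous mortality are mutual inverses", {
  expect_equal(fraction_to_rate(0), 0)
  expect_equal(rate_to_fraction(1), 1 - exp(-1), tolerance = 1e-12)
  F <- seq(0.1, 0.9, by = 0.1)
  expect_equal(rate_to_fraction(fraction_to_rate(F)), F, tolerance = 1e-12)
  f <- c(0.01, 0.5, 2, 10)
  expect_equal(fraction_to_rate(rate_to_fraction(f)), f, tolerance = 1e-12)
  expect_error(fraction_to_rate(1), "\\[0, 1\\)")
  expect_error(fraction_to_rate(-0.1), "\\[0, 1\\)")
  expect_error(rate_to_fraction(-1), "non-negative")
})

test_that("gompertz_step matches elementwise brute-force evaluation", {
  p <- random_stable_params(3)
  set.seed(5)
  x <- runif(4, 5, 200)
  f <- runif(4, 0, 0.5)
  eps <- rnorm(4, 0, 0.1)
  got <- gompertz_step(x, p, f, eps)
  # scalar re-computation of x_i * exp(r_i - f_i + sum_j A_ij log x_j + e_i)
  want <- vapply(1:4, function(i) {
    acc <- p$r[i] - f[i] + eps[i]
    for (j in 1:4) acc <- acc + p$A[i, j] * log(x[j])
    x[i] * exp(acc)
  }, 0)
  expect_equal(got, want, tolerance = 1e-12)
  expect_true(all(got > 0))
  expect_error(gompertz_step(c(-1, 1, 1, 1), p), "positive")
})

test_that("the interior equilibrium is a fixed point of the noise-free map", {
  for (seed in 1:5) {
    p <- random_stable_params(seed)
    f <- abs(rnorm(4, 0.2, 0.1))
    xstar <- equilibrium_biomass(p, f)
    expect_equal(gompertz_step(xstar, p, f) / xstar, rep(1, 4),
                 tolerance = 1e-10)
  }
  # one-group reduction: r = 0, a = 1 maps any state to 1
  p1 <- list(r = 0, A = matrix(-1, 1, 1))
  expect_equal(gompertz_step(7.3, p1), 1)
  # kappa = exp(r/a) is the scalar unfished equilibrium
  p1 <- list(r = 0.8, A = matrix(-0.4, 1, 1))
  expect_equal(equilibrium_biomass(p1), exp(0.8 / 0.4), tolerance = 1e-12)
})

test_that("transition density matches per-component lognormal oracle", {
  p <- random_stable_params(2)
  set.seed(11)
  x <- runif(4, 10, 100)
  xn <- runif(4, 10, 100)
  f <- runif(4, 0, 0.3)
  got <- transition_logdensity(xn, x, p, f)
  delta <- vapply(1:4, function(i)
    log(x[i]) + p$r[i] - f[i] + sum(p$A[i, ] * log(x)), 0)
  # independent per-component evaluation via the normal density of log x
  want <- sum(vapply(1:4, function(i)
    dnorm(log(xn[i]), delta[i], p$eta[i], log = TRUE) - log(xn[i]), 0))
  expect_equal(got, want, tolerance = 1e-12)
  # at the location the quadratic form vanishes
  at_mode <- transition_logdensity(exp(delta), x, p, f)
  expect_equal(at_mode,
               sum(-delta - 0.5 * log(2 * pi * p$eta^2)),
               tolerance = 1e-12)
})

test_that("transition density integrates to one (importance-sampling check)", {
  p <- random_stable_params(4)
  x <- c(20, 40, 60, 15)
  f <- rep(0.2, 4)
  delta <- log(x) + p$r - f + drop(p$A %*% log(x))
  set.seed(99)
  n <- 2e4
  # proposal: wider lognormal around the same location
  prop_sd <- 1.5 * p$eta
  xs <- matrix(rlnorm(4 * n, delta, prop_sd), 4, n)
  logw <- apply(xs, 2, function(xn)
    transition_logdensity(xn, x, p, f) -
      sum(dlnorm(xn, delta, prop_sd, log = TRUE)))
  est <- mean(exp(logw))
  se <- sd(exp(logw)) / sqrt(n)
  expect_lt(abs(est - 1), 3 * se + 1e-3)
})

test_that("simulated trajectories are reproducible and ergodic", {
  p <- random_stable_params(6)
  t1 <- simulate_trajectory(p, 30, F = 0.2, seed = 123)
  t2 <- simulate_trajectory(p, 30, F = 0.2, seed = 123)
  expect_identical(t1$x, t2$x)
  expect_true(all(t1$x > 0))

  # noise-free monotone approach to the one-group equilibrium
  p1 <- list(r = 0.5, A = matrix(-0.6, 1, 1), eta = 0.1)
  kappa <- exp(0.5 / 0.6)
  for (x0 in c(kappa / 4, kappa * 4)) {
    tr <- simulate_trajectory(p1, 40, x0 = x0, noise = FALSE)
    d <- diff(as.numeric(tr$x))
    expect_true(all(d > 0) || all(d < 0))
    expect_equal(as.numeric(tr$x[, 40]), kappa, tolerance = 1e-4)
  }

  # ergodic average of log biomass matches -A^{-1}(r - f) within 3 MC SEs
  f <- rep(0.1, 4)
  tr <- simulate_trajectory(p, 1e5, f = f, seed = 77,
                            x0 = equilibrium_biomass(p, f))
  lx <- t(log(tr$x))
  m_hat <- colMeans(lx)
  m <- -solve(p$A, p$r - f)
  # batch-means standard error accounting for autocorrelation
  nb <- 100
  bm <- apply(lx, 2, function(v) tapply(v, rep(1:nb, each = 1e3), mean))
  se <- apply(bm, 2, sd) / sqrt(nb)
  expect_true(all(abs(m_hat - m) < 3 * se))
})
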