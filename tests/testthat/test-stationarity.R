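test_that("stationarity is decided by the spectral radius of I + A", {
  chk <- is_stationary(-0.5 * diag(3))
  expect_true(chk$stationary)
  expect_equal(chk$spectral_radius, 0.5, tolerance = 1e-12)
  chk0 <- is_stationary(matrix(0, 2, 2))
  expect_false(chk0$stationary)
  expect_equal(chk0$spectral_radius, 1)
})

test_that("scalar Lyapunov solution matches the geometric-series closed form", {
  for (a in c(0.1, 0.5, 0.9)) {
    s <- 0.3
    p <- list(r = 0.4, A = matrix(-a, 1, 1), eta = s)
    sol <- solve_stationary(p, f = 0.1)
    expect_equal(as.numeric(sol$P), s^2 / (1 - (1 - a)^2),
                 tolerance = 1e-10)
    expect_equal(as.numeric(sol$m), (0.4 - 0.1) / a, tolerance = 1e-12)
  }
  # unfished one-group median is kappa = exp(r/a)
  p <- list(r = 0.6, A = matrix(-0.3, 1, 1), eta = 0.1)
  expect_equal(as.numeric(solve_stationary(p, 0)$median), exp(2),
               tolerance = 1e-10)
})

test_that("Lyapunov residual vanishes and quantiles are ordered", {
  for (seed in c(2, 7, 21)) {
    p <- random_stable_params(seed)
    sol <- solve_stationary(p, f = 0.2)
    B <- diag(4) + p$A
    resid <- sol$P - B %*% sol$P %*% t(B) - diag(p$eta^2)
    expect_lt(max(abs(resid)), 1e-8)
    expect_true(all(eigen(sol$P, only.values = TRUE)$values > -1e-10))
    qs <- sol$quantile(c(0.05, 0.25, 0.5, 0.75, 0.95))
    expect_true(all(apply(qs, 1, diff) > 0))
    expect_equal(unname(sol$quantile(0.5)[, 1]), unname(sol$median),
                 tolerance = 1e-12)
  }
  p <- random_stable_params(2)
  p$A <- matrix(0, 4, 4)
  expect_error(solve_stationary(p, 0), "not stationary")
})

test_that("long simulations reproduce the stationary moments", {
  p <- random_stable_params(5)
  f <- rep(0.1, 4)
  sol <- solve_stationary(p, f)
  tr <- simulate_trajectory(p, 2e5, f = f, seed = 55, x0 = sol$median)
  lx <- t(log(tr$x))
  nb <- 100
  grp <- rep(1:nb, each = nrow(lx) / nb)
  bm <- apply(lx, 2, function(v) tapply(v, grp, mean))
  se_m <- apply(bm, 2, sd) / sqrt(nb)
  expect_true(all(abs(colMeans(lx) - sol$m) < 3 * se_m))
  # marginal variances against diag(P), batch-estimated SEs
  bv <- apply(lx, 2, function(v) tapply(v, grp, var))
  se_v <- apply(bv, 2, sd) / sqrt(nb)
  expect_true(all(abs(apply(lx, 2, var) - diag(sol$P)) < 3 * se_v))
})

test_that("scenario mortality vectors follow their defining rules", {
  fit <- shared_fit()
  f0 <- scenario_f(fit, "f0")
  expect_true(all(f0 == 0))
  favg <- scenario_f(fit, "fAvg")
  d <- extract_draws(fit)
  # per-draw arithmetic mean of f(t) = -log(1 - F(t)) over the years
  want1 <- rowMeans(-log1p(-d$F_arr[, 1, ]))
  expect_equal(unname(favg[, "K"]), want1, tolerance = 1e-12)
  fg <- scenario_f(fit, "fG")
  expect_true(all(fg[, "G"] == 0))
  expect_equal(fg[, c("K", "B", "D")], favg[, c("K", "B", "D")])
  fmt <- scenario_f(fit, "fMT")
  expect_equal(unname(fmt[, "B"]), unname(0.38 * favg[, "B"]),
               tolerance = 1e-12)
  expect_equal(unname(fmt[, "D"]), unname(0.55 * favg[, "D"]),
               tolerance = 1e-12)
  expect_equal(fmt[, c("K", "G")], favg[, c("K", "G")])
})

test_that("scenario projections obey the closed-form elasticity transfer", {
  fit <- shared_fit()
  proj <- project_scenarios(fit, c("f0", "fAvg", "fG"))
  expect_s3_class(proj, "gssm_scenarios")
  s <- proj$summary
  bio <- s[s$quantity %in% c("median_biomass", "mean_biomass"), ]
  expect_true(all(bio$q05 < bio$median & bio$median < bio$q95))
  # landings quantities degenerate to zero under the no-fishing scenario
  expect_true(all(s$q05 <= s$median & s$median <= s$q95))
  expect_true(all(s$median[s$scenario == "f0" &
                             grepl("landings", s$quantity)] == 0))

  # per-draw check: log-median difference between scenarios equals
  # -A^{-1} applied to the mortality difference, exactly
  d <- extract_draws(fit)
  favg <- scenario_f(fit, "fAvg")
  fg <- scenario_f(fit, "fG")
  set.seed(1)
  for (k in sample(nrow(d$r), 25)) {
    A <- matrix(d$A[k, ], 4, 4)
    if (!is_stationary(A)$stationary) next
    p <- list(r = d$r[k, ], A = A, eta = d$eta[k, ])
    m_avg <- solve_stationary(p, favg[k, ])
    m_g <- solve_stationary(p, fg[k, ])
    # median shift under the release equals -A^{-1} (f_avg - f_G)
    expect_equal(log(m_g$median) - log(m_avg$median),
                 drop(-solve(A) %*% (favg[k, ] - fg[k, ])),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # relaxing fishing can only raise medians when the elasticity column
    # of the released group is non-negative
    Minv <- -solve(A)
    relax_col <- Minv[, 4]  # group G released under fG
    if (all(relax_col >= 0))
      expect_true(all(m_g$median >= m_avg$median - 1e-10))
  }

  # a scenario handed fAvg's own mortalities reproduces fAvg exactly
  proj2 <- project_scenarios(fit, list(a = favg, b = favg))
  sa <- proj2$summary[proj2$summary$scenario == "a", -1]
  sb <- proj2$summary[proj2$summary$scenario == "b", -1]
  expect_equal(sa, sb, ignore_attr = TRUE)
})
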