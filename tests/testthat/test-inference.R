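test_that("log posterior equals the sum of its component densities", {
  st <- ecosystem_structure()
  study <- shared_study()
  panel <- study$panel
  cfg <- prior_config()
  p <- study$truth
  x <- study$trajectory$x
  got <- log_posterior(p, x, panel, cfg, st)
  f <- -log1p(-p$F)
  want <- log_prior_density(p, cfg, st) +
    landings_loglik(panel, x, p$F, cfg$landings_logvar) +
    cpue_loglik(panel, x, p$q, p$sigma)
  for (t in 2:ncol(x))
    want <- want + transition_logdensity(x[, t], x[, t - 1], p, f[, t - 1])
  expect_equal(got, want, tolerance = 1e-10)

  # with all CPUE removed only prior + process + landings terms remain
  empty <- observation_panel(panel$cpue[0, ], panel$landings, st)
  expect_equal(log_posterior(p, x, empty, cfg, st),
               got - cpue_loglik(panel, x, p$q, p$sigma),
               tolerance = 1e-10)

  bad <- p
  bad$A[1, 1] <- -1.5
  expect_identical(log_posterior(bad, x, panel, cfg, st), -Inf)
})

test_that("chain initialization is feasible and deterministic", {
  st <- ecosystem_structure()
  study <- shared_study()
  cfg <- prior_config()
  h <- landings_matrix(study$panel)
  ini1 <- initialize_chain(study$panel, cfg, st, seed = 5)
  ini2 <- initialize_chain(study$panel, cfg, st, seed = 5)
  expect_identical(ini1, ini2)
  expect_true(all(ini1$x >= h))          # feasible harvest sequence
  expect_true(all(ini1$F > 0 & ini1$F < 1))
  expect_true(all(ini1$q > 0))
  expect_true(all(ini1$amag >= 0 & ini1$amag <= 1))
  ini3 <- initialize_chain(study$panel, cfg, st, seed = 6)
  expect_false(identical(ini1$x, ini3$x))
})

test_that("MCMC runs are reproducible and respect support constraints", {
  study <- shared_study()
  pr <- reduced_protocol(n_chains = 2, n_adapt = 200, n_iter = 300,
                         thin = 1, seed = 21)
  f1 <- gompertz_ssm(study$panel, protocol = pr)
  f2 <- gompertz_ssm(study$panel, protocol = pr)
  expect_identical(as.matrix(f1$draws), as.matrix(f2$draws))
  d <- extract_draws(f1)
  expect_true(all(d$amag >= 0 & d$amag <= 1))
  expect_true(all(d$eta > 0) && all(d$sigma > 0) && all(d$q > 0))
  expect_true(all(d$F_arr > 0 & d$F_arr < 1))
  expect_true(all(is.finite(d$x_arr)) && all(d$x_arr > 0))
})

test_that("the posterior ties fished landings to the recorded harvest", {
  fit <- shared_fit()
  d <- extract_draws(fit)
  h <- landings_matrix(fit$panel)
  implied <- apply(d$F_arr * d$x_arr, c(2, 3), mean)
  expect_true(all(abs(implied / h - 1) < 0.05))
})

test_that("potential scale reduction factors behave canonically", {
  set.seed(9)
  base <- matrix(rnorm(5000), 1000, 5,
                 dimnames = list(NULL, paste0("p", 1:5)))
  copies <- list(base, base, base)
  gr <- gelman_rubin(copies)
  # B = 0 gives the classic estimator sqrt((n-1)/n), i.e. 1 - 1/(2n)
  expect_equal(gr$psrf, rep(1, 5), tolerance = 1e-3)

  shifted <- list(base, base + 10)
  gr2 <- gelman_rubin(shifted)
  expect_true(all(gr2$psrf > 5))

  iid <- lapply(1:4, function(i)
    matrix(rnorm(1e4), 1e4, 1, dimnames = list(NULL, "a")))
  gr3 <- gelman_rubin(iid)
  expect_true(gr3$psrf > 0.99 && gr3$psrf < 1.02)
  expect_gte(gr3$upper, gr3$psrf)

  # agreement with the coda reference implementation
  ml <- coda::mcmc.list(lapply(1:3, function(i)
    coda::mcmc(matrix(rnorm(3000, sd = 1 + i / 10), 1000, 3,
                      dimnames = list(NULL, paste0("v", 1:3))))))
  mine <- gelman_rubin(ml)
  ref <- coda::gelman.diag(ml, autoburnin = FALSE, multivariate = FALSE)$psrf
  expect_equal(mine$psrf, unname(ref[, 1]), tolerance = 0.01)
  expect_equal(mine$upper, unname(ref[, 2]), tolerance = 0.02)
  expect_error(gelman_rubin(list(base)), "2 chains")
})

test_that("posterior summaries answer the standard queries", {
  fit <- shared_fit()
  qs <- posterior_summary(fit, "quantiles")
  expect_true(all(qs$q05 <= qs$median & qs$median <= qs$q95))
  ex <- posterior_summary(fit, "exceed", threshold = 0)
  expect_true(all(ex$prob == 1))  # magnitudes are positive
  pw <- posterior_summary(fit, "pairwise")
  expect_equal(nrow(pw), 4L)  # the four predator-prey pairs
  expect_true(all(pw$prob >= 0 & pw$prob <= 1))
  ps <- posterior_summary(fit, "stationary")
  expect_true(ps >= 0 && ps <= 1)
})

test_that("fit methods expose coherent estimates", {
  fit <- shared_fit()
  est <- coef(fit)
  expect_s3_class(est, "gssm_params")
  expect_true(all(abs(est$A[fit$structure$sign_pattern == 0 &
                              row(est$A) != col(est$A)]) < 1e-12))
  ls <- latent_states(fit)
  expect_true(all(ls$q05 < ls$median & ls$median < ls$q95))
  pr <- predict(fit)
  expect_true(all(pr$median > 0))
  sim <- simulate(fit, nsim = 20, seed = 3, n_years = 5)
  expect_equal(dim(sim), c(20L, 4L, 6L))
  expect_true(all(sim > 0))
  res <- residuals(fit)
  expect_true(all(is.finite(res$residual)))
  expect_lt(abs(mean(res$residual)), 0.5)
})
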