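test_that("panel validation enforces targeting, positivity and uniqueness", {
  st <- ecosystem_structure()
  study <- shared_study()
  cp <- study$panel$cpue
  ld <- study$panel$landings
  expect_s3_class(observation_panel(cp, ld, st), "obs_panel")
  bad <- cp
  bad$group[bad$gear == "Pot"][1] <- "G"  # Pot does not target G
  expect_error(observation_panel(bad, ld, st), "non-targeted")
  bad <- rbind(cp, cp[1, ])
  expect_error(observation_panel(bad, ld, st), "duplicate")
  bad <- cp
  bad$effort[5] <- -1
  expect_error(observation_panel(bad, ld, st), "positive")
  bad <- cp
  bad$gear[1] <- "Trap"
  expect_error(observation_panel(bad, ld, st), "unknown gear")
})

test_that("CPUE likelihood matches per-record lognormal oracle", {
  st <- ecosystem_structure()
  study <- shared_study()
  panel <- study$panel
  x <- study$trajectory$x
  q <- study$truth$q
  sigma <- study$truth$sigma
  got <- cpue_loglik(panel, x, q, sigma)
  cp <- panel$cpue
  want <- 0
  for (rr in seq_len(nrow(cp))) {
    xi <- x[cp$group[rr], as.character(cp$year[rr])]
    qv <- q[paste(cp$gear[rr], cp$group[rr], sep = ":")]
    want <- want + dlnorm(cp$catch[rr],
                          log(qv * cp$effort[rr] * xi),
                          sigma[cp$gear[rr]], log = TRUE)
  }
  expect_equal(got, unname(want), tolerance = 1e-10)

  # single record at the location: kernel reduces to -log C - log sd term
  one <- observation_panel(cp[1, ], panel$landings, st)
  xi <- x[cp$group[1], as.character(cp$year[1])]
  qv <- q[paste(cp$gear[1], cp$group[1], sep = ":")]
  sv <- sigma[cp$gear[1]]
  C <- qv * cp$effort[1] * xi
  one$cpue$catch <- C
  expect_equal(cpue_loglik(one, x, q, sigma),
               unname(-log(C) - 0.5 * log(2 * pi * sv^2)),
               tolerance = 1e-10)

  # doubling effort with catch fixed shifts the location by log 2
  two <- one
  two$cpue$effort <- 2 * one$cpue$effort
  expect_equal(cpue_loglik(two, x, q, sigma) - cpue_loglik(one, x, q, sigma),
               unname(dnorm(log(C), log(C) + log(2), sv, log = TRUE) -
                        dnorm(log(C), log(C), sv, log = TRUE)),
               tolerance = 1e-10)
})

test_that("landings likelihood is the near-deterministic lognormal tie", {
  study <- shared_study()
  panel <- study$panel
  x <- study$trajectory$x
  F <- study$truth$F
  got <- landings_loglik(panel, x, F)
  ld <- panel$landings
  want <- sum(vapply(seq_len(nrow(ld)), function(rr) {
    dlnorm(ld$landings[rr],
           log(F[ld$group[rr], as.character(ld$year[rr])]) +
             log(x[ld$group[rr], as.character(ld$year[rr])]),
           sqrt(0.001), log = TRUE)
  }, 0))
  expect_equal(got, want, tolerance = 1e-10)
  # exact h = F x maximizes each record's kernel
  exact <- panel
  idx <- cbind(match(ld$group, rownames(x)),
               match(as.character(ld$year), colnames(x)))
  exact$landings$landings <- F[idx] * x[idx]
  expect_gt(landings_loglik(exact, x, F), got)
})

test_that("simulated observations recover their generating scales", {
  st <- ecosystem_structure()
  x <- matrix(c(100, 30, 70, 25), 4, 3,
              dimnames = list(st$groups, 2001:2003))
  F <- matrix(0.3, 4, 3, dimnames = list(st$groups, 2001:2003))
  q <- setNames(rep(0.01, 18), st$combos$combo)
  sigma <- setNames(rep(0.25, 8), st$gears)
  effort <- matrix(100, 8, 2, dimnames = list(st$gears, 2002:2003))
  panel <- simulate_observations(x, F, q, sigma, effort, st, seed = 5)
  expect_s3_class(panel, "obs_panel")
  expect_equal(nrow(panel$cpue), 36L)  # 18 combos x 2 years

  # near-degenerate noise returns C ~= qEx and h ~= Fx
  p0 <- simulate_observations(x, F, q, sigma = setNames(rep(1e-10, 8),
                                                        st$gears),
                              effort, st, landings_logvar = 1e-20, seed = 6)
  gi <- match(p0$cpue$group, st$groups)
  yi <- match(as.character(p0$cpue$year), colnames(x))
  expect_equal(p0$cpue$catch, 0.01 * p0$cpue$effort * x[cbind(gi, yi)],
               tolerance = 1e-6)
  li <- cbind(match(p0$landings$group, st$groups),
              match(as.character(p0$landings$year), colnames(x)))
  expect_equal(p0$landings$landings, F[li] * x[li], tolerance = 1e-6)

  # sd of log(C / qEx) concentrates at sigma over replicates
  lr <- unlist(lapply(1:50, function(s) {
    p <- simulate_observations(x, F, q, sigma, effort, st, seed = 100 + s)
    gi <- match(p$cpue$group, st$groups)
    yi <- match(as.character(p$cpue$year), colnames(x))
    log(p$cpue$catch / (0.01 * p$cpue$effort * x[cbind(gi, yi)]))
  }))
  expect_equal(sd(lr), 0.25, tolerance = 0.02)
})

test_that("dropping a year's CPUE changes the likelihood by that year's term", {
  st <- ecosystem_structure()
  study <- shared_study()
  panel <- study$panel
  x <- study$trajectory$x
  yr <- panel$cpue_years[4]
  keep <- panel$cpue$year != yr
  sub <- observation_panel(panel$cpue[keep, ], panel$landings, st)
  onl <- observation_panel(panel$cpue[!keep, ], panel$landings, st)
  expect_equal(cpue_loglik(panel, x, study$truth$q, study$truth$sigma),
               cpue_loglik(sub, x, study$truth$q, study$truth$sigma) +
                 cpue_loglik(onl, x, study$truth$q, study$truth$sigma),
               tolerance = 1e-10)
})
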