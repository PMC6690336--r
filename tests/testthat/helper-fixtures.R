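# Shared fixtures, built in code and cached for the duration of a test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

shared_study <- function() cached("study", generate_study(seed = 42))

# one moderately sized posterior fit reused across test files
shared_fit <- function() cached("fit", gompertz_ssm(
  shared_study()$panel,
  protocol = reduced_protocol(n_chains = 2, n_adapt = 1500, n_iter = 3000,
                              thin = 3, seed = 7)))

shared_prior_fit <- function() cached("prior_fit", gompertz_ssm(
  shared_study()$panel, likelihood = FALSE,
  protocol = reduced_protocol(n_chains = 2, n_adapt = 500, n_iter = 5000,
                              thin = 2, seed = 11)))

# small random stationary parameter set (no panel machinery)
random_stable_params <- function(seed = 1, structure = ecosystem_structure()) {
  set.seed(seed)
  repeat {
    sp <- structure$sign_pattern
    amag <- matrix(runif(16, 0.05, 0.6), 4, 4)
    diag(amag) <- runif(4, 0.3, 0.9)
    A <- sp * amag
    if (is_stationary(A)$stationary) break
  }
  model_params(r = rnorm(4, 0.5, 0.5), A = A, eta = runif(4, 0.05, 0.3),
               x0 = runif(4, 10, 100), structure = structure)
}

# a fabricated minimal fit object with constant draws, for closed-form
# checks of the predictive machinery
constant_draw_fit <- function(q = 0.01, x = 50, sigma = 0.3, nd = 4000,
                              seed = 1) {
  set.seed(seed)
  st <- ecosystem_structure()
  study <- shared_study()
  n <- st$n_groups
  Tl <- length(study$panel$landings_years)
  nm <- c(paste0("r[", 1:4, "]"),
          paste0("amag[", rep(1:4, 4), ",", rep(1:4, each = 4), "]"),
          paste0("eta[", 1:4, "]"), paste0("sigma[", 1:8, "]"),
          paste0("q[", 1:18, "]"),
          paste0("x[", rep(1:4, Tl), ",", rep(1:Tl, each = 4), "]"),
          paste0("F[", rep(1:4, Tl), ",", rep(1:Tl, each = 4), "]"))
  M <- matrix(0.5, nd, length(nm), dimnames = list(NULL, nm))
  M[, grepl("^sigma", nm)] <- sigma
  M[, grepl("^q\\[", nm)] <- q
  M[, grepl("^x\\[", nm)] <- x
  M[, grepl("^eta", nm)] <- 0.1
  draws <- coda::mcmc.list(coda::mcmc(M))
  fit <- list(draws = draws, structure = st, panel = study$panel,
              prior = prior_config(), protocol = reduced_protocol(),
              likelihood = TRUE, years = study$panel$landings_years)
  class(fit) <- "gssm"
  fit
}
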