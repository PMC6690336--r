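#' MCMC protocol
#'
#' Chain settings for posterior sampling. The reference protocol is five
#' independent chains of 500,000 adaptive iterations followed by 500,000
#' sampling iterations thinned by 10; \code{\link{reduced_protocol}} gives a
#' short protocol suitable for simulation studies and tests.
#'
#' @param n_chains number of independent chains (>= 2 for convergence
#'   diagnostics).
#' @param n_adapt adaptation (warmup) iterations per chain.
#' @param n_iter post-adaptation iterations per chain.
#' @param thin thinning interval applied to the sampling phase.
#' @param seed integer master seed; chain c uses \code{seed + c}.
#' @return list of class \code{"gssm_protocol"}.
#' @export
mcmc_protocol <- function(n_chains = 5, n_adapt = 500000, n_iter = 500000,
                          thin = 10, seed = 1L) {
  stopifnot(n_chains >= 1, n_adapt >= 0, n_iter >= 1, thin >= 1)
  out <- list(n_chains = as.integer(n_chains), n_adapt = as.integer(n_adapt),
              n_iter = as.integer(n_iter), thin = as.integer(thin),
              seed = as.integer(seed))
  class(out) <- "gssm_protocol"
  out
}

#' @rdname mcmc_protocol
#' @export
reduced_protocol <- function(n_chains = 4, n_adapt = 2000, n_iter = 2000,
                             thin = 1, seed = 1L) {
  mcmc_protocol(n_chains, n_adapt, n_iter, thin, seed)
}

# BUGS model code for the state space model, generated from the structure.
# likelihood = FALSE samples only the static-parameter priors (fished
# fractions, sds, initial states, density dependence, growth, catchability),
# without the latent transition chain: the sampler correctness check
# compares these marginals against their analytic forms.
build_model_code <- function(likelihood = TRUE) {
  if (!likelihood) {
    return("model {
  for (i in 1:Ng) {
    eta[i] ~ dlnorm(proc_m, proc_tau)
    x[i, 1] ~ dlnorm(log_href[i], init_tau)
    r[i] ~ dnorm(amag[i, i] * log_hbar[i], 1 / (amag[i, i] * amag[i, i]))
    for (j in 1:Ng) {
      amag[i, j] ~ dunif(0, 1)
    }
    for (t in 1:Tl) {
      F[i, t] ~ dunif(0, 1)
    }
  }
  for (k in 1:Nk) {
    sigma[k] ~ dlnorm(obs_m, obs_tau)
  }
  for (c in 1:Nc) {
    q[c] ~ dlnorm(q_m[c], q_tau)
  }
}
")
  }
  obs <- "
  for (i in 1:Ng) {
    for (t in 1:Tl) {
      h[i, t] ~ dlnorm(log(F[i, t]) + logx[i, t], land_tau)
    }
  }
  for (o in 1:Nobs) {
    C[o] ~ dlnorm(log(q[combo[o]]) + logE[o] + logx[grp[o], yr[o]],
                  obstau[gear[o]])
  }
"
  paste0("model {
  for (i in 1:Ng) {
    eta[i] ~ dlnorm(proc_m, proc_tau)
    proctau[i] <- 1 / (eta[i] * eta[i])
    x[i, 1] ~ dlnorm(log_href[i], init_tau)
    r[i] ~ dnorm(amag[i, i] * log_hbar[i], 1 / (amag[i, i] * amag[i, i]))
    for (j in 1:Ng) {
      amag[i, j] ~ dunif(0, 1)
      A[i, j] <- sgn[i, j] * amag[i, j]
    }
    for (t in 1:Tl) {
      F[i, t] ~ dunif(0, 1)
      f[i, t] <- -log(1 - F[i, t])
      logx[i, t] <- log(x[i, t])
    }
    for (t in 2:Tl) {
      mu[i, t] <- logx[i, t - 1] + r[i] - f[i, t - 1] +
        inprod(A[i, 1:Ng], logx[1:Ng, t - 1])
      x[i, t] ~ dlnorm(mu[i, t], proctau[i])
    }
  }
  for (k in 1:Nk) {
    sigma[k] ~ dlnorm(obs_m, obs_tau)
    obstau[k] <- 1 / (sigma[k] * sigma[k])
  }
  for (c in 1:Nc) {
    q[c] ~ dlnorm(q_m[c], q_tau)
  }
", obs, "}
")
}

# keep only the year-1 latent init when the transition chain is absent
trim_inits_prior_only <- function(ini) {
  ini$x <- ini$x[, 1L, drop = FALSE]
  ini
}

# Data list for the JAGS model from a panel + prior config.
build_model_data <- function(panel, prior, structure, likelihood = TRUE) {
  h <- landings_matrix(panel)
  Tl <- ncol(h)
  gi <- match(structure$combos$group, structure$groups)
  dat <- list(
    Ng = structure$n_groups, Nk = structure$n_gears,
    Nc = nrow(structure$combos), Tl = Tl,
    sgn = unname(structure$sign_pattern),
    log_href = unname(log(prior$h_ref)),
    log_hbar = unname(log(prior$hbar_ref)),
    proc_m = prior$proc_sd_logmean, proc_tau = 1 / prior$proc_sd_logvar,
    obs_m = prior$obs_sd_logmean, obs_tau = 1 / prior$obs_sd_logvar,
    init_tau = 1 / prior$init_state_logvar,
    q_m = unname(-log(prior$hbar_ref[gi])),
    q_tau = 1 / prior$catchability_logvar)
  if (!likelihood) dat$sgn <- NULL
  if (likelihood) {
    cp <- panel$cpue
    dat$h <- unname(h)
    dat$land_tau <- 1 / prior$landings_logvar
    dat$Nobs <- nrow(cp)
    dat$C <- cp$catch
    dat$logE <- log(cp$effort)
    dat$combo <- match(paste(cp$gear, cp$group, sep = ":"),
                       structure$combos$combo)
    dat$grp <- match(cp$group, structure$groups)
    dat$yr <- match(cp$year, as.integer(colnames(h)))
    dat$gear <- match(cp$gear, structure$gears)
  }
  dat
}

#' Chain starting point
#'
#' Draws a feasible starting point for one chain: latent biomasses from the
#' heavy-tailed Pareto initializer (so every \code{x[i, t] >= h[i, t]} and
#' the harvest sequence is feasible), fished fractions at the implied
#' \code{h/x} (always in (0, 1)), log catchabilities at the mean log CPUE
#' index minus the log of the Pareto-median reference biomass, and all other
#' unknowns from their priors.
#'
#' @param panel an \code{\link{observation_panel}}.
#' @param config a \code{\link{prior_config}}.
#' @param structure an \code{\link{ecosystem_structure}}.
#' @param seed integer seed (deterministic given seed).
#' @return named list of initial values for the sampler.
#' @export
initialize_chain <- function(panel, config, structure, seed = 1L) {
  set.seed(seed)
  h <- landings_matrix(panel)
  n <- structure$n_groups
  Tl <- ncol(h)
  x <- matrix(pareto_init_sampler(n * Tl, as.numeric(h)), n, Tl)
  F <- h / x
  amag <- matrix(stats::runif(n * n), n, n)
  a_ii <- diag(amag)
  r <- stats::rnorm(n, a_ii * log(config$hbar_ref), a_ii)
  eta <- stats::rlnorm(n, config$proc_sd_logmean, sqrt(config$proc_sd_logvar))
  sigma <- stats::rlnorm(structure$n_gears, config$obs_sd_logmean,
                         sqrt(config$obs_sd_logvar))
  # reference biomass: Pareto median sqrt(2) * typical landings per group
  xtilde <- apply(h, 1, stats::median) * sqrt(2)
  cp <- panel$cpue
  logcpue <- tapply(log(cp$catch / cp$effort),
                    paste(cp$gear, cp$group, sep = ":"), mean)
  gi <- match(structure$combos$group, structure$groups)
  q <- exp(logcpue[structure$combos$combo] - log(xtilde[gi]))
  miss <- !is.finite(q)
  if (any(miss))
    q[miss] <- stats::rlnorm(sum(miss), -log(config$hbar_ref[gi][miss]),
                             sqrt(config$catchability_logvar))
  list(x = x, F = F, amag = amag, r = r, eta = eta, sigma = sigma,
       q = unname(q))
}

#' Fit the Bayesian multivariate Gompertz state space model
#'
#' Samples the joint posterior of the static parameters (growth rates r,
#' signed density-dependence matrix A, process-noise sds eta,
#' observation-error sds sigma, catchabilities q), the annual fished
#' fractions F and the latent biomass trajectory x, given a CPUE/landings
#' observation panel, using MCMC (JAGS via rjags). The model code is
#' generated from the ecosystem structure; the landings constraint is the
#' soft lognormal likelihood with log-variance
#' \code{prior$landings_logvar}.
#'
#' @param panel an \code{\link{observation_panel}}.
#' @param structure the ecosystem structure (defaults to the panel's).
#' @param prior a \code{\link{prior_config}}.
#' @param protocol an \code{\link{mcmc_protocol}}; sampling is reproducible
#'   given \code{protocol$seed}.
#' @param likelihood \code{FALSE} switches the observation likelihood off
#'   and samples the prior (sampler correctness check).
#' @param monitor character vector of nodes to record.
#' @param quiet suppress JAGS progress output.
#' @return object of class \code{"gssm"}: list with \code{draws} (a
#'   \code{coda::mcmc.list} over all monitored scalars), \code{structure},
#'   \code{panel}, \code{prior}, \code{protocol}, \code{likelihood} and
#'   \code{years} (landings years labelling the latent-state columns).
#' @examples
#' \donttest{
#' study <- generate_study(seed = 1)
#' fit <- gompertz_ssm(study$panel, protocol = reduced_protocol(
#'   n_chains = 2, n_adapt = 500, n_iter = 500))
#' summary(fit)
#' }
#' @export
gompertz_ssm <- function(panel, structure = panel$structure,
                         prior = prior_config(),
                         protocol = mcmc_protocol(),
                         likelihood = TRUE,
                         monitor = c("r", "amag", "eta", "sigma", "q",
                                     "x", "F"),
                         quiet = TRUE) {
  stopifnot(inherits(panel, "obs_panel"))
  if (protocol$n_chains < 2)
    warning("fewer than 2 chains: convergence diagnostics unavailable")
  code <- build_model_code(likelihood = likelihood)
  dat <- build_model_data(panel, prior, structure, likelihood = likelihood)
  inits <- lapply(seq_len(protocol$n_chains), function(c) {
    ini <- initialize_chain(panel, prior, structure,
                            seed = protocol$seed + c)
    if (!likelihood) ini <- trim_inits_prior_only(ini)
    c(ini, list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = protocol$seed + c))
  })
  t0 <- proc.time()[["elapsed"]]
  jm <- rjags::jags.model(textConnection(code), data = dat, inits = inits,
                          n.chains = protocol$n_chains,
                          n.adapt = protocol$n_adapt, quiet = quiet)
  draws <- rjags::coda.samples(jm, variable.names = monitor,
                               n.iter = protocol$n_iter,
                               thin = protocol$thin)
  elapsed <- proc.time()[["elapsed"]] - t0
  out <- list(draws = draws, structure = structure, panel = panel,
              prior = prior, protocol = protocol, likelihood = likelihood,
              years = panel$landings_years, elapsed = elapsed,
              call = match.call())
  class(out) <- "gssm"
  out
}

#' Extract posterior draws as parameter arrays
#'
#' Parses the monitored scalars of a fit into arrays indexed by draw
#' (chains stacked): \code{r}, \code{eta}, \code{sigma}, \code{q} as
#' draws-by-component matrices; \code{A} as a draws-by-(n^2) matrix of the
#' signed density-dependence entries in column-major order; \code{amag}
#' likewise for the magnitudes; \code{x_arr} and \code{F_arr} as
#' draws-by-group-by-year arrays.
#'
#' @param fit a \code{\link{gompertz_ssm}} fit.
#' @return list of arrays plus \code{land_years}.
#' @export
extract_draws <- function(fit) {
  M <- as.matrix(fit$draws)
  st <- fit$structure
  n <- st$n_groups
  Tl <- length(fit$years)
  cols <- colnames(M)
  pick <- function(stub, k) {
    nm <- paste0(stub, "[", seq_len(k), "]")
    M[, nm, drop = FALSE]
  }
  amag <- M[, paste0("amag[", rep(1:n, n), ",", rep(1:n, each = n), "]"),
            drop = FALSE]
  sgn <- as.numeric(st$sign_pattern)  # column-major
  A <- sweep(amag, 2, sgn, `*`)
  arr <- function(stub) {
    Tn <- sum(startsWith(cols, paste0(stub, "["))) / n
    nm <- paste0(stub, "[", rep(1:n, Tn), ",", rep(seq_len(Tn), each = n),
                 "]")
    array(M[, nm], c(nrow(M), n, Tn))
  }
  list(r = pick("r", n), amag = amag, A = A, eta = pick("eta", n),
       sigma = pick("sigma", st$n_gears),
       q = pick("q", nrow(st$combos)),
       x_arr = if (any(startsWith(cols, "x["))) arr("x") else NULL,
       F_arr = if (any(startsWith(cols, "F["))) arr("F") else NULL,
       land_years = fit$years)
}

#' Joint log posterior density
#'
#' Evaluates the unnormalized log posterior of a full parameter set and
#' latent trajectory: log prior, plus the landings likelihood of the first
#' modelled year, plus for each subsequent year the lognormal transition
#' density (with the previous year's mortality), the landings likelihood and
#' the CPUE likelihood. Returns \code{-Inf} outside the support.
#'
#' @param params a \code{\link{model_params}} with all components,
#'   \code{F} being a group-by-landings-years matrix with year column
#'   names.
#' @param x group-by-year latent biomass matrix over the landings years
#'   (columns named by year); \code{x[, 1]} must equal \code{params$x0}.
#' @param panel an \code{\link{observation_panel}}.
#' @param config a \code{\link{prior_config}}.
#' @param structure an \code{\link{ecosystem_structure}}.
#' @return scalar log density (possibly \code{-Inf}).
#' @export
log_posterior <- function(params, x, panel, config, structure) {
  yrs <- panel$landings_years
  if (!identical(as.integer(colnames(x)), as.integer(yrs)))
    stop("x columns must be named by the landings years")
  if (!identical(as.integer(colnames(params$F)), as.integer(yrs)))
    stop("params$F columns must be named by the landings years")
  if (any(x <= 0)) return(-Inf)
  lp <- log_prior_density(params, config, structure)
  if (!is.finite(lp)) return(lp)
  f <- -log1p(-params$F)
  for (t in seq_along(yrs)[-1L]) {
    lp <- lp + transition_logdensity(x[, t], x[, t - 1L], params,
                                     f[, t - 1L])
  }
  lp <- lp + landings_loglik(panel, x, params$F, config$landings_logvar)
  lp <- lp + cpue_loglik(panel, x, params$q, params$sigma, structure)
  lp
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes the classic PSRF per scalar parameter from two or more chains of
#' equal length: with within-chain variance W and between-chain variance B,
#' the pooled variance estimate is \eqn{\hat V = (n-1)/n W + B/n} and
#' PSRF = sqrt(V/W). The upper 97.5 percent confidence bound follows the
#' Brooks-Gelman corrected sampling-variance construction (as implemented in
#' the coda package, against which this function is cross-checked).
#'
#' @param draws a \code{coda::mcmc.list}, a \code{\link{gompertz_ssm}} fit,
#'   or a list of equal-size draws-by-parameter matrices (one per chain).
#' @return data frame with columns \code{parameter}, \code{psrf} and
#'   \code{upper}.
#' @export
gelman_rubin <- function(draws) {
  if (inherits(draws, "gssm")) draws <- draws$draws
  if (inherits(draws, "mcmc.list"))
    chains <- lapply(draws, function(ch) as.matrix(ch))
  else chains <- lapply(draws, as.matrix)
  m <- length(chains)
  if (m < 2) stop("at least 2 chains are required")
  ns <- vapply(chains, nrow, 0L)
  if (length(unique(ns)) != 1) stop("chains must have equal length")
  nit <- ns[1L]
  p <- ncol(chains[[1L]])
  nms <- colnames(chains[[1L]])
  if (is.null(nms)) nms <- paste0("par", seq_len(p))
  psrf <- upper <- numeric(p)
  for (j in seq_len(p)) {
    X <- vapply(chains, function(ch) ch[, j], numeric(nit))  # nit x m
    mus <- colMeans(X)
    W <- mean(apply(X, 2, stats::var))
    B <- nit * stats::var(mus)
    Vhat <- (nit - 1) / nit * W + B / nit
    if (W <= 0) { psrf[j] <- 1; upper[j] <- 1; next }
    R2 <- Vhat / W
    psrf[j] <- sqrt(R2)
    # Brooks & Gelman (1998) upper bound via variance of the numerator
    s2 <- apply(X, 2, stats::var)
    var_W <- stats::var(s2) / m
    var_B <- 2 * B^2 / (m - 1)
    cov_WB <- (nit / m) * (stats::cov(s2, mus^2) -
                             2 * mean(mus) * stats::cov(s2, mus))
    var_V <- ((nit - 1) / nit)^2 * var_W + ((m + 1) / (m * nit))^2 * var_B +
      2 * ((nit - 1) * (m + 1) / (m * nit^2)) * cov_WB
    df <- max(2 * Vhat^2 / var_V, 2.01)
    fixup <- (df + 3) / (df + 1)
    Bdf <- m - 1
    Wdf <- 2 * W^2 / (stats::var(s2) / m)
    upper[j] <- sqrt(fixup * ((nit - 1) / nit +
                                (m + 1) / (m * nit) *
                                  stats::qf(0.975, Bdf, Wdf) * B / W))
  }
  data.frame(parameter = nms, psrf = psrf, upper = upper,
             row.names = NULL)
}

#' Posterior summaries and event probabilities
#'
#' Summary queries over posterior draws: marginal quantiles of any
#' monitored component, exceedance probabilities of density-dependence
#' magnitudes \code{P(a[i, j] > threshold)}, pairwise comparisons
#' \code{P(a[i, j] > a[j, i])} (bottom-up versus top-down strength), and the
#' posterior probability that the system is stationary.
#'
#' @param fit a \code{\link{gompertz_ssm}} fit.
#' @param query one of \code{"quantiles"}, \code{"exceed"},
#'   \code{"pairwise"}, \code{"stationary"}.
#' @param pars for \code{"quantiles"}: regular expression selecting
#'   monitored scalars (default all static parameters).
#' @param threshold for \code{"exceed"}: magnitude threshold (default 0.2).
#' @param pairs for \code{"exceed"}/\code{"pairwise"}: 2-column matrix or
#'   list of group-label pairs (i, j); default all interacting off-diagonal
#'   pairs of the sign pattern.
#' @return a data frame (quantiles, exceedance or pairwise probabilities) or
#'   a single probability (stationary).
#' @export
posterior_summary <- function(fit, query = c("quantiles", "exceed",
                                             "pairwise", "stationary"),
                              pars = "^(r|amag|eta|sigma|q)\\[",
                              threshold = 0.2, pairs = NULL) {
  query <- match.arg(query)
  st <- fit$structure
  n <- st$n_groups
  if (query == "quantiles") {
    M <- as.matrix(fit$draws)
    M <- M[, grepl(pars, colnames(M)), drop = FALSE]
    if (!ncol(M)) stop("no monitored parameters match 'pars'")
    qs <- t(apply(M, 2, stats::quantile,
                  probs = c(0.5, 0.25, 0.75, 0.05, 0.95)))
    return(data.frame(parameter = rownames(qs), median = qs[, 1],
                      q25 = qs[, 2], q75 = qs[, 3], q05 = qs[, 4],
                      q95 = qs[, 5], row.names = NULL))
  }
  draws <- extract_draws(fit)
  if (query == "stationary") {
    ok <- apply(draws$A, 1, function(a)
      is_stationary(matrix(a, n, n))$stationary)
    return(mean(ok))
  }
  if (is.null(pairs)) {
    sp <- st$sign_pattern
    idx <- which(sp != 0 & row(sp) != col(sp), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pairs <- cbind(st$groups[idx[, 1]], st$groups[idx[, 2]])
  }
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  amat <- function(i, j) draws$amag[, (match(j, st$groups) - 1L) * n +
                                      match(i, st$groups)]
  if (query == "exceed") {
    out <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      data.frame(i = c(i, j), j = c(j, i),
                 prob = c(mean(amat(i, j) > threshold),
                          mean(amat(j, i) > threshold)))
    }))
    out$threshold <- threshold
    return(out)
  }
  # pairwise: P(a_ij > a_ji)
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(k) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    data.frame(i = i, j = j, prob = mean(amat(i, j) > amat(j, i)))
  }))
}
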