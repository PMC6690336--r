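#' Stationarity check for the log-linear system
#'
#' The log-transformed dynamics \eqn{log x(t+1) = (I + A) log x(t) + r - f +
#' \epsilon(t)} are strictly stationary iff the spectral radius of
#' \eqn{I + A} is below one.
#'
#' @param A density-dependence matrix (or \code{\link{model_params}}).
#' @return list with \code{stationary} (logical) and \code{spectral_radius}.
#' @export
is_stationary <- function(A) {
  if (inherits(A, "gssm_params")) A <- A$A
  rho <- max(Mod(eigen(diag(nrow(A)) + A, only.values = TRUE)$values))
  list(stationary = rho < 1, spectral_radius = rho)
}

#' Stationary distribution under constant fishing mortality
#'
#' Under a constant mortality vector \code{f} and stationarity, log biomass
#' is multivariate normal with location \eqn{m = -A^{-1}(r - f)} and
#' covariance \eqn{P} solving the discrete Lyapunov equation
#' \eqn{P = (I + A) P (I + A)^T + S}; biomass itself is multivariate
#' lognormal LN(m, P). The Lyapunov equation is solved exactly by the
#' vectorized linear system \eqn{(I - B \otimes B) vec(P) = vec(S)} with
#' \eqn{B = I + A}.
#'
#' @param params list with \code{r}, \code{A} and \code{eta}.
#' @param f constant mortality vector (recycled); default 0.
#' @return object of class \code{"gssm_stationary"}: list with \code{m},
#'   \code{P}, \code{median} (exp(m)), \code{mean} (exp(m + diag(P)/2)), the
#'   spectral radius, and a \code{quantile} function of \code{p} returning
#'   per-group marginal quantiles exp(m + sqrt(diag(P)) * qnorm(p)).
#' @export
solve_stationary <- function(params, f = 0) {
  A <- params$A
  n <- nrow(A)
  f <- rep_len(f, n)
  chk <- is_stationary(A)
  if (!chk$stationary)
    stop("system is not stationary (spectral radius ",
         signif(chk$spectral_radius, 4), " >= 1)")
  m <- as.numeric(-solve(A, params$r - f))
  B <- diag(n) + A
  S <- diag(params$eta^2, n)
  vecP <- solve(diag(n * n) - kronecker(B, B), as.numeric(S))
  P <- matrix(vecP, n, n)
  P <- (P + t(P)) / 2
  nm <- names(params$r)
  names(m) <- nm
  dimnames(P) <- list(nm, nm)
  sdlog <- sqrt(diag(P))
  out <- list(m = m, P = P, median = exp(m),
              mean = exp(m + diag(P) / 2),
              spectral_radius = chk$spectral_radius,
              quantile = function(p) exp(m + outer(sdlog, stats::qnorm(p))))
  class(out) <- "gssm_stationary"
  out
}

#' @export
print.gssm_stationary <- function(x, ...) {
  cat("Stationary log-biomass distribution (spectral radius",
      signif(x$spectral_radius, 4), ")\n")
  print(data.frame(median_kt = signif(x$median, 4),
                   mean_kt = signif(x$mean, 4),
                   sd_log = signif(sqrt(diag(x$P)), 4)))
  invisible(x)
}

#' Constant-fishing scenario mortality vectors
#'
#' Builds, for every posterior draw, the constant mortality vector of a
#' named management scenario: \code{"f0"} (no fishing), \code{"fAvg"}
#' (per-draw arithmetic mean over the modelled years of the annual
#' instantaneous mortalities \eqn{f_i(t) = -log(1 - F_i(t))}),
#' \code{"fG"} (\code{fAvg} with the mortality of one group, default the
#' pelagic piscivores \code{"G"}, set to zero) and \code{"fMT"}
#' (\code{fAvg} with per-group multipliers representing the exclusion of a
#' gear, by default benthivore mortality reduced to 0.38 and demersal
#' piscivore mortality to 0.55 of their averages, i.e. one minus the gear's
#' landings share of each group).
#'
#' @param fit a \code{\link{gompertz_ssm}} fit.
#' @param scenario one of \code{"f0"}, \code{"fAvg"}, \code{"fG"},
#'   \code{"fMT"}.
#' @param zero_group group whose mortality is zeroed under \code{"fG"}.
#' @param multipliers named per-group multipliers for \code{"fMT"}; groups
#'   not named keep multiplier 1.
#' @return draws-by-group matrix of constant mortality vectors.
#' @export
scenario_f <- function(fit, scenario = c("fAvg", "f0", "fG", "fMT"),
                       zero_group = "G",
                       multipliers = c(B = 0.38, D = 0.55)) {
  scenario <- match.arg(scenario)
  draws <- extract_draws(fit)
  groups <- fit$structure$groups
  n <- length(groups)
  nd <- dim(draws$F_arr)[1L]
  favg <- apply(-log1p(-draws$F_arr), c(1, 2), mean)  # draws x group
  colnames(favg) <- groups
  out <- switch(scenario,
    f0 = matrix(0, nd, n, dimnames = list(NULL, groups)),
    fAvg = favg,
    fG = {
      m <- favg
      m[, zero_group] <- 0
      m
    },
    fMT = {
      m <- favg
      for (g in names(multipliers)) m[, g] <- m[, g] * multipliers[[g]]
      m
    })
  out
}

#' Posterior stationary projections under management scenarios
#'
#' For each posterior draw and each scenario, solves the stationary
#' distribution under the scenario's constant mortality and summarizes the
#' per-group stationary medians, means and expected landings
#' \eqn{h = F x = (1 - e^{-f}) x} over draws by the posterior median and
#' central 50/90 percent intervals. Non-stationary draws are excluded with
#' a logged count.
#'
#' @param fit a \code{\link{gompertz_ssm}} fit.
#' @param scenarios character vector of scenario names understood by
#'   \code{\link{scenario_f}}, or a named list of draws-by-group mortality
#'   matrices.
#' @param ... passed to \code{\link{scenario_f}}.
#' @return object of class \code{"gssm_scenarios"}: list with \code{summary}
#'   (long data frame: scenario, group, quantity in
#'   \{median_biomass, mean_biomass, landings_median_biomass,
#'   landings_mean_biomass\}, posterior median and interval columns),
#'   \code{n_nonstationary} per scenario and \code{n_draws}.
#' @export
project_scenarios <- function(fit, scenarios = c("f0", "fAvg", "fG", "fMT"),
                              ...) {
  if (is.character(scenarios)) {
    fmats <- lapply(scenarios, function(s) scenario_f(fit, s, ...))
    names(fmats) <- scenarios
  } else fmats <- scenarios
  draws <- extract_draws(fit)
  st <- fit$structure
  n <- st$n_groups
  nd <- nrow(draws$r)
  res <- list(); nonstat <- integer(length(fmats)); names(nonstat) <- names(fmats)
  for (s in names(fmats)) {
    fm <- fmats[[s]]
    med <- mea <- lmed <- lmea <- matrix(NA_real_, nd, n)
    for (d in seq_len(nd)) {
      p <- list(r = draws$r[d, ], A = matrix(draws$A[d, ], n, n),
                eta = draws$eta[d, ])
      if (!is_stationary(p$A)$stationary) next
      sd_ <- solve_stationary(p, fm[d, ])
      med[d, ] <- sd_$median
      mea[d, ] <- sd_$mean
      Fv <- -expm1(-fm[d, ])
      lmed[d, ] <- Fv * sd_$median
      lmea[d, ] <- Fv * sd_$mean
    }
    ok <- stats::complete.cases(med)
    nonstat[s] <- sum(!ok)
    qfun <- function(M) apply(M[ok, , drop = FALSE], 2, stats::quantile,
                              probs = c(0.5, 0.25, 0.75, 0.05, 0.95))
    for (quant in c("median_biomass", "mean_biomass",
                    "landings_median_biomass", "landings_mean_biomass")) {
      M <- switch(quant, median_biomass = med, mean_biomass = mea,
                  landings_median_biomass = lmed,
                  landings_mean_biomass = lmea)
      qs <- qfun(M)
      res[[paste(s, quant)]] <- data.frame(
        scenario = s, group = st$groups, quantity = quant,
        median = qs[1, ], q25 = qs[2, ], q75 = qs[3, ],
        q05 = qs[4, ], q95 = qs[5, ], row.names = NULL)
    }
  }
  out <- list(summary = do.call(rbind, res), n_nonstationary = nonstat,
              n_draws = nd)
  rownames(out$summary) <- NULL
  class(out) <- "gssm_scenarios"
  out
}

#' @export
print.gssm_scenarios <- function(x, ...) {
  cat("Stationary scenario projections over", x$n_draws, "draws\n")
  sub <- x$summary[x$summary$quantity == "median_biomass", ]
  print(data.frame(scenario = sub$scenario, group = sub$group,
                   median_kt = signif(sub$median, 4),
                   q05 = signif(sub$q05, 4), q95 = signif(sub$q95, 4)))
  invisible(x)
}
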