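#' Default configuration for synthetic studies
#'
#' Configuration mirroring the shape of the Bay of Biscay study inputs:
#' four functional groups observed by eight gears through 18 targeted
#' combinations, a 17-year landings span (first year latent-state only) and
#' a 16-year CPUE span, reference landings anchors
#' \code{h_ref = c(56, 23, 35, 3)} kt (year preceding the first modelled
#' year) and \code{hbar_ref = c(145, 30, 73, 27)} kt (historical mean), and
#' fixed, documented true parameters so that tests are stable. The true
#' parameter set uses moderate intra-group density dependence, weaker
#' trophic coupling consistent with the sign pattern, observation-error and
#' process-noise sds near the centre of their priors, and a target fished
#' fraction around 0.3 per group and year.
#'
#' @param first_year first landings year (latent-state initial year).
#' @param n_land_years number of landings years.
#' @param params_source \code{"fixed"} for the documented default truth, or
#'   \code{"prior"} to draw the truth from the prior (stationarity enforced
#'   by rejection when \code{require_stationary}).
#' @param require_stationary reject non-stationary truths (and error for a
#'   non-stationary fixed truth).
#' @param target_F group-by-year matrix (or scalar/vector) of target fished
#'   fractions used to generate the harvest schedule; \code{NULL} keeps the
#'   schedule of the parameter source (prior-drawn fractions under
#'   \code{params_source = "prior"}, as required for calibration studies).
#' @param effort_sd log-scale innovation sd of the lognormal random-walk
#'   effort series (synthetic-only construct).
#' @param prior the \code{\link{prior_config}} used for anchors and (when
#'   \code{params_source = "prior"}) truth draws.
#' @return list of class \code{"gssm_study_config"}.
#' @export
study_config <- function(first_year = 1999L, n_land_years = 17L,
                         params_source = c("fixed", "prior"),
                         require_stationary = TRUE,
                         target_F = 0.3, effort_sd = 0.2,
                         prior = prior_config()) {
  params_source <- match.arg(params_source)
  out <- list(first_year = as.integer(first_year),
              n_land_years = as.integer(n_land_years),
              params_source = params_source,
              require_stationary = require_stationary,
              target_F = target_F, effort_sd = effort_sd, prior = prior)
  class(out) <- "gssm_study_config"
  out
}

# Fixed, documented ground-truth parameters for the default 4-group system.
default_true_params <- function(structure, prior, n_years) {
  sp <- structure$sign_pattern
  amag <- matrix(0, 4, 4)
  diag(amag) <- c(0.6, 0.5, 0.45, 0.4)
  amag[sp != 0 & row(sp) != col(sp)] <- 0.15
  A <- sp * amag
  # r chosen so unfished equilibria sit near the historical-mean anchors
  r <- as.numeric(-A %*% log(prior$hbar_ref))
  eta <- c(0.15, 0.12, 0.12, 0.2)
  sigma <- rep(c(0.3, 0.25, 0.15, 0.3, 0.3, 0.35, 0.4, 0.25),
               length.out = structure$n_gears)
  gi <- match(structure$combos$group, structure$groups)
  q <- 1 / as.numeric(prior$hbar_ref[gi])
  F <- matrix(0.3, structure$n_groups, n_years)
  x0 <- as.numeric(prior$hbar_ref) * 0.8
  model_params(r = r, A = A, eta = eta, sigma = sigma, q = q, F = F,
               x0 = x0, structure = structure)
}

#' Generate a complete synthetic study with known ground truth
#'
#' Builds study inputs emulating the real data's shape and statistical
#' assumptions: a positive lognormal random-walk effort series per gear,
#' a latent biomass trajectory simulated from the process model under the
#' target fished fractions, landings drawn from the reporting-error model
#' and CPUE drawn from the observation model for the targeted combinations
#' only. The generating parameters are attached as ground truth.
#'
#' @param config a \code{\link{study_config}}.
#' @param seed integer seed; the study is reproducible given the seed.
#' @param structure an \code{\link{ecosystem_structure}}.
#' @return object of class \code{"gssm_study"}: list with \code{panel} (an
#'   \code{\link{observation_panel}}), \code{truth} (the generating
#'   \code{\link{model_params}}), \code{trajectory} (latent biomass matrix),
#'   \code{effort} and \code{config}.
#' @examples
#' study <- generate_study(seed = 1)
#' nrow(study$panel$cpue)  # 288 CPUE records: 18 combos x 16 years
#' @export
generate_study <- function(config = study_config(), seed = 1L,
                           structure = ecosystem_structure()) {
  set.seed(seed)
  prior <- config$prior
  n <- structure$n_groups
  Tl <- config$n_land_years
  land_years <- seq.int(config$first_year, length.out = Tl)
  cpue_years <- land_years[-1L]
  for (attempt in seq_len(1000L)) {
    if (config$params_source == "fixed") {
      truth <- default_true_params(structure, prior, Tl)
    } else {
      truth <- sample_prior(prior, structure, n_years = Tl)
    }
    if (!is.null(config$target_F))
      truth$F <- matrix(config$target_F, n, Tl)
    stat_ok <- is_stationary(truth$A)$stationary
    if (stat_ok || !config$require_stationary) break
    if (config$params_source == "fixed")
      stop("fixed true parameters are non-stationary")
  }
  if (config$require_stationary && !stat_ok)
    stop("no stationary prior draw found")
  rownames(truth$F) <- structure$groups
  colnames(truth$F) <- land_years
  traj <- simulate_trajectory(truth, n_years = Tl,
                              F = truth$F[, -Tl, drop = FALSE],
                              x0 = truth$x0, years = config$first_year)
  # guard against numerically wild prior draws
  if (any(!is.finite(traj$x)) || any(traj$x <= 0) ||
      any(traj$x > 1e8) || any(traj$x < 1e-8)) {
    if (config$params_source == "fixed")
      stop("fixed true parameters produced a degenerate trajectory")
    return(generate_study(config, seed + 100003L, structure))
  }
  effort <- matrix(NA_real_, structure$n_gears, Tl - 1L,
                   dimnames = list(structure$gears, cpue_years))
  e0 <- stats::rlnorm(structure$n_gears, log(100), 0.3)
  effort[, 1L] <- e0
  for (t in seq_len(Tl - 2L))
    effort[, t + 1L] <- effort[, t] *
      stats::rlnorm(structure$n_gears, 0, config$effort_sd)
  panel <- simulate_observations(traj$x, truth$F, truth$q, truth$sigma,
                                 effort, structure,
                                 landings_logvar = prior$landings_logvar)
  out <- list(panel = panel, truth = truth, trajectory = traj,
              effort = effort, config = config, seed = seed)
  class(out) <- "gssm_study"
  out
}

#' @export
print.gssm_study <- function(x, ...) {
  cat("Synthetic study (seed", x$seed, "):",
      nrow(x$panel$cpue), "CPUE records,",
      nrow(x$panel$landings), "landings records\n")
  invisible(x)
}

#' Write a synthetic study's ground truth to a JSON sidecar
#'
#' @param study a \code{\link{generate_study}} result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_ground_truth <- function(study, path) {
  tr <- study$truth
  obj <- list(r = tr$r, A = tr$A, eta = tr$eta, sigma = tr$sigma,
              q = tr$q, F = tr$F, x0 = tr$x0, seed = study$seed)
  jsonlite::write_json(obj, path, digits = NA, pretty = TRUE,
                       auto_unbox = TRUE)
  invisible(path)
}
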