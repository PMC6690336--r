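#' Refit with one year's CPUE held out
#'
#' Removes the CPUE block of a single year from the likelihood (landings of
#' every year are always retained, so the held-out year's latent states
#' remain informed by the harvest) and refits with identical machinery.
#'
#' @param panel an \code{\link{observation_panel}}.
#' @param year the held-out CPUE year.
#' @param prior a \code{\link{prior_config}}.
#' @param protocol an \code{\link{mcmc_protocol}} (typically reduced).
#' @param ... passed to \code{\link{gompertz_ssm}}.
#' @return a \code{\link{gompertz_ssm}} fit conditioned on all CPUE except
#'   the held-out year, carrying the held-out records in
#'   \code{$holdout}.
#' @export
holdout_fit <- function(panel, year, prior = prior_config(),
                        protocol = reduced_protocol(), ...) {
  keep <- panel$cpue$year != year
  held <- panel$cpue[!keep, , drop = FALSE]
  sub <- observation_panel(panel$cpue[keep, , drop = FALSE],
                           panel$landings, panel$structure)
  fit <- gompertz_ssm(sub, prior = prior, protocol = protocol, ...)
  fit$holdout <- held
  fit$holdout_year <- year
  fit
}

#' Posterior predictive CPUE for held-out records
#'
#' For each retained posterior draw, simulates the catch of every held-out
#' record from the observation model (effort treated as known), and reports
#' the predictive median and central 50/90 percent intervals of CPUE
#' (catch/effort) next to the observed value.
#'
#' @param fit a \code{\link{holdout_fit}} result (or any fit plus explicit
#'   \code{records}).
#' @param records data frame of records (year, gear, group, catch, effort);
#'   defaults to \code{fit$holdout}.
#' @param seed optional integer seed for the predictive simulation.
#' @return data frame with one row per record: observed CPUE, predictive
#'   median and interval bounds, and indicator columns \code{below_median},
#'   \code{in50}, \code{in90}.
#' @export
predictive_cpue <- function(fit, records = fit$holdout, seed = NULL) {
  if (is.null(records) || !nrow(records)) stop("no held-out records")
  if (!is.null(seed)) set.seed(seed)
  st <- fit$structure
  draws <- extract_draws(fit)
  nd <- nrow(draws$r)
  yi <- match(records$year, fit$years)
  gi <- match(records$group, st$groups)
  ki <- match(records$gear, st$gears)
  ci <- match(paste(records$gear, records$group, sep = ":"),
              st$combos$combo)
  out <- do.call(rbind, lapply(seq_len(nrow(records)), function(rr) {
    xb <- draws$x_arr[, gi[rr], yi[rr]]
    mu <- log(draws$q[, ci[rr]]) + log(xb)  # location of CPUE = C/E
    sim <- stats::rlnorm(nd, mu, draws$sigma[, ki[rr]])
    qs <- stats::quantile(sim, c(0.5, 0.25, 0.75, 0.05, 0.95))
    obs <- records$catch[rr] / records$effort[rr]
    data.frame(year = records$year[rr], gear = records$gear[rr],
               group = records$group[rr], observed = obs,
               pred_median = qs[[1]], q25 = qs[[2]], q75 = qs[[3]],
               q05 = qs[[4]], q95 = qs[[5]],
               below_median = obs < qs[[1]],
               in50 = obs >= qs[[2]] & obs <= qs[[3]],
               in90 = obs >= qs[[4]] & obs <= qs[[5]])
  }))
  rownames(out) <- NULL
  out
}

#' Coverage audit over cross-validation reports
#'
#' Aggregates held-out predictive reports over all years into the three
#' adequacy proportions: observations below the predictive median, within
#' the central 50 percent interval and within the central 90 percent
#' interval. For an adequate model these should be close to 0.5, 0.5 and
#' 0.9.
#'
#' @param reports a data frame (or list of data frames, one per held-out
#'   year) as returned by \code{\link{predictive_cpue}}.
#' @return list with \code{n_records}, \code{prop_below_median},
#'   \code{prop_in50}, \code{prop_in90}.
#' @export
coverage_audit <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports))
    reports <- do.call(rbind, reports)
  list(n_records = nrow(reports),
       prop_below_median = mean(reports$below_median),
       prop_in50 = mean(reports$in50),
       prop_in90 = mean(reports$in90))
}

#' Year-blocked predictive cross-validation
#'
#' Runs the full blocked cross-validation: for every CPUE year (or the
#' subset given), refits the model with that year's CPUE block held out,
#' simulates the posterior predictive CPUE for the held-out records and
#' audits interval coverage over all records. Refits run independently with
#' per-year seeds derived from the protocol's master seed.
#'
#' @param panel an \code{\link{observation_panel}}.
#' @param years CPUE years to hold out (default all).
#' @param prior a \code{\link{prior_config}}.
#' @param protocol an \code{\link{mcmc_protocol}} for the refits.
#' @param ... passed to \code{\link{gompertz_ssm}}.
#' @return object of class \code{"gssm_cv"}: list with \code{records} (one
#'   row per held-out record) and the \code{\link{coverage_audit}} fields.
#' @export
cross_validate <- function(panel, years = panel$cpue_years,
                           prior = prior_config(),
                           protocol = reduced_protocol(), ...) {
  reports <- lapply(seq_along(years), function(k) {
    pr <- protocol
    pr$seed <- protocol$seed + 1000L * k
    fit <- holdout_fit(panel, years[k], prior = prior, protocol = pr, ...)
    predictive_cpue(fit, seed = pr$seed)
  })
  records <- do.call(rbind, reports)
  out <- c(list(records = records), coverage_audit(records))
  class(out) <- "gssm_cv"
  out
}

#' @export
print.gssm_cv <- function(x, ...) {
  cat("Year-blocked cross-validation:", x$n_records, "held-out records\n")
  cat(sprintf("  below predictive median: %.3f (nominal 0.50)\n",
              x$prop_below_median))
  cat(sprintf("  within central 50%% interval: %.3f (nominal 0.50)\n",
              x$prop_in50))
  cat(sprintf("  within central 90%% interval: %.3f (nominal 0.90)\n",
              x$prop_in90))
  invisible(x)
}
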