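#' Observation panel: CPUE records and landings series
#'
#' Validates and bundles the two observation tables of the model: per-year
#' catch and effort for each targeted gear/group combination (the CPUE
#' panel) and the per-year international landings per group. Catch of
#' non-targeted combinations is assumed ignorable and a record for one is a
#' validation error.
#'
#' @param cpue data frame with columns \code{year}, \code{gear},
#'   \code{group}, \code{catch} (tonnes or survey t/km2, positive) and
#'   \code{effort} (positive).
#' @param landings data frame with columns \code{year}, \code{group},
#'   \code{landings} (kt, positive).
#' @param structure an \code{\link{ecosystem_structure}}.
#' @return list of class \code{"obs_panel"} with sorted, validated
#'   \code{cpue} and \code{landings} tables, the year spans and the
#'   structure.
#' @export
observation_panel <- function(cpue, landings, structure) {
  need_c <- c("year", "gear", "group", "catch", "effort")
  need_l <- c("year", "group", "landings")
  if (!all(need_c %in% names(cpue)))
    stop("cpue must have columns ", paste(need_c, collapse = ", "))
  if (!all(need_l %in% names(landings)))
    stop("landings must have columns ", paste(need_l, collapse = ", "))
  if (!all(cpue$gear %in% structure$gears))
    stop("unknown gear label(s): ",
         paste(setdiff(cpue$gear, structure$gears), collapse = ", "))
  if (!all(c(cpue$group, landings$group) %in% structure$groups))
    stop("unknown group label(s)")
  bad <- !structure$targeting[cbind(match(cpue$gear, structure$gears),
                                    match(cpue$group, structure$groups))]
  if (any(bad))
    stop("CPUE records for non-targeted combinations: ",
         paste(unique(paste(cpue$gear[bad], cpue$group[bad], sep = ":")),
               collapse = ", "))
  if (any(cpue$catch <= 0) || any(cpue$effort <= 0))
    stop("catch and effort must be positive")
  if (any(landings$landings <= 0)) stop("landings must be positive")
  key <- paste(cpue$year, cpue$gear, cpue$group)
  if (anyDuplicated(key))
    stop("duplicate CPUE record(s): ", key[duplicated(key)][1L])
  lkey <- paste(landings$year, landings$group)
  if (anyDuplicated(lkey))
    stop("duplicate landings record(s): ", lkey[duplicated(lkey)][1L])
  if (!all(cpue$year %in% landings$year))
    stop("every CPUE year must be covered by the landings series")
  cpue <- cpue[order(cpue$year, match(cpue$gear, structure$gears),
                     match(cpue$group, structure$groups)), , drop = FALSE]
  landings <- landings[order(landings$year,
                             match(landings$group, structure$groups)), ,
                       drop = FALSE]
  rownames(cpue) <- rownames(landings) <- NULL
  out <- list(cpue = cpue, landings = landings,
              cpue_years = sort(unique(cpue$year)),
              landings_years = sort(unique(landings$year)),
              structure = structure)
  class(out) <- "obs_panel"
  out
}

#' @export
print.obs_panel <- function(x, ...) {
  cat("Observation panel:", nrow(x$cpue), "CPUE records over",
      length(x$cpue_years), "years;", nrow(x$landings),
      "landings records over", length(x$landings_years), "years\n")
  invisible(x)
}

#' Landings matrix helper
#'
#' Group-by-year matrix of landings (kt) extracted from a panel.
#' @param panel an \code{\link{observation_panel}}.
#' @return group-by-year matrix with dimnames.
#' @export
landings_matrix <- function(panel) {
  groups <- panel$structure$groups
  yrs <- panel$landings_years
  h <- matrix(NA_real_, length(groups), length(yrs),
              dimnames = list(groups, yrs))
  h[cbind(match(panel$landings$group, groups),
          match(panel$landings$year, yrs))] <- panel$landings$landings
  if (anyNA(h)) stop("landings series is incomplete")
  h
}

#' CPUE log likelihood
#'
#' Sum over targeted records of the lognormal log density
#' \eqn{LN(C_{ik}(t) | log(q_{ik} E_k(t) x_i(t)), \sigma_k^2)}.
#'
#' @param panel an \code{\link{observation_panel}}.
#' @param x group-by-year latent biomass matrix whose columns are named by
#'   year and cover all CPUE years.
#' @param q catchability vector named by combination \code{"gear:group"}.
#' @param sigma observation-error sd vector named by gear.
#' @param structure the \code{\link{ecosystem_structure}} (defaults to the
#'   panel's).
#' @return scalar log likelihood.
#' @export
cpue_loglik <- function(panel, x, q, sigma, structure = panel$structure) {
  cp <- panel$cpue
  yi <- match(as.character(cp$year), colnames(x))
  if (anyNA(yi)) stop("latent states must cover all CPUE years")
  gi <- match(cp$group, structure$groups)
  xb <- x[cbind(gi, yi)]
  qv <- q[paste(cp$gear, cp$group, sep = ":")]
  sv <- sigma[cp$gear]
  if (anyNA(qv) || anyNA(sv)) stop("q or sigma missing for some record")
  sum(stats::dlnorm(cp$catch, meanlog = log(qv * cp$effort * xb),
                    sdlog = sv, log = TRUE))
}

#' Landings log likelihood
#'
#' Sum of lognormal log densities
#' \eqn{h_i(t) \sim LN(log F_i(t) + log x_i(t), landings\_logvar)}; the
#' default variance 0.001 gives roughly probability 0.9 of less than 5
#' percent reporting error.
#'
#' @param panel an \code{\link{observation_panel}}.
#' @param x group-by-year latent biomass matrix, columns named by year,
#'   covering all landings years.
#' @param F group-by-year fished-fraction matrix, columns named by year.
#' @param landings_logvar log-scale variance of the reporting error.
#' @return scalar log likelihood.
#' @export
landings_loglik <- function(panel, x, F, landings_logvar = 0.001) {
  ld <- panel$landings
  groups <- panel$structure$groups
  yi <- match(as.character(ld$year), colnames(x))
  yF <- match(as.character(ld$year), colnames(F))
  if (anyNA(yi) || anyNA(yF))
    stop("x and F must cover all landings years (named columns)")
  gi <- match(ld$group, groups)
  mu <- log(F[cbind(gi, yF)]) + log(x[cbind(gi, yi)])
  sum(stats::dlnorm(ld$landings, meanlog = mu, sdlog = sqrt(landings_logvar),
                    log = TRUE))
}

#' Simulate an observation panel from latent states
#'
#' Generates CPUE for targeted combinations and landings for all groups and
#' years from the observation models, given a latent trajectory, fished
#' fractions, catchabilities, observation-error sds and an effort series.
#'
#' @param x group-by-year latent biomass matrix, columns named by year.
#' @param F group-by-year fished-fraction matrix, columns named by year
#'   (landings years).
#' @param q catchability vector named \code{"gear:group"}.
#' @param sigma observation-error sd vector named by gear.
#' @param effort gear-by-year positive effort matrix, columns named by year
#'   (CPUE years).
#' @param structure an \code{\link{ecosystem_structure}}.
#' @param landings_logvar landings reporting-error log variance.
#' @param seed optional integer seed.
#' @return an \code{\link{observation_panel}}.
#' @export
simulate_observations <- function(x, F, q, sigma, effort, structure,
                                  landings_logvar = 0.001, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cpue_years <- as.integer(colnames(effort))
  cb <- structure$combos
  rec <- do.call(rbind, lapply(cpue_years, function(yr) {
    data.frame(year = yr, gear = cb$gear, group = cb$group,
               stringsAsFactors = FALSE)
  }))
  gi <- match(rec$group, structure$groups)
  yi <- match(as.character(rec$year), colnames(x))
  ei <- cbind(match(rec$gear, structure$gears),
              match(as.character(rec$year), colnames(effort)))
  rec$effort <- effort[ei]
  qv <- q[paste(rec$gear, rec$group, sep = ":")]
  rec$catch <- stats::rlnorm(nrow(rec),
                             meanlog = log(qv * rec$effort * x[cbind(gi, yi)]),
                             sdlog = sigma[rec$gear])
  land_years <- as.integer(colnames(F))
  ld <- expand.grid(group = structure$groups, year = land_years,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lgi <- match(ld$group, structure$groups)
  lyi <- match(as.character(ld$year), colnames(x))
  ld$landings <- stats::rlnorm(nrow(ld),
                               meanlog = log(F[cbind(lgi,
                                                     match(as.character(ld$year),
                                                           colnames(F)))]) +
                                 log(x[cbind(lgi, lyi)]),
                               sdlog = sqrt(landings_logvar))
  observation_panel(rec, ld[, c("year", "group", "landings")], structure)
}
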