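#' Read an observation panel from CSV files
#'
#' Reads the long-format CPUE and landings tables and applies the standard
#' unit conversions before validation: landings in tonnes are converted to
#' kilotonnes (column \code{landings_tonnes}), survey CPUE in kg/km2 to
#' t/km2 and commercial catch in kg to tonnes (via the optional
#' \code{unit} column with values \code{"t"}, \code{"kg"} or
#' \code{"kg_km2"}). Unknown labels, non-positive values, duplicate keys
#' and records for non-targeted combinations are rejected with informative
#' errors.
#'
#' @param cpue_csv path to the CPUE CSV: columns \code{year}, \code{gear},
#'   \code{group}, \code{catch}, \code{effort}, optional \code{unit}.
#' @param landings_csv path to the landings CSV: columns \code{year},
#'   \code{group}, and \code{landings_tonnes} (or \code{landings} already
#'   in kt).
#' @param structure an \code{\link{ecosystem_structure}}.
#' @return an \code{\link{observation_panel}}.
#' @export
read_panel <- function(cpue_csv, landings_csv,
                       structure = ecosystem_structure()) {
  cp <- utils::read.csv(cpue_csv, stringsAsFactors = FALSE)
  ld <- utils::read.csv(landings_csv, stringsAsFactors = FALSE)
  if ("unit" %in% names(cp)) {
    kg <- cp$unit %in% c("kg", "kg_km2")
    cp$catch[kg] <- cp$catch[kg] / 1000
    cp$unit <- NULL
  }
  if ("landings_tonnes" %in% names(ld)) {
    ld$landings <- ld$landings_tonnes / 1000
    ld$landings_tonnes <- NULL
  }
  observation_panel(cp, ld, structure)
}

#' Write an observation panel to CSV files
#'
#' Inverse of \code{\link{read_panel}} (values written in the model's
#' working units: catch in tonnes, landings in kilotonnes under column
#' \code{landings}); the write/read round trip is lossless.
#'
#' @param panel an \code{\link{observation_panel}}.
#' @param cpue_csv,landings_csv output paths.
#' @return invisibly, the two paths.
#' @export
write_panel <- function(panel, cpue_csv, landings_csv) {
  utils::write.csv(panel$cpue, cpue_csv, row.names = FALSE)
  utils::write.csv(panel$landings, landings_csv, row.names = FALSE)
  invisible(c(cpue_csv, landings_csv))
}

#' Persist posterior draws as CSV plus JSON metadata
#'
#' Writes the monitored draws in a long columnar layout (chain, iteration,
#' parameter, value) and a JSON sidecar with the protocol, seed and
#' structure labels.
#'
#' @param fit a \code{\link{gompertz_ssm}} fit.
#' @param draws_csv,meta_json output paths.
#' @return invisibly, the two paths.
#' @export
write_draws <- function(fit, draws_csv, meta_json) {
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    M <- as.matrix(fit$draws[[ch]])
    data.frame(chain = ch, iteration = rep(seq_len(nrow(M)), ncol(M)),
               parameter = rep(colnames(M), each = nrow(M)),
               value = as.numeric(M))
  }))
  utils::write.csv(long, draws_csv, row.names = FALSE)
  meta <- list(protocol = unclass(fit$protocol),
               groups = fit$structure$groups,
               gears = fit$structure$gears,
               combos = fit$structure$combos$combo,
               years = fit$years, likelihood = fit$likelihood)
  jsonlite::write_json(meta, meta_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(draws_csv, meta_json))
}
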