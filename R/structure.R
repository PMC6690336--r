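#' Ecosystem structure: groups, gears, targeting and sign pattern
#'
#' Defines the fixed qualitative structure of the functional-group model:
#' the ordered functional-group labels, the ordered gear labels, the boolean
#' gear-by-group targeting matrix (which gear/group combinations contribute
#' CPUE observations) and the sign pattern of the density-dependence matrix
#' \code{A}.
#'
#' The defaults describe a four-group shelf ecosystem: planktivores
#' (\code{K}), benthivores (\code{B}), demersal piscivores (\code{D}) and
#' pelagic piscivores (\code{G}), observed by seven commercial gear types
#' plus one fishery-independent bottom-trawl survey, giving 18 targeted
#' gear-by-group combinations. The consumers \code{D} and \code{G} exert
#' top-down (negative) density dependence on the basal resources \code{K}
#' and \code{B}, which in turn exert bottom-up (positive) effects on the
#' consumers; intra-group density dependence is negative; the two basal
#' groups do not interact directly, nor do the two consumer groups.
#'
#' @param groups character vector of functional-group labels, in fixed order.
#' @param gears character vector of gear labels, in fixed order.
#' @param targeting logical gear-by-group matrix; \code{TRUE} where the gear
#'   targets the group. Row/column names must match \code{gears}/\code{groups}.
#'   The default encodes the 18 targeted combinations of the four-group,
#'   eight-gear system.
#' @param sign_pattern integer group-by-group matrix with entries in
#'   \{-1, 0, +1\}: the sign of each entry of the density-dependence matrix
#'   \code{A}. Entry \code{(i, j)} is the sign of the effect of group
#'   \code{j}'s biomass on group \code{i}'s per capita growth. The diagonal
#'   must be -1.
#' @return An object of class \code{"eco_structure"}: a list with elements
#'   \code{groups}, \code{gears}, \code{targeting}, \code{sign_pattern},
#'   \code{n_groups}, \code{n_gears} and \code{combos} (a data frame of the
#'   targeted gear/group combinations in a fixed order).
#' @examples
#' str4 <- ecosystem_structure()
#' str4$n_groups      # 4
#' nrow(str4$combos)  # 18 targeted combinations
#' @export
ecosystem_structure <- function(groups = c("K", "B", "D", "G"),
                                gears = c("Dredge", "Hook", "Mixed trawl",
                                          "Net", "Pelagic trawl", "Pot",
                                          "Purse seine", "Survey"),
                                targeting = default_targeting(gears, groups),
                                sign_pattern = default_sign_pattern(groups)) {
  stopifnot(is.character(groups), is.character(gears),
            !anyDuplicated(groups), !anyDuplicated(gears))
  targeting <- as.matrix(targeting)
  storage.mode(targeting) <- "logical"
  if (!identical(dim(targeting), c(length(gears), length(groups))))
    stop("targeting must be a gears x groups matrix")
  dimnames(targeting) <- list(gears, groups)
  if (any(rowSums(targeting) < 1))
    stop("every gear must target at least one group")
  sign_pattern <- as.matrix(sign_pattern)
  if (!identical(dim(sign_pattern), c(length(groups), length(groups))))
    stop("sign_pattern must be a square groups x groups matrix")
  if (!all(sign_pattern %in% c(-1, 0, 1)))
    stop("sign_pattern entries must be -1, 0 or +1")
  if (!all(diag(sign_pattern) == -1))
    stop("diagonal of sign_pattern must be -1 (intra-group density dependence)")
  dimnames(sign_pattern) <- list(groups, groups)

  combos <- data.frame(
    gear = gears[rep(seq_along(gears), times = rowSums(targeting))],
    group = unlist(lapply(seq_along(gears),
                          function(k) groups[targeting[k, ]])),
    stringsAsFactors = FALSE)
  combos$combo <- paste(combos$gear, combos$group, sep = ":")

  structure(list(groups = groups, gears = gears, targeting = targeting,
                 sign_pattern = sign_pattern, n_groups = length(groups),
                 n_gears = length(gears), combos = combos),
            class = "eco_structure")
}

#' @rdname ecosystem_structure
#' @export
default_targeting <- function(gears = c("Dredge", "Hook", "Mixed trawl",
                                        "Net", "Pelagic trawl", "Pot",
                                        "Purse seine", "Survey"),
                              groups = c("K", "B", "D", "G")) {
  tg <- matrix(FALSE, length(gears), length(groups),
               dimnames = list(gears, groups))
  sets <- list(
    "Dredge" = c("B", "D"),
    "Hook" = c("D", "G"),
    "Mixed trawl" = c("B", "D"),
    "Net" = c("B", "D", "G"),
    "Pelagic trawl" = c("K", "D", "G"),
    "Pot" = c("B"),
    "Purse seine" = c("K", "G"),
    "Survey" = c("K", "B", "D"))
  for (g in intersect(gears, names(sets)))
    tg[g, intersect(groups, sets[[g]])] <- TRUE
  tg
}

#' @rdname ecosystem_structure
#' @export
default_sign_pattern <- function(groups = c("K", "B", "D", "G")) {
  n <- length(groups)
  sp <- matrix(0L, n, n, dimnames = list(groups, groups))
  diag(sp) <- -1L
  basal <- intersect(groups, c("K", "B"))
  consumers <- intersect(groups, c("D", "G"))
  # top-down: consumers depress basal per capita growth
  sp[basal, consumers] <- -1L
  # bottom-up: basal resources feed consumers
  sp[consumers, basal] <- 1L
  sp
}

#' @export
print.eco_structure <- function(x, ...) {
  cat("Ecosystem structure:", x$n_groups, "functional groups (",
      paste(x$groups, collapse = ", "), "),", x$n_gears, "gears\n")
  cat("Targeted gear x group combinations:", nrow(x$combos), "\n")
  invisible(x)
}
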