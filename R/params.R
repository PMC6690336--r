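#' Model parameters for the multivariate Gompertz state space model
#'
#' Bundles and validates the static unknowns of the model: the density
#' independent log growth rates \code{r} (per year, may be negative), the
#' density-dependence matrix \code{A} (entry \code{A[i, j]} is the signed
#' elasticity of group \code{i}'s one-year look-ahead prediction to group
#' \code{j}'s biomass; magnitudes in [0, 1]), the process-noise standard
#' deviations \code{eta} (log scale, one per group), the observation-error
#' standard deviations \code{sigma} (log scale, one per gear), catchabilities
#' \code{q} (one per targeted gear/group combination, CPUE units per
#' kilotonne of biomass), annual fished fractions \code{F} in (0, 1)
#' (group-by-year matrix) and the initial biomass vector \code{x0}
#' (kilotonnes).
#'
#' @param r numeric vector of per-group growth rates (1/yr).
#' @param A numeric group-by-group density-dependence matrix. Its sign
#'   pattern must agree with \code{structure$sign_pattern} and all magnitudes
#'   must lie in [0, 1].
#' @param eta positive numeric vector of process-noise standard deviations.
#' @param sigma positive numeric vector of observation-error standard
#'   deviations, one per gear (named by gear when a structure is given).
#' @param q positive numeric vector of catchabilities named by targeted
#'   combination \code{"gear:group"} (order of \code{structure$combos}).
#' @param F numeric group-by-year matrix of fished fractions in (0, 1), or
#'   \code{NULL} when not needed.
#' @param x0 positive numeric vector of initial biomasses (kt), or
#'   \code{NULL}.
#' @param structure an \code{\link{ecosystem_structure}} used for validation,
#'   or \code{NULL} to validate shapes only.
#' @return A validated list of class \code{"gssm_params"}.
#' @export
model_params <- function(r, A, eta, sigma = NULL, q = NULL, F = NULL,
                         x0 = NULL, structure = NULL) {
  A <- as.matrix(A)
  r <- as.numeric(r)
  eta <- as.numeric(eta)
  n <- length(r)
  if (!identical(dim(A), c(n, n)))
    stop("A must be a square matrix conformable with r")
  if (any(abs(A) > 1 + 1e-12))
    stop("density-dependence magnitudes |A[i,j]| must lie in [0, 1]")
  if (length(eta) != n || any(eta <= 0))
    stop("eta must be a positive vector of length n_groups")
  if (!is.null(sigma) && any(sigma <= 0)) stop("sigma must be positive")
  if (!is.null(q) && any(q <= 0)) stop("q must be positive")
  if (!is.null(F)) {
    F <- as.matrix(F)
    if (nrow(F) != n) stop("F must have one row per group")
    if (any(F <= 0 | F >= 1)) stop("fished fractions F must lie in (0, 1)")
  }
  if (!is.null(x0) && (length(x0) != n || any(x0 <= 0)))
    stop("x0 must be a positive vector of length n_groups")
  if (!is.null(structure)) {
    if (structure$n_groups != n) stop("r length does not match structure")
    sp <- structure$sign_pattern
    if (any(sign(A)[sp == 0] != 0))
      stop("A has non-zero entries where the sign pattern is 0")
    if (any(A[sp == -1] > 0) || any(A[sp == 1] < 0))
      stop("signs of A disagree with the structure's sign pattern")
    names(r) <- structure$groups
    dimnames(A) <- list(structure$groups, structure$groups)
    names(eta) <- structure$groups
    if (!is.null(sigma)) {
      if (length(sigma) != structure$n_gears)
        stop("sigma must have one entry per gear")
      names(sigma) <- structure$gears
    }
    if (!is.null(q)) {
      if (length(q) != nrow(structure$combos))
        stop("q must have one entry per targeted combination")
      names(q) <- structure$combos$combo
    }
    if (!is.null(x0)) names(x0) <- structure$groups
    if (!is.null(F)) rownames(F) <- structure$groups
  }
  structure(list(r = r, A = A, eta = eta, sigma = sigma, q = q, F = F,
                 x0 = x0),
            class = "gssm_params")
}

#' @export
print.gssm_params <- function(x, ...) {
  cat("Gompertz state space model parameters:", length(x$r), "groups\n")
  cat("r:", signif(x$r, 3), "\n")
  cat("A:\n"); print(signif(x$A, 3))
  cat("eta:", signif(x$eta, 3), "\n")
  if (!is.null(x$sigma)) cat("sigma:", signif(x$sigma, 3), "\n")
  invisible(x)
}
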