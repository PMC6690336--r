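#' One-year look-ahead elasticity matrix
#'
#' The elasticity of next year's biomass of group i to this year's biomass
#' of group j is the (i, j) entry of \eqn{I + A}: \eqn{1 - a_{ii}} on the
#' diagonal and the signed magnitude \eqn{A_{ij}} off it. It is invariant
#' over time and biomass.
#'
#' @param A density-dependence matrix (or a \code{\link{model_params}}
#'   object, from which \code{A} is taken).
#' @return square elasticity matrix \code{I + A}.
#' @export
lookahead_elasticity <- function(A) {
  if (inherits(A, "gssm_params")) A <- A$A
  A <- as.matrix(A)
  diag(nrow(A)) + A
}

#' One-year look-ahead elasticities to fishing mortality
#'
#' The elasticity of next year's biomass of group i to the instantaneous
#' fishing mortality of group i in the current year is \eqn{-f_i(t) =
#' log(1 - F_i(t))}: always non-positive and varying by year.
#'
#' @param F fished fractions in (0, 1): vector or group-by-year matrix.
#' @return object of the same shape with entries \eqn{-f_i(t)}.
#' @export
fishing_elasticity <- function(F) {
  if (any(F <= 0 | F >= 1)) stop("fished fractions must lie in (0, 1)")
  -(-log1p(-F))
}

#' Long-term elasticity matrix
#'
#' The elasticities of the stationary distribution's means, medians or any
#' marginal quantiles to the unfished fractions \eqn{U_i = 1 - F_i} are the
#' entries of \eqn{-A^{-1}} (quantile-invariant).
#'
#' @param A density-dependence matrix (or \code{\link{model_params}}).
#' @return \eqn{-A^{-1}}.
#' @export
longterm_elasticity <- function(A) {
  if (inherits(A, "gssm_params")) A <- A$A
  A <- as.matrix(A)
  d <- det(A)
  if (!is.finite(d) || abs(d) < 1e-12)
    stop("A is singular or near-singular; long-term elasticities undefined")
  -solve(A)
}

#' Cumulative long-term elasticities for multi-group scenarios
#'
#' Elasticities add: a simultaneous proportional increase of the unfished
#' fractions of several groups sums the corresponding columns of
#' \eqn{-A^{-1}}; groups with increased fishing pressure (decreased unfished
#' fraction) enter with a minus sign.
#'
#' @param A density-dependence matrix (or \code{\link{model_params}}).
#' @param increase labels or indices of groups whose unfished fraction
#'   increases (fishing relaxed).
#' @param decrease labels or indices of groups whose unfished fraction
#'   decreases (fishing intensified). A group named in both sets cancels
#'   exactly (difference of identical columns).
#' @return per-group vector of cumulative elasticities.
#' @export
cumulative_elasticity <- function(A, increase = NULL, decrease = NULL) {
  M <- longterm_elasticity(A)
  idx <- function(g) if (is.character(g)) match(g, colnames(M)) else g
  up <- idx(increase); dn <- idx(decrease)
  out <- numeric(nrow(M))
  if (length(up)) out <- out + rowSums(M[, up, drop = FALSE])
  if (length(dn)) out <- out - rowSums(M[, dn, drop = FALSE])
  names(out) <- rownames(M)
  out
}

#' Per-draw elasticity summaries from a fitted model
#'
#' Computes the look-ahead elasticity matrix, the long-term elasticity
#' matrix and the annual fishing elasticities for every retained posterior
#' draw and summarizes them by the posterior median, central 50 and 90
#' percent intervals and the interquartile distance. Draws with
#' near-singular \code{A} (|det| below \code{tol}) are excluded from
#' long-term summaries, with the count reported.
#'
#' @param fit a \code{\link{gompertz_ssm}} fit.
#' @param tol determinant modulus below which a draw's \code{A} is treated
#'   as singular.
#' @return list of class \code{"gssm_elasticity"} with long-format summary
#'   data frames \code{lookahead}, \code{longterm}, \code{fishing} (columns
#'   \code{i}, \code{j} or \code{year}, \code{median}, \code{q25},
#'   \code{q75}, \code{q05}, \code{q95}, \code{iqd}) and
#'   \code{n_singular}.
#' @export
elasticity_report <- function(fit, tol = 1e-12) {
  st <- fit$structure
  n <- st$n_groups
  draws <- extract_draws(fit)
  nd <- nrow(draws$A)
  look <- array(NA_real_, c(nd, n, n))
  long <- array(NA_real_, c(nd, n, n))
  singular <- logical(nd)
  I <- diag(n)
  for (d in seq_len(nd)) {
    A <- matrix(draws$A[d, ], n, n)
    look[d, , ] <- I + A
    dt <- det(A)
    if (is.finite(dt) && abs(dt) >= tol) long[d, , ] <- -solve(A)
    else singular[d] <- TRUE
  }
  summ <- function(arr, ii, jj) {
    v <- arr[, ii, jj]
    qs <- stats::quantile(v, c(0.5, 0.25, 0.75, 0.05, 0.95), na.rm = TRUE)
    c(median = qs[[1]], q25 = qs[[2]], q75 = qs[[3]], q05 = qs[[4]],
      q95 = qs[[5]], iqd = qs[[3]] - qs[[2]])
  }
  grid <- expand.grid(i = seq_len(n), j = seq_len(n))
  mk <- function(arr) {
    out <- cbind(data.frame(i = st$groups[grid$i], j = st$groups[grid$j]),
                 t(mapply(function(ii, jj) summ(arr, ii, jj),
                          grid$i, grid$j)))
    rownames(out) <- NULL
    out
  }
  fyears <- draws$land_years
  fe <- log1p(-draws$F_arr)  # -f_i(t), draws x group x year
  fs <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(seq_along(fyears), function(t) {
      qs <- stats::quantile(fe[, i, t], c(0.5, 0.25, 0.75, 0.05, 0.95))
      data.frame(group = st$groups[i], year = as.integer(fyears[t]),
                 median = qs[[1]], q25 = qs[[2]], q75 = qs[[3]],
                 q05 = qs[[4]], q95 = qs[[5]], iqd = qs[[3]] - qs[[2]])
    }))
  }))
  rownames(fs) <- NULL
  out <- list(lookahead = mk(look), longterm = mk(long), fishing = fs,
              n_singular = sum(singular), n_draws = nd)
  class(out) <- "gssm_elasticity"
  out
}

#' @export
print.gssm_elasticity <- function(x, ...) {
  cat("Elasticity report over", x$n_draws, "posterior draws (",
      x$n_singular, "near-singular draws excluded from long-term)\n")
  cat("Posterior median look-ahead elasticities (I + A):\n")
  n <- sqrt(nrow(x$lookahead))
  M <- matrix(x$lookahead$median, n, n)
  dimnames(M) <- list(unique(x$lookahead$i), unique(x$lookahead$j))
  print(signif(M, 3))
  invisible(x)
}
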