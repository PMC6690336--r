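#' Convert between annual fished fraction and instantaneous mortality
#'
#' The fished fraction \eqn{F} of biomass removed in a year relates to the
#' piecewise-constant instantaneous fishing mortality rate \eqn{f} (1/yr) by
#' \eqn{f = -log(1 - F)} and inversely \eqn{F = 1 - e^{-f}}.
#'
#' @param F fished fraction(s) in [0, 1).
#' @param f non-negative instantaneous mortality rate(s).
#' @return numeric vector of the converted quantity.
#' @examples
#' fraction_to_rate(0.5)   # log(2)
#' rate_to_fraction(1)     # 1 - exp(-1)
#' @export
fraction_to_rate <- function(F) {
  if (any(!is.finite(F)) || any(F < 0) || any(F >= 1))
    stop("fished fraction F must lie in [0, 1)")
  -log1p(-F)
}

#' @rdname fraction_to_rate
#' @export
rate_to_fraction <- function(f) {
  if (any(!is.finite(f)) || any(f < 0))
    stop("instantaneous mortality f must be non-negative")
  -expm1(-f)
}

#' One-year step of the multivariate Gompertz map
#'
#' Advances biomass one year under the discrete multivariate Gompertz (Fox)
#' model \deqn{x(t+1) = diag[x(t)] exp[r - f + A log x(t) + eps],} the
#' log-linear per capita growth model whose parameters are the one-year
#' look-ahead elasticities. With \code{eps = 0} the step is deterministic;
#' the exponential per capita growth form can never predict non-positive
#' biomass.
#'
#' @param x positive biomass vector (kt).
#' @param params a \code{\link{model_params}} object, or any list with
#'   elements \code{r} and \code{A}.
#' @param f non-negative vector of instantaneous fishing mortalities
#'   (recycled to length of \code{x}); default 0.
#' @param eps process-noise vector on the log scale; default 0
#'   (deterministic step).
#' @return positive biomass vector at the next year.
#' @examples
#' p <- list(r = 0, A = matrix(-1, 1, 1))
#' gompertz_step(5, p)  # 1: x * exp(-log x) for any x > 0
#' @export
gompertz_step <- function(x, params, f = 0, eps = 0) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("biomass x must be positive and finite")
  if (any(f < 0)) stop("fishing mortality f must be non-negative")
  as.numeric(x * exp(params$r - f + drop(params$A %*% log(x)) + eps))
}

#' Interior equilibrium of the noise-free Gompertz map
#'
#' The fixed point \eqn{x^* = exp[-A^{-1}(r - f)]} shared by the discrete
#' map and its continuous-time parent model.
#'
#' @inheritParams gompertz_step
#' @return positive equilibrium biomass vector.
#' @export
equilibrium_biomass <- function(params, f = 0) {
  n <- length(params$r)
  f <- rep_len(f, n)
  as.numeric(exp(-solve(params$A, params$r - f)))
}

#' Log transition density of the stochastic Gompertz model
#'
#' Evaluates the multivariate lognormal transition density
#' \eqn{p(x(t+1) | x(t)) = LN(x(t+1) | \delta(t), S)} with location
#' \eqn{\delta(t) = log x(t) + r - f(t) + A log x(t)} and diagonal log-scale
#' covariance \eqn{S = diag[\eta^2]}.
#'
#' @param x_next positive biomass vector at year t+1.
#' @param x positive biomass vector at year t.
#' @param params list with \code{r}, \code{A} and \code{eta}.
#' @param f non-negative mortality vector for year t.
#' @return scalar log density.
#' @export
transition_logdensity <- function(x_next, x, params, f = 0) {
  if (any(x_next <= 0) || any(x <= 0) || any(!is.finite(c(x, x_next))))
    stop("biomasses must be positive and finite")
  delta <- log(x) + params$r - rep_len(f, length(x)) +
    drop(params$A %*% log(x))
  sum(stats::dlnorm(x_next, meanlog = delta, sdlog = params$eta, log = TRUE))
}

#' Simulate a biomass trajectory
#'
#' Iterates \code{\link{gompertz_step}} with i.i.d. Gaussian process noise
#' \eqn{\epsilon(t) \sim N(0, S)} on the log scale, under a fishing schedule
#' given either as fished fractions or as instantaneous mortalities.
#'
#' @param params list with \code{r}, \code{A}, \code{eta} and optionally
#'   \code{x0}.
#' @param n_years number of years in the returned trajectory (including the
#'   first).
#' @param F optional fished-fraction schedule: scalar, per-group vector, or
#'   group-by-(n_years - 1) matrix (fractions applied to the transition out
#'   of each year).
#' @param f alternative schedule on the instantaneous-mortality scale;
#'   ignored if \code{F} given.
#' @param x0 starting biomass; defaults to \code{params$x0}.
#' @param years integer label of the first year (default 1).
#' @param seed optional integer seed; when supplied the trajectory is
#'   reproducible. \code{NULL} uses (and advances) the current RNG state.
#' @param noise logical; \code{FALSE} gives the deterministic trajectory.
#' @return object of class \code{"gssm_trajectory"}: list with \code{years}
#'   (integer vector) and \code{x} (group-by-year positive matrix, kt).
#' @export
simulate_trajectory <- function(params, n_years, F = NULL, f = NULL,
                                x0 = params$x0, years = 1L, seed = NULL,
                                noise = TRUE) {
  stopifnot(n_years >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- length(params$r)
  if (is.null(x0)) stop("x0 must be supplied (or present in params)")
  if (!is.null(F)) {
    f <- fraction_to_rate(F)
  } else if (is.null(f)) f <- 0
  fmat <- matrix(f, nrow = n, ncol = max(1L, n_years - 1L))
  x <- matrix(NA_real_, n, n_years)
  x[, 1L] <- x0
  if (n_years > 1L) {
    for (t in seq_len(n_years - 1L)) {
      eps <- if (noise) stats::rnorm(n, 0, params$eta) else rep(0, n)
      x[, t + 1L] <- gompertz_step(x[, t], params, fmat[, t], eps)
    }
  }
  yrs <- seq.int(years, length.out = n_years)
  dimnames(x) <- list(names(params$r), yrs)
  structure(list(years = yrs, x = x), class = "gssm_trajectory")
}

#' @export
print.gssm_trajectory <- function(x, ...) {
  cat("Biomass trajectory:", nrow(x$x), "groups x", ncol(x$x), "years (",
      min(x$years), "-", max(x$years), ")\n")
  invisible(x)
}
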