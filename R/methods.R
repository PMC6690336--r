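#' @export
print.gssm <- function(x, ...) {
  cat("Bayesian multivariate Gompertz state space model",
      if (!x$likelihood) "(prior-only sampling)" else "", "\n")
  cat("  groups:", paste(x$structure$groups, collapse = ", "), "\n")
  cat("  years:", min(x$years), "-", max(x$years), ";",
      nrow(x$panel$cpue), "CPUE records\n")
  cat("  chains:", x$protocol$n_chains, "x", x$protocol$n_iter,
      "iterations (thin", x$protocol$thin, ") after",
      x$protocol$n_adapt, "adaptation\n")
  cat("  retained draws:", nrow(as.matrix(x$draws)), "\n")
  invisible(x)
}

#' Summary of a fitted Gompertz state space model
#'
#' Posterior quantiles of the static parameters, the posterior probability
#' of stationarity and the worst potential scale reduction factor.
#'
#' @param object a \code{\link{gompertz_ssm}} fit.
#' @param ... unused.
#' @return list of class \code{"summary.gssm"}.
#' @export
summary.gssm <- function(object, ...) {
  qs <- posterior_summary(object, "quantiles")
  gr <- tryCatch(gelman_rubin(object), error = function(e) NULL)
  out <- list(quantiles = qs,
              p_stationary = posterior_summary(object, "stationary"),
              max_psrf = if (!is.null(gr)) max(gr$psrf) else NA_real_,
              n_draws = nrow(as.matrix(object$draws)))
  class(out) <- "summary.gssm"
  out
}

#' @export
print.summary.gssm <- function(x, ...) {
  cat("Posterior summary (", x$n_draws, "draws )\n")
  cat("P(stationary) =", signif(x$p_stationary, 4),
      "; max PSRF =", signif(x$max_psrf, 4), "\n")
  sub <- x$quantiles[grepl("^(r|eta|sigma)\\[", x$quantiles$parameter), ]
  print(data.frame(parameter = sub$parameter,
                   median = signif(sub$median, 3),
                   q05 = signif(sub$q05, 3), q95 = signif(sub$q95, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Posterior-median parameter estimates
#'
#' @param object a \code{\link{gompertz_ssm}} fit.
#' @param ... unused.
#' @return a \code{\link{model_params}} object built from component-wise
#'   posterior medians (the signed \code{A} medians inherit the structure's
#'   sign pattern).
#' @export
coef.gssm <- function(object, ...) {
  d <- extract_draws(object)
  st <- object$structure
  n <- st$n_groups
  med <- function(M) apply(M, 2, stats::median)
  A <- matrix(med(d$A), n, n)
  F <- matrix(apply(d$F_arr, c(2, 3), stats::median), n,
              length(object$years))
  colnames(F) <- object$years
  x0 <- apply(d$x_arr[, , 1, drop = FALSE], 2, stats::median)
  model_params(r = med(d$r), A = A, eta = med(d$eta), sigma = med(d$sigma),
               q = med(d$q), F = F, x0 = x0, structure = st)
}

#' Posterior median latent biomass trajectory with intervals
#'
#' @param fit a \code{\link{gompertz_ssm}} fit.
#' @return data frame: group, year, median, q25, q75, q05, q95 (kt).
#' @export
latent_states <- function(fit) {
  d <- extract_draws(fit)
  st <- fit$structure
  out <- do.call(rbind, lapply(seq_len(st$n_groups), function(i) {
    do.call(rbind, lapply(seq_along(fit$years), function(t) {
      qs <- stats::quantile(d$x_arr[, i, t],
                            c(0.5, 0.25, 0.75, 0.05, 0.95))
      data.frame(group = st$groups[i], year = fit$years[t],
                 median = qs[[1]], q25 = qs[[2]], q75 = qs[[3]],
                 q05 = qs[[4]], q95 = qs[[5]])
    }))
  }))
  rownames(out) <- NULL
  out
}

#' One-year look-ahead posterior predictions
#'
#' For each posterior draw, advances the latent state of the last (or a
#' given) year one step with the deterministic Gompertz map under that
#' draw's final-year mortality, and summarizes the predicted biomass.
#'
#' @param object a \code{\link{gompertz_ssm}} fit.
#' @param year year to predict from (default the last modelled year).
#' @param ... unused.
#' @return data frame: group, year_from, median, q05, q95 of next-year
#'   biomass (kt).
#' @export
predict.gssm <- function(object, year = max(object$years), ...) {
  d <- extract_draws(object)
  st <- object$structure
  n <- st$n_groups
  t0 <- match(year, object$years)
  if (is.na(t0)) stop("year outside the modelled span")
  nd <- nrow(d$r)
  pred <- matrix(NA_real_, nd, n)
  for (k in seq_len(nd)) {
    p <- list(r = d$r[k, ], A = matrix(d$A[k, ], n, n))
    f <- -log1p(-d$F_arr[k, , t0])
    pred[k, ] <- gompertz_step(d$x_arr[k, , t0], p, f)
  }
  qs <- apply(pred, 2, stats::quantile, probs = c(0.5, 0.05, 0.95))
  data.frame(group = st$groups, year_from = year, median = qs[1, ],
             q05 = qs[2, ], q95 = qs[3, ], row.names = NULL)
}

#' Simulate trajectories from the posterior
#'
#' Draws posterior parameter sets and simulates forward trajectories from
#' the last modelled year's latent state under the fitted final-year
#' fishing mortality (or a supplied constant mortality vector).
#'
#' @param object a \code{\link{gompertz_ssm}} fit.
#' @param nsim number of posterior draws to simulate (sampled without
#'   replacement when fewer than the retained draws).
#' @param seed optional integer seed.
#' @param n_years years to simulate forward.
#' @param f constant mortality vector; default the draw's final-year value.
#' @param ... unused.
#' @return array nsim x groups x (n_years + 1) of biomasses (kt), the first
#'   slice being the starting state.
#' @export
simulate.gssm <- function(object, nsim = 100, seed = NULL, n_years = 10,
                          f = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- extract_draws(object)
  st <- object$structure
  n <- st$n_groups
  nd <- nrow(d$r)
  take <- if (nsim < nd) sample.int(nd, nsim) else seq_len(nd)
  Tl <- length(object$years)
  out <- array(NA_real_, c(length(take), n, n_years + 1))
  for (s in seq_along(take)) {
    k <- take[s]
    p <- list(r = d$r[k, ], A = matrix(d$A[k, ], n, n),
              eta = d$eta[k, ])
    fk <- if (is.null(f)) -log1p(-d$F_arr[k, , Tl]) else f
    tr <- simulate_trajectory(p, n_years + 1, f = fk,
                              x0 = d$x_arr[k, , Tl])
    out[s, , ] <- tr$x
  }
  dimnames(out) <- list(NULL, st$groups,
                        seq(max(object$years), by = 1,
                            length.out = n_years + 1))
  out
}

#' Observation-scale residuals
#'
#' Standardized log-scale CPUE residuals at the posterior-median parameters
#' and latent states: \eqn{(log C - log(q E x)) / \sigma_k} per record.
#'
#' @param object a \code{\link{gompertz_ssm}} fit.
#' @param ... unused.
#' @return the CPUE table with fitted log-location and standardized
#'   residual columns.
#' @export
residuals.gssm <- function(object, ...) {
  est <- coef.gssm(object)
  d <- extract_draws(object)
  st <- object$structure
  xmed <- apply(d$x_arr, c(2, 3), stats::median)
  colnames(xmed) <- object$years
  cp <- object$panel$cpue
  gi <- match(cp$group, st$groups)
  yi <- match(cp$year, object$years)
  mu <- log(est$q[paste(cp$gear, cp$group, sep = ":")] * cp$effort *
              xmed[cbind(gi, yi)])
  cp$fitted_log <- mu
  cp$residual <- (log(cp$catch) - mu) / est$sigma[cp$gear]
  cp
}

#' Plot posterior latent biomass trajectories
#'
#' One panel per functional group: posterior median (line), central 50
#' percent (dark) and 90 percent (light) credible bands, with the recorded
#' landings overlaid as a dotted line. Base graphics.
#'
#' @param x a \code{\link{gompertz_ssm}} fit.
#' @param log_scale logical; plot on a log y-axis.
#' @param ... passed to \code{plot}.
#' @export
plot.gssm <- function(x, log_scale = TRUE, ...) {
  ls <- latent_states(x)
  h <- landings_matrix(x$panel)
  st <- x$structure
  op <- graphics::par(mfrow = grDevices::n2mfrow(st$n_groups),
                      mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (g in st$groups) {
    sub <- ls[ls$group == g, ]
    ylim <- range(sub$q05, sub$q95, h[g, ])
    graphics::plot(sub$year, sub$median, type = "n", ylim = ylim,
                   log = if (log_scale) "y" else "", xlab = "year",
                   ylab = "biomass (kt)", main = g, ...)
    graphics::polygon(c(sub$year, rev(sub$year)), c(sub$q05, rev(sub$q95)),
                      col = "grey85", border = NA)
    graphics::polygon(c(sub$year, rev(sub$year)), c(sub$q25, rev(sub$q75)),
                      col = "grey65", border = NA)
    graphics::lines(sub$year, sub$median, col = "white", lwd = 2)
    graphics::lines(as.integer(colnames(h)), h[g, ], lty = 3)
  }
  invisible(x)
}
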