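#' @export
print.landscape_fit <- function(x, ...) {
  cat("Landscape tilt fit (", x$method, " method)\n", sep = "")
  cat("  formula:", deparse(x$formula), "\n")
  cat("  grid:", min(x$grid), "..", max(x$grid),
      " (", length(x$grid), " points)\n", sep = "")
  print(coef(x))
  invisible(x)
}

#' Fitted tilt per stratum
#' @param object a [landscape_fit()] object.
#' @param ... unused.
#' @return Named numeric vector of fitted `k` values.
#' @export
coef.landscape_fit <- function(object, ...) {
  vapply(object$fits, `[[`, numeric(1), "k_hat")
}

#' Summary of a landscape fit
#'
#' One row per stratum with the fitted tilt, the observed rising proportion
#' and rising median, the model's values at the fitted tilt, and the
#' minimal distance split into its components.
#'
#' @param object a [landscape_fit()] object.
#' @param ... unused.
#' @return A data frame of class `"summary.landscape_fit"`.
#' @export
summary.landscape_fit <- function(object, ...) {
  rows <- lapply(names(object$fits), function(nm) {
    f <- object$fits[[nm]]
    i <- match(f$k_hat, f$distance$k)
    data.frame(stratum = nm, k_hat = f$k_hat,
               n = f$observed$n_total,
               obs_prop_rising = f$observed$prop_rising,
               fit_prop_rising = f$distance$sim_prop[i],
               obs_median_rising = f$observed$median_rising,
               fit_median_rising = f$distance$sim_median[i],
               distance = f$distance$total[i],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("summary.landscape_fit", "data.frame")
  out
}

#' @export
print.summary.landscape_fit <- function(x, digits = 4, ...) {
  cat("Fitted landscape tilts:\n")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Model predictions at the fitted tilts
#'
#' Stationary rising probability or rising median of the fitted landscape
#' for each stratum (quadrature oracle, independent of the fitting method).
#'
#' @param object a [landscape_fit()] object.
#' @param type `"prob"` for the rising probability, `"median"` for the
#'   rising median (normalised onglide units).
#' @param k optional numeric vector of tilts to evaluate instead of the
#'   fitted ones.
#' @param ... unused.
#' @return Named numeric vector.
#' @export
predict.landscape_fit <- function(object, type = c("prob", "median"),
                                  k = NULL, ...) {
  type <- match.arg(type)
  if (is.null(k)) k <- coef(object)
  fun <- if (type == "prob") rising_probability else rising_median
  vapply(k, function(kk)
    fun(landscape("cubic_tilt", kk, object$sigma)), numeric(1))
}

#' Residual mismatch of a landscape fit
#'
#' Observed minus fitted values per stratum, on the scale of each fitting
#' criterion: the rising proportion and the rising median.
#'
#' @param object a [landscape_fit()] object.
#' @param ... unused.
#' @return A data frame with `stratum`, `prop_residual`, `median_residual`.
#' @export
residuals.landscape_fit <- function(object, ...) {
  s <- summary(object)
  data.frame(stratum = s$stratum,
             prop_residual = s$obs_prop_rising - s$fit_prop_rising,
             median_residual = s$obs_median_rising - s$fit_median_rising)
}

#' @export
fitted.landscape_fit <- function(object, ...) {
  predict(object, type = "prob")
}

#' Simulate onglide ensembles from a fitted landscape
#'
#' Draws `nsim` final states from the stochastic system at each stratum's
#' fitted tilt — parametric-bootstrap style replicate data on the
#' normalised onglide scale.
#'
#' @param object a [landscape_fit()] object.
#' @param nsim runs per stratum.
#' @param seed integer seed.
#' @param ... unused.
#' @return Named list (one numeric vector per stratum).
#' @export
simulate.landscape_fit <- function(object, nsim = 2500, seed = 1, ...) {
  ks <- coef(object)
  out <- lapply(seq_along(ks), function(i)
    simulate(landscape("cubic_tilt", ks[i], object$sigma), nsim = nsim,
             seed = seed + i, dt = object$dt, n_steps = object$n_steps,
             init = object$init))
  names(out) <- names(ks)
  out
}

#' Distance curves of a landscape fit
#'
#' Plots the total distance against the candidate tilt for each stratum,
#' marking the fitted minimum — the standard diagnostic for the grid
#' search.
#'
#' @param x a [landscape_fit()] object.
#' @param strata which strata to draw (default all).
#' @param ... passed to [graphics::plot()].
#' @export
plot.landscape_fit <- function(x, strata = names(x$fits), ...) {
  old <- graphics::par(mfrow = c(1, length(strata)))
  on.exit(graphics::par(old))
  for (nm in strata) {
    f <- x$fits[[nm]]
    graphics::plot(f$distance$k, f$distance$total, type = "l",
                   xlab = "tilt k", ylab = "distance", main = nm, ...)
    graphics::abline(v = f$k_hat, lty = 2, col = "red")
  }
  invisible(x)
}
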