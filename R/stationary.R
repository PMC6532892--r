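#' Stationary density of the noisy landscape system
#'
#' Long-run density of the overdamped Langevin system
#' \eqn{dx = F(x)\,dt + \sigma\,dW}: \eqn{p(x) \propto \exp(-2V(x)/\sigma^2)},
#' evaluated on a grid and normalised to integrate to one by the trapezoid
#' rule. The quartic growth of the potential makes mass outside a modest
#' grid negligible, so quadrature on a finite interval is a faithful
#' deterministic oracle for the stochastic simulation.
#'
#' @param spec a [landscape()] object with `sigma > 0`.
#' @param grid ordered numeric vector of states. Must span at least
#'   \eqn{[-2, 2]} with 1001 or more points; the default is 4001 points on
#'   \eqn{[-2, 2]} (`cubic_tilt`) or \eqn{[-3, 3]} (`linear_tilt`).
#' @return A data frame with columns `x` and `density`.
#' @export
stationary_density <- function(spec, grid = NULL) {
  check_landscape(spec)
  if (is.null(grid)) {
    half <- if (spec$family == "linear_tilt") 3 else 2
    grid <- seq(-half, half, length.out = 4001L)
  }
  if (length(grid) < 1001L || min(grid) > -2 || max(grid) < 2 || is.unsorted(grid))
    stop("grid must be ordered, span at least [-2, 2] and have >= 1001 points")
  lw <- -2 * potential(spec, grid) / spec$sigma^2
  d <- exp(lw - max(lw))            # guard against underflow for large |V|
  z <- trapz(grid, d)
  data.frame(x = grid, density = d / z)
}

# trapezoid quadrature on an ordered grid
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' Probability of a rising outcome under the stationary law
#'
#' Fraction of stationary mass at \eqn{x > 0}: the model-side analogue of
#' the rising-accent proportion. Strictly increasing in the tilt `k` and
#' exactly 1/2 at `k = 0` by symmetry.
#'
#' @inheritParams stationary_density
#' @return A probability in \eqn{[0, 1]}.
#' @export
rising_probability <- function(spec, grid = NULL) {
  d <- stationary_density(spec, grid)
  pos <- d$x >= 0
  trapz(d$x[pos], d$density[pos])
}

#' Median of the rising portion of the stationary law
#'
#' Median of the stationary distribution conditioned on \eqn{x > 0},
#' the model-side analogue of the observed median of rising onglides.
#'
#' @inheritParams stationary_density
#' @return A positive state value.
#' @export
rising_median <- function(spec, grid = NULL) {
  d <- stationary_density(spec, grid)
  pos <- d$x >= 0
  x <- d$x[pos]; y <- d$density[pos]
  n <- length(x)
  cum <- c(0, cumsum((y[-1] + y[-n]) * diff(x)) / 2)
  tot <- cum[n]
  if (tot <= 0) stop("no positive stationary mass; rising median undefined")
  stats::approx(cum / tot, x, xout = 0.5, ties = "ordered")$y
}

# CDF of the stationary law as a function, for KS tests and
# inverse-transform sampling
stationary_cdf <- function(spec, grid = NULL) {
  d <- stationary_density(spec, grid)
  n <- nrow(d)
  cum <- c(0, cumsum((d$density[-1] + d$density[-n]) * diff(d$x)) / 2)
  cum <- cum / cum[n]
  stats::approxfun(d$x, cum, yleft = 0, yright = 1, ties = "ordered")
}
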