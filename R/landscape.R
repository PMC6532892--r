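#' Construct a one-dimensional attractor landscape
#'
#' A landscape is a parameterised potential family for the state variable
#' \eqn{x} (the tonal onglide on the normalised scale). Three families are
#' supported:
#' \describe{
#'   \item{\code{"intro_linear"}}{\eqn{V(x) = x^2/4}, \eqn{F(x) = -x/2}: a
#'     single attractor at 0, used for worked examples of discrete iteration.}
#'   \item{\code{"linear_tilt"}}{\eqn{V(x) = x^4 - x^2 - kx}: the textbook
#'     tilted double well whose attractor pair vanishes in a saddle-node
#'     bifurcation at \eqn{|k| = 4/(3\sqrt{6})}.}
#'   \item{\code{"cubic_tilt"}}{\eqn{V(x) = 18x^4 - kx^3 - 7.5x^2}: the
#'     production model for falling (left well) versus rising (right well)
#'     pitch accents; the control parameter \eqn{k} tilts the landscape and
#'     trades the two attractors' relative stability.}
#' }
#'
#' @param family one of `"cubic_tilt"`, `"linear_tilt"`, `"intro_linear"`.
#' @param k control parameter (dimensionless tilt). Ignored by
#'   `"intro_linear"`.
#' @param sigma standard deviation of the driving Gaussian noise (state
#'   units); must be positive.
#' @return An object of class `"landscape"`.
#' @examples
#' ls <- landscape("cubic_tilt", k = 5.4)
#' potential(ls, 0.5)
#' fixed_points(ls)
#' @export
landscape <- function(family = c("cubic_tilt", "linear_tilt", "intro_linear"),
                      k = 0, sigma = 1) {
  family <- match.arg(family)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k))
    stop("'k' must be a single finite number")
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stop("'sigma' must be a single positive number")
  structure(list(family = family, k = k, sigma = sigma),
            class = "landscape")
}

family_code <- function(spec) {
  match(spec$family, c("intro_linear", "linear_tilt", "cubic_tilt")) - 1L
}

check_landscape <- function(spec) {
  if (!inherits(spec, "landscape"))
    stop("'spec' must be a landscape object; see landscape()")
  invisible(spec)
}

#' Potential energy of a landscape
#'
#' @param spec a [landscape()] object.
#' @param x numeric vector of states; must be finite.
#' @return `V(x)`, same length as `x`.
#' @export
potential <- function(spec, x) {
  check_landscape(spec)
  if (!is.numeric(x) || any(!is.finite(x))) stop("'x' must be finite numeric")
  k <- spec$k
  switch(spec$family,
    intro_linear = x^2 / 4,
    linear_tilt  = x^4 - x^2 - k * x,
    cubic_tilt   = 18 * x^4 - k * x^3 - 7.5 * x^2
  )
}

#' Deterministic force of a landscape
#'
#' The force is the negative derivative of the potential, \eqn{F = -dV/dx}.
#' Noise is added by the simulator, not here.
#'
#' @inheritParams potential
#' @return `F(x)`, same length as `x`.
#' @export
force <- function(spec, x) {
  check_landscape(spec)
  if (!is.numeric(x) || any(!is.finite(x))) stop("'x' must be finite numeric")
  k <- spec$k
  switch(spec$family,
    intro_linear = -x / 2,
    linear_tilt  = -(4 * x^3 - 2 * x - k),
    cubic_tilt   = -(72 * x^3 - 3 * k * x^2 - 15 * x)
  )
}

# second derivative of V, used to classify fixed points
potential_curvature <- function(spec, x) {
  k <- spec$k
  switch(spec$family,
    intro_linear = rep(0.5, length(x)),
    linear_tilt  = 12 * x^2 - 2,
    cubic_tilt   = 216 * x^2 - 6 * k * x - 15
  )
}

#' Fixed points of a landscape
#'
#' Finds all real roots of the force and classifies each as an attractor
#' (potential minimum, positive curvature) or repeller (maximum, negative
#' curvature). A degenerate root with zero curvature (the saddle-node point)
#' is reported as a repeller with `degenerate = TRUE`.
#'
#' @param spec a [landscape()] object.
#' @param tol absolute tolerance on `|F(x*)|` used to accept a root.
#' @return A data frame with columns `location`, `kind`
#'   (`"attractor"`/`"repeller"`), `potential`, `curvature`, `degenerate`,
#'   sorted by location.
#' @export
fixed_points <- function(spec, tol = 1e-12) {
  check_landscape(spec)
  k <- spec$k
  roots <- switch(spec$family,
    intro_linear = 0,
    linear_tilt = {
      # real roots of 4x^3 - 2x - k via polyroot, polished by Newton
      z <- polyroot(c(-k, -2, 0, 4))
      r <- Re(z[abs(Im(z)) < 1e-8])
      g <- 12 * r^2 - 2
      ok <- abs(g) > 1e-6            # Newton polish away from the double root
      r[ok] <- r[ok] - (4 * r[ok]^3 - 2 * r[ok] - k) / g[ok]
      r <- sort(r)
      r[c(TRUE, diff(r) > 1e-8)]     # merge numerically coincident roots
    },
    cubic_tilt = {
      # 72x^3 - 3kx^2 - 15x = 3x (24x^2 - kx - 5); the quadratic's root
      # product is -5/24 < 0, so one positive and one negative root always
      disc <- sqrt(k^2 + 480)
      sort(c(0, (k - disc) / 48, (k + disc) / 48))
    }
  )
  stopifnot(all(abs(force(spec, roots)) < max(tol, 1e-9 * (1 + abs(k)))))
  curv <- potential_curvature(spec, roots)
  data.frame(
    location = roots,
    kind = ifelse(curv > 0, "attractor", "repeller"),
    potential = potential(spec, roots),
    curvature = curv,
    degenerate = curv == 0
  )
}

#' Number of attractors and the saddle-node threshold
#'
#' For the `linear_tilt` family the double well collapses to a single well
#' when the tilt passes the saddle-node point: two attractors exist for
#' \eqn{|k| < k_c} and one for \eqn{|k| > k_c}, with
#' \eqn{k_c = 4/(3\sqrt{6})} obtained from the double-root condition of
#' \eqn{4x^3 - 2x - k}. The `cubic_tilt` family keeps both attractors for
#' every finite `k` (critical value `NA`).
#'
#' @param spec a [landscape()] object.
#' @return A list with `n_attractors` (integer) and `k_critical`
#'   (`NA` when the count never changes).
#' @export
attractor_count <- function(spec) {
  check_landscape(spec)
  switch(spec$family,
    intro_linear = list(n_attractors = 1L, k_critical = NA_real_),
    cubic_tilt   = list(n_attractors = 2L, k_critical = NA_real_),
    linear_tilt = {
      k_c <- 4 / (3 * sqrt(6))
      n <- if (abs(spec$k) < k_c) 2L else 1L
      list(n_attractors = n, k_critical = k_c)
    }
  )
}

#' Deterministic unit-step iteration of the force map
#'
#' The discrete update \eqn{x_{i+1} = x_i + F(x_i)} with unit step and no
#' noise, as used in worked examples of state evolution towards an
#' attractor.
#'
#' @param spec a [landscape()] object.
#' @param x0 starting state.
#' @param n number of steps (`n >= 0`).
#' @return Numeric vector of `n + 1` states, beginning with `x0`.
#' @export
iterate_map <- function(spec, x0, n) {
  check_landscape(spec)
  stopifnot(is.numeric(x0), length(x0) == 1L, is.finite(x0),
            length(n) == 1L, n >= 0, n == as.integer(n))
  out <- numeric(n + 1)
  out[1] <- x0
  for (i in seq_len(n)) {
    out[i + 1] <- out[i] + force(spec, out[i])
    if (!is.finite(out[i + 1]) || abs(out[i + 1]) > 1e6)
      stop("iteration diverged at step ", i)
  }
  out
}

#' @export
print.landscape <- function(x, ...) {
  form <- switch(x$family,
    intro_linear = "V(x) = x^2/4",
    linear_tilt  = sprintf("V(x) = x^4 - x^2 - %gx", x$k),
    cubic_tilt   = sprintf("V(x) = 18x^4 - %gx^3 - 7.5x^2", x$k)
  )
  cat("Attractor landscape [", x$family, "]\n", sep = "")
  cat("  ", form, "   k =", x$k, "  sigma =", x$sigma, "\n")
  fp <- fixed_points(x)
  att <- fp[fp$kind == "attractor", , drop = FALSE]
  cat("  attractors at:", paste(signif(att$location, 5), collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn landscape plot the potential (and optionally the stationary
#'   density) over a state range.
#' @param x a landscape object (plot method).
#' @param xlim state range to draw.
#' @param density logical; overlay the stationary density of the noisy
#'   system.
#' @param ... passed to [graphics::plot()].
#' @export
plot.landscape <- function(x, xlim = c(-1.2, 1.2), density = FALSE, ...) {
  xs <- seq(xlim[1], xlim[2], length.out = 512)
  graphics::plot(xs, potential(x, xs), type = "l", lwd = 2,
                 xlab = "state x (normalised onglide)",
                 ylab = "potential V(x)", ...)
  fp <- fixed_points(x)
  graphics::points(fp$location, fp$potential,
                   pch = ifelse(fp$kind == "attractor", 19, 1))
  if (density) {
    g <- seq(-2, 2, length.out = 2001)
    d <- stationary_density(x, g)
    sc <- diff(range(potential(x, xs))) / max(d$density)
    graphics::lines(g, d$density * sc + min(potential(x, xs)),
                    col = "grey50", lty = 2)
  }
  invisible(x)
}
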