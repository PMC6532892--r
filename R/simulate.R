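#' Stochastic simulation of accent production
#'
#' Simulates an ensemble of independent runs of the noisy landscape system
#' with the Euler-Maruyama scheme
#' \deqn{x_{i+1} = x_i + F(x_i)\,dt + \sigma\sqrt{dt}\,\eta_i,\qquad
#'       \eta_i \sim N(0, 1),}
#' each run starting from a uniformly drawn initial state and stopping after
#' a fixed time window. The final state of one run is one produced pitch
#' accent: negative for a falling, positive for a rising onglide.
#'
#' The defaults (`dt = 0.005`, `n_steps = 2000`, so a window of 10 time
#' units) reach the stationary regime for the tilts used in fitting; see
#' [equilibration_check()].
#'
#' @param object a [landscape()] object.
#' @param nsim number of runs in the ensemble (one accent per run).
#' @param seed optional integer passed to [set.seed()]; if `NULL` the
#'   current RNG state is used. Identical `object`, arguments and seed give
#'   a bit-identical ensemble.
#' @param dt time step.
#' @param n_steps steps per run.
#' @param init length-2 interval from which each run's initial state is
#'   drawn uniformly.
#' @param ... unused.
#' @return Numeric vector of `nsim` final states.
#' @examples
#' ls <- landscape("cubic_tilt", k = 3.3)
#' x <- simulate(ls, nsim = 500, seed = 1)
#' mean(x > 0) # rising fraction
#' @export
simulate.landscape <- function(object, nsim = 2500, seed = NULL,
                               dt = 0.005, n_steps = 2000,
                               init = c(-1, 1), ...) {
  check_landscape(object)
  stopifnot(dt > 0, n_steps >= 1, nsim >= 1,
            length(init) == 2L, init[1] < init[2])
  if (!is.null(seed)) set.seed(seed)
  x0 <- stats::runif(nsim, init[1], init[2])
  em_ensemble_cpp(x0, family_code(object), object$k, object$sigma,
                  dt, as.integer(n_steps))
}

#' Check that the simulation window reaches the stationary regime
#'
#' Runs ensembles at doubling step counts and compares the rising fraction
#' across the doublings and against the quadrature value of
#' [rising_probability()]. Convergence is declared when the last two
#' fractions differ by no more than twice the binomial standard error and
#' the last fraction agrees with the quadrature value at the same
#' resolution.
#'
#' @param spec a [landscape()] object.
#' @param nsim runs per ensemble.
#' @param dt time step.
#' @param n_steps largest step count examined (doublings up from
#'   `n_steps / 2^(n_levels - 1)`).
#' @param n_levels number of doublings.
#' @param seed integer seed.
#' @return A list with a data frame `report` (columns `n_steps`,
#'   `rising_fraction`), the quadrature `stationary_value`, and a logical
#'   `converged`.
#' @export
equilibration_check <- function(spec, nsim = 2500, dt = 0.005,
                                n_steps = 2000, n_levels = 4, seed = 1) {
  check_landscape(spec)
  steps <- rev(round(n_steps / 2^(seq_len(n_levels) - 1)))
  steps <- steps[steps >= 1]
  frac <- vapply(seq_along(steps), function(i) {
    x <- simulate(spec, nsim = nsim, seed = seed + i, dt = dt,
                  n_steps = steps[i])
    mean(x > 0)
  }, numeric(1))
  m <- length(steps)
  se <- max(sqrt(frac[m] * (1 - frac[m]) / nsim), 1e-6)
  stat <- rising_probability(spec)
  agree_doubling <- m < 2 || abs(frac[m] - frac[m - 1]) <= 2 * se
  agree_oracle <- abs(frac[m] - stat) <= 3 * se
  list(report = data.frame(n_steps = steps, rising_fraction = frac),
       stationary_value = stat,
       converged = agree_doubling && agree_oracle)
}
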