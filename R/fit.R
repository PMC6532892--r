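#' Distance between observed and simulated onglide summaries
#'
#' The grid fit compares an observed set of onglides to model output on two
#' criteria: (1) the balance of the distribution, as the absolute
#' difference of rising proportions, and (2) the location of the rising
#' portion, as the absolute difference of rising-subset medians. The total
#' distance is the weighted sum of the two components.
#'
#' The balance criterion uses the rising proportion (bounded in
#' \eqn{[0,1]}) rather than a literal falls:rises quotient, which is
#' unbounded as rises vanish and would swamp the additive combination.
#'
#' @param targets a list with `prop_rising` and `median_rising` (the
#'   observed values), e.g. an [onglide_summary()].
#' @param sim_stats an [onglide_summary()] of simulated output (or any list
#'   with the same fields).
#' @param weights non-negative length-2 vector: weights of the proportion
#'   and median components.
#' @param median_penalty distance charged for the median component when the
#'   median is undefined on either side (no rises).
#' @return A list: `total`, `prop_component`, `median_component`.
#' @export
onglide_distance <- function(targets, sim_stats, weights = c(1, 1),
                             median_penalty = 1e3) {
  stopifnot(length(weights) == 2L, all(weights >= 0))
  dprop <- abs(targets$prop_rising - sim_stats$prop_rising)
  m_obs <- targets$median_rising
  m_sim <- sim_stats$median_rising
  if (weights[2] == 0) {
    dmed <- 0
  } else if (is.null(m_obs) || is.null(m_sim) || is.na(m_obs) || is.na(m_sim)) {
    warning("rising median undefined; using penalty for the median component")
    dmed <- median_penalty
  } else {
    dmed <- abs(m_obs - m_sim)
  }
  list(total = weights[1] * dprop + weights[2] * dmed,
       prop_component = dprop, median_component = dmed)
}

#' Fit the landscape tilt to onglide data by simulation-based grid search
#'
#' For each candidate tilt `k` on a grid, ensembles of the stochastic
#' landscape system are simulated, their rising proportion and rising
#' median are averaged over replicates, and the weighted distance
#' ([onglide_distance()]) to the observed data is computed; the `k` with
#' the minimal distance wins. With a formula such as
#' `onglide_norm ~ condition`, one tilt is fitted per stratum of the
#' right-hand side (use `condition + group` for per-group fits).
#'
#' `method = "quadrature"` replaces the simulated ensembles with the
#' deterministic stationary law \eqn{\propto \exp(-2V/\sigma^2)}
#' (quadrature oracle): instant and noise-free, at the cost of ignoring
#' any finite-window effect.
#'
#' @param formula a formula, response = signed onglides (normalised scale),
#'   right-hand side = stratifying factors, e.g. `onglide_norm ~ condition`.
#'   Use `~ 1` to fit a single tilt to all records.
#' @param data data frame holding the formula's variables; background rows
#'   are excluded.
#' @param grid candidate tilt values (defaults to the fitting grid
#'   \eqn{-5, -4.9, \ldots, 10}).
#' @param replicates simulated ensembles per grid point whose summary
#'   statistics are averaged (default 10).
#' @param nsim runs per ensemble (default 2500).
#' @param sigma noise standard deviation of the landscape.
#' @param weights passed to [onglide_distance()]; `c(1, 0)` fits on the
#'   rising proportion alone.
#' @param method `"simulation"` (the reference procedure) or
#'   `"quadrature"` (deterministic oracle).
#' @param dt,n_steps,init simulation window, passed to
#'   [simulate.landscape()].
#' @param seed integer; replicate `r` uses seed `seed + r` at every grid
#'   point (common random numbers across the grid), recorded in the result.
#' @return An object of class `"landscape_fit"`; see
#'   [coef.landscape_fit()], [summary.landscape_fit()],
#'   [predict.landscape_fit()], [plot.landscape_fit()].
#' @examples
#' d <- generate_onglides(generator_spec(seed = 7))
#' d$onglide_norm <- signed_log(d$onglide_st)
#' fit <- landscape_fit(onglide_norm ~ condition, d, method = "quadrature")
#' coef(fit)
#' @export
landscape_fit <- function(formula, data, grid = seq(-5, 10, by = 0.1),
                          replicates = 10, nsim = 2500, sigma = 1,
                          weights = c(1, 1),
                          method = c("simulation", "quadrature"),
                          dt = 0.005, n_steps = 2000, init = c(-1, 1),
                          seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  if (!length(grid)) stop("empty grid")
  grid <- sort(grid)
  data <- drop_background(data)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (is.null(y)) stop("formula needs a response: the onglide values")
  strata <- if (ncol(mf) > 1L) interaction(mf[-1L], drop = TRUE, sep = ":")
            else factor(rep("all", length(y)))

  sim_stats <- precompute_grid_stats(grid, sigma, method, replicates, nsim,
                                     dt, n_steps, init, seed)

  fits <- lapply(split(y, strata), function(yy) {
    obs <- onglide_summary(yy)
    comp <- mapply(function(p, m) {
      d <- onglide_distance(obs, list(prop_rising = p, median_rising = m),
                            weights = weights)
      c(d$total, d$prop_component, d$median_component)
    }, sim_stats$prop, sim_stats$median)
    total <- comp[1, ]
    best <- which(total == min(total))
    best <- best[which.min(abs(grid[best]))] # tie -> most parsimonious tilt
    list(k_hat = grid[best],
         distance = data.frame(k = grid, total = total,
                               prop_component = comp[2, ],
                               median_component = comp[3, ],
                               sim_prop = sim_stats$prop,
                               sim_median = sim_stats$median),
         observed = obs)
  })

  structure(list(
    call = match.call(), formula = formula, strata = levels(strata),
    fits = fits, grid = grid, method = method, sigma = sigma,
    weights = weights, replicates = replicates, nsim = nsim,
    dt = dt, n_steps = n_steps, init = init, seed = seed,
    seed_rule = "seed + replicate, shared across grid points"
  ), class = "landscape_fit")
}

# mean rising proportion / rising median of the model at every grid k,
# shared by all strata of one fit
precompute_grid_stats <- function(grid, sigma, method, replicates, nsim,
                                  dt, n_steps, init, seed) {
  if (method == "quadrature") {
    prop <- vapply(grid, function(k)
      rising_probability(landscape("cubic_tilt", k, sigma)), numeric(1))
    med <- vapply(grid, function(k)
      rising_median(landscape("cubic_tilt", k, sigma)), numeric(1))
    return(list(prop = prop, median = med))
  }
  prop <- med <- numeric(length(grid))
  for (i in seq_along(grid)) {
    ls <- landscape("cubic_tilt", grid[i], sigma)
    p <- m <- numeric(replicates)
    for (r in seq_len(replicates)) {
      # replicate r reuses seed + r at every grid point: common random
      # numbers across the grid, so the distance curve's noise largely
      # cancels when comparing neighbouring tilts
      x <- simulate(ls, nsim = nsim, seed = seed + r,
                    dt = dt, n_steps = n_steps, init = init)
      p[r] <- mean(x > 0)
      m[r] <- if (any(x > 0)) stats::median(x[x > 0]) else NA_real_
    }
    prop[i] <- mean(p)
    med[i] <- mean(m) # NA if any replicate had no rises: penalised later
  }
  list(prop = prop, median = med)
}

#' Deterministic inverse of the rising probability
#'
#' Returns the grid tilt whose stationary rising probability (quadrature
#' oracle) is closest to a target proportion. Because the rising
#' probability is strictly increasing in `k`, the inverse is unique up to
#' grid resolution.
#'
#' @param target_prop observed rising proportion, strictly between 0 and 1.
#' @param grid candidate tilt values.
#' @param sigma noise standard deviation.
#' @return The best-matching grid `k` (scalar).
#' @examples
#' invert_rising_probability(0.5) # 0 by symmetry
#' @export
invert_rising_probability <- function(target_prop, grid = seq(-5, 10, by = 0.1),
                                      sigma = 1) {
  stopifnot(length(target_prop) == 1L, target_prop > 0, target_prop < 1)
  rp <- vapply(grid, function(k)
    rising_probability(landscape("cubic_tilt", k, sigma)), numeric(1))
  if (target_prop < min(rp) || target_prop > max(rp))
    stop(sprintf("target %.3f outside achievable range [%.3f, %.3f] on this grid",
                 target_prop, min(rp), max(rp)))
  grid[which.min(abs(rp - target_prop))]
}
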