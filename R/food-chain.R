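#' Food-chain model parameters
#'
#' Bioenergetic parameter set of the tri-trophic resource-consumer-predator
#' chain. All rates except the half-saturation constants and the resource
#' carrying capacity `K` come from bioenergetics and body-size allometry; `K`
#' is the bifurcation parameter that switches the attractor between a stable
#' equilibrium (K = 0.78), a two-point limit cycle (K = 0.85), a four-point
#' limit cycle (K = 0.92) and chaos (K = 0.997).
#'
#' @param K Resource carrying capacity.
#' @param x_c,y_c Consumer mass-specific metabolic rate and ingestion ratio.
#' @param x_p,y_p Predator counterparts.
#' @param R0,C0 Half-saturation constants of the two functional responses.
#' @param r Resource intrinsic growth rate.
#' @return A `food_chain_params` list.
#' @export
food_chain_params <- function(K, x_c = 0.4, y_c = 2.009, x_p = 0.08,
                              y_p = 2.876, R0 = 0.16129, C0 = 0.5, r = 1) {
  p <- list(K = K, x_c = x_c, y_c = y_c, x_p = x_p, y_p = y_p,
            R0 = R0, C0 = C0, r = r)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1 || v <= 0, TRUE))) {
    stop("all food-chain parameters must be positive scalars")
  }
  structure(p, class = "food_chain_params")
}

.food_chain_rhs <- function(t, y, p) {
  R <- y[1]; C <- y[2]; P <- y[3]
  list(c(
    p$r * R * (1 - R / p$K) - p$x_c * p$y_c * C * R / (R + p$R0),
    p$x_c * C * (-1 + p$y_c * R / (R + p$R0)) - p$x_p * p$y_p * P * C / (C + p$C0),
    p$x_p * P * (-1 + p$y_p * C / (C + p$C0))
  ))
}

#' Simulate the tri-trophic food chain
#'
#' Integrates the resource-consumer-predator ODE with an adaptive solver
#' ([deSolve::ode()], lsoda, rtol 1e-8 / atol 1e-10), discards the burn-in
#' transient and returns the three trajectories sampled at `output_step`.
#' Deterministic: no randomness enters here (observation noise is added
#' separately by [add_observation_noise()]).
#'
#' The default initial state (0.5, 0.3, 0.8) lies in the basin of the
#' three-species coexistence attractor for all four reference `K` values;
#' states with a large resource and small predator fall into a coexisting
#' predator-free attractor instead and must be avoided.
#'
#' @param params A [food_chain_params()].
#' @param total_time Integration end time (must exceed `burn_in`).
#' @param burn_in Initial stretch discarded as transient.
#' @param output_step Spacing of the returned samples, in model time units.
#' @param initial_state Named numeric vector `c(R=, C=, P=)`, all positive.
#' @param rtol,atol Solver tolerances.
#' @return A named list of three [regime_series()] (`R`, `C`, `P`) on the
#'   post-burn-in time grid, with the regime label `sprintf("K=%g", K)`.
#' @export
simulate_food_chain <- function(params, total_time = 4500, burn_in = 2000,
                                output_step = 1,
                                initial_state = c(R = 0.5, C = 0.3, P = 0.8),
                                rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(params, "food_chain_params"))
  if (total_time <= burn_in) stop("total_time must exceed burn_in")
  if (any(initial_state <= 0) || length(initial_state) != 3L) {
    stop("initial_state must be three positive densities")
  }
  times <- seq(0, total_time, by = output_step)
  out <- deSolve::ode(y = stats::setNames(as.numeric(initial_state), c("R", "C", "P")),
                      times = times, func = .food_chain_rhs, parms = params,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(out, "istate")[1] < 0) stop("ODE solver failed")
  out <- out[out[, "time"] > burn_in, , drop = FALSE]
  if (any(!is.finite(out))) stop("non-finite state in food-chain trajectory")
  lab <- sprintf("K=%g", params$K)
  stats::setNames(lapply(c("R", "C", "P"), function(v) {
    regime_series(out[, v], out[, "time"], regime = lab, variable = v)
  }), c("R", "C", "P"))
}

#' Subsample a series at a fixed stride
#'
#' Keeps every `every`-th observation, starting from the first. With the
#' food chain's unit output step and `every = 5`, the two-point limit cycle
#' (period about 52 time units) yields roughly 10 samples per cycle.
#'
#' @param series A [regime_series()].
#' @param every Positive integer stride.
#' @return The thinned [regime_series()].
#' @export
sample_series <- function(series, every = 5L) {
  stopifnot(inherits(series, "regime_series"))
  every <- as.integer(every)
  if (every < 1L) stop("`every` must be a positive integer")
  keep <- seq(1L, length(series$values), by = every)
  regime_series(series$values[keep], series$times[keep],
                regime = series$regime, variable = series$variable,
                standardized = FALSE)
}

#' Add multiplicative-scaled observation noise
#'
#' Adds i.i.d. Gaussian observation noise whose standard deviation is the
#' noise level `rho` times the standard deviation of the deterministic series
#' itself, so `rho` is interpretable as a fractional noise level per species.
#'
#' @param series The deterministic (sampled) [regime_series()].
#' @param rho Non-negative observation-noise level.
#' @param seed Optional integer seed; the draw is deterministic given it.
#' @param sd_reference Reference standard deviation `sigma` of the
#'   deterministic dynamics. Defaults to the sample sd of `series` (which must
#'   then be positive); pass it explicitly when the series at hand is a short
#'   window of a longer deterministic trajectory.
#' @return The noisy [regime_series()].
#' @export
add_observation_noise <- function(series, rho, seed = NULL, sd_reference = NULL) {
  stopifnot(inherits(series, "regime_series"))
  if (rho < 0) stop("rho must be non-negative")
  if (rho == 0) return(series)
  if (is.null(sd_reference)) sd_reference <- stats::sd(series$values)
  if (!is.finite(sd_reference) || sd_reference <= 0) {
    stop("zero-variance deterministic series: supply a positive `sd_reference`")
  }
  e <- .with_seed(seed, stats::rnorm(length(series$values), 0, sd_reference))
  series$values <- series$values + rho * e
  series$standardized <- FALSE
  series
}

.local_extrema <- function(v) {
  n <- length(v)
  if (n < 3L) return(list(max = integer(), min = integer()))
  core <- v[2:(n - 1L)]
  list(max = which(core > v[1:(n - 2L)] & core > v[3:n]) + 1L,
       min = which(core < v[1:(n - 2L)] & core < v[3:n]) + 1L)
}

## single-linkage clustering of sorted values: a gap larger than `gap` starts
## a new cluster; returns per-cluster ranges
.gap_clusters <- function(vals, gap) {
  v <- sort(vals)
  brk <- which(diff(v) > gap)
  start <- c(1L, brk + 1L); end <- c(brk, length(v))
  data.frame(lo = v[start], hi = v[end], n = end - start + 1L)
}

#' Classify the attractor of a deterministic food-chain series
#'
#' Labels a post-burn-in deterministic trajectory as `"equilibrium"`,
#' `"cycle_k"` or `"aperiodic"`. The series is standardized internally and its
#' local extrema (maxima and minima jointly - an n-point limit cycle visits n
#' distinct extremum levels per period) are clustered by a gap rule; a clean
#' k-level cycle shows k tight, well-separated clusters, whereas a chaotic
#' trajectory's extrema smear into broad bands.
#'
#' @param series A deterministic [regime_series()] (no observation noise).
#' @param eq_tol Absolute range below which the series counts as an
#'   equilibrium.
#' @param gap_tol Minimum gap (standardized units) separating extremum-level
#'   clusters.
#' @param spread_tol Maximum within-cluster spread (standardized units) for a
#'   level to count as repeating; wider clusters mean the extrema never
#'   settle, i.e. aperiodic dynamics.
#' @param max_levels Cluster count above which the series is called
#'   aperiodic.
#' @return A character label: `"equilibrium"`, `"cycle_2"`, `"cycle_4"`, ...
#'   or `"aperiodic"`.
#' @export
classify_food_chain_regime <- function(series, eq_tol = 1e-4, gap_tol = 0.1,
                                       spread_tol = 0.02, max_levels = 8L) {
  stopifnot(inherits(series, "regime_series"))
  v <- series$values
  if (diff(range(v)) < eq_tol) return("equilibrium")
  z <- (v - mean(v)) / stats::sd(v)
  ex <- .local_extrema(z)
  vals <- z[c(ex$max, ex$min)]
  if (length(ex$max) < 8L) {
    stop("series too short to classify: fewer than 8 local maxima")
  }
  cl <- .gap_clusters(vals, gap_tol)
  if (nrow(cl) > max_levels) return("aperiodic")
  if (any(cl$hi - cl$lo > spread_tol)) return("aperiodic")
  sprintf("cycle_%d", nrow(cl))
}

#' Estimate the limit-cycle period from peak recurrence
#'
#' Mean time between successive visits to the highest local-maximum level
#' (peaks within `gap_tol` of the largest, on the standardized scale). For a
#' limit cycle this is the full cycle period regardless of how many distinct
#' peak levels the cycle has.
#'
#' @param series A deterministic [regime_series()].
#' @param gap_tol Tolerance (standardized units) for assigning peaks to the
#'   top level.
#' @return The period in the series' time units.
#' @export
cycle_period <- function(series, gap_tol = 0.1) {
  stopifnot(inherits(series, "regime_series"))
  z <- (series$values - mean(series$values)) / stats::sd(series$values)
  pk <- .local_extrema(z)$max
  if (length(pk) < 3L) stop("too few local maxima to estimate a period")
  top <- pk[z[pk] > max(z[pk]) - gap_tol]
  if (length(top) < 2L) stop("top peak level visited fewer than twice")
  mean(diff(series$times[top]))
}
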