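#' Derive a child seed deterministically
#'
#' Folds a base seed and any number of integer coordinates (replicate index,
#' grid row, grid column, ...) into a new seed in `[1, 2^31 - 2]` with a
#' linear-congruential mix. Used so that every replicate and every landscape
#' cell draws from an independent, reproducible stream: re-running with the
#' same base seed is bit-identical, and changing any coordinate decorrelates
#' the stream.
#'
#' @param seed Integer base seed.
#' @param ... Integer coordinates.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  s <- as.double(seed) %% 2147483647
  for (v in c(...)) {
    s <- (s * 48271 + as.double(v) * 8191 + 1) %% 2147483647
  }
  as.integer(s) + 1L
}

## Reference K values of the four food-chain regimes
.fc_regime_K <- c(A = 0.78, B = 0.85, C = 0.92, D = 0.997)

## Cache of deterministic sampled food-chain pools: simulating the skeleton is
## the expensive step and it is identical across replicates and cells.
.fc_pool_cache <- new.env(parent = emptyenv())

#' Deterministic sampled pool for one food-chain regime
#'
#' Simulates the food chain for one of the reference regimes (A: K = 0.78
#' equilibrium, B: K = 0.85 two-point cycle, C: K = 0.92 four-point cycle,
#' D: K = 0.997 chaos), subsamples every fifth unit-step output point, and
#' returns the sampled deterministic trajectories together with each species'
#' standard deviation (the reference scale for observation noise) and an
#' equilibrium flag. Results are cached per regime and pool length within the
#' session.
#'
#' @param regime One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param pool_length Number of sampled points in the pool (replicate windows
#'   are drawn from it).
#' @param burn_in Transient discarded before sampling.
#' @param every Sampling stride over the unit-step output.
#' @return A list with `series` (named list of sampled deterministic
#'   [regime_series()]), `sd` (named per-species sd), `mean` (per-species
#'   mean), `equilibrium` (logical) and `regime`.
#' @export
food_chain_pool <- function(regime = c("A", "B", "C", "D"), pool_length = 500L,
                            burn_in = 5000, every = 5L) {
  regime <- match.arg(regime)
  key <- sprintf("%s_%d_%g_%d", regime, pool_length, burn_in, every)
  if (!is.null(.fc_pool_cache[[key]])) return(.fc_pool_cache[[key]])
  K <- .fc_regime_K[[regime]]
  total <- burn_in + every * (pool_length + 2L)
  traj <- simulate_food_chain(food_chain_params(K), total_time = total,
                              burn_in = burn_in, output_step = 1)
  sampled <- lapply(traj, sample_series, every = every)
  sampled <- lapply(sampled, function(s) {
    s$values <- s$values[seq_len(pool_length)]
    s$times <- s$times[seq_len(pool_length)]
    s$regime <- regime
    s
  })
  pool <- list(
    series = sampled,
    sd = vapply(sampled, function(s) stats::sd(s$values), 0),
    mean = vapply(sampled, function(s) mean(s$values), 0),
    equilibrium = diff(range(sampled$C$values)) < 1e-4,
    regime = regime
  )
  .fc_pool_cache[[key]] <- pool
  pool
}

#' Replicate factory for noisy food-chain regime series
#'
#' Returns a function of a seed that draws one replicate of the regime: a
#' fixed window of length `length` from the deterministic sampled pool, plus
#' a fresh draw of observation noise at level `rho` scaled by each species'
#' deterministic standard deviation, each species standardized. The
#' deterministic skeleton is the regime; observation noise is the replicate-
#' level stochastic element, so replicates share the window (and its sampling
#' phase) and differ only in the noise realization. For an equilibrium regime
#' the deterministic sd is (numerically) zero, so the noise scale falls back
#' to `rho` times the species' equilibrium value: after standardization the
#' replicate is i.i.d. noise around the fixed point, the stochastic
#' equilibrium, whatever the value of `rho`.
#'
#' @param regime One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param rho Observation-noise level (must be positive for the equilibrium
#'   regime, which otherwise has zero variance).
#' @param length Window length (number of sampled observations).
#' @param window_start Index of the window's first sampled point in the pool.
#' @param pool_length,burn_in Passed to [food_chain_pool()].
#' @return A function `f(seed)` returning a named list of standardized
#'   [regime_series()] (`R`, `C`, `P`).
#' @export
food_chain_replicate_factory <- function(regime, rho, length, window_start = 1L,
                                         pool_length = 500L, burn_in = 5000) {
  pool <- food_chain_pool(regime, pool_length = pool_length, burn_in = burn_in)
  n_pool <- base::length(pool$series$R$values)
  if (window_start + length - 1L > n_pool) {
    stop("window extends beyond the pool length")
  }
  if (pool$equilibrium && rho <= 0) {
    stop("the equilibrium regime needs rho > 0 (noise-free constant series cannot be tested)")
  }
  force(rho); force(length)
  idx <- window_start:(window_start + length - 1L)
  function(seed) {
    .with_seed(seed, {
      out <- lapply(names(pool$series), function(v) {
        s <- pool$series[[v]]
        sd_ref <- if (pool$equilibrium) abs(pool$mean[[v]]) else pool$sd[[v]]
        w <- regime_series(s$values[idx], seq_len(length), regime = regime,
                           variable = v)
        w$values <- w$values + rho * stats::rnorm(length, 0, sd_ref)
        standardize(w)
      })
      stats::setNames(out, names(pool$series))
    })
  }
}

#' Detection probability for one landscape cell
#'
#' Runs the directional regime test on `n_replicates` independent draws of
#' target regime `i` and library regime `j` and returns the fraction of
#' replicates that detect a dynamical difference at level `alpha`, with its
#' binomial standard error.
#'
#' @param factory_i,factory_j Functions of a seed returning one replicate of
#'   each regime (see [food_chain_replicate_factory()]).
#' @param n_replicates Number of replicate tests.
#' @param alpha Significance level.
#' @param seed Base seed; replicate seeds are derived from it.
#' @param ... Passed to [directional_regime_test()] (mode, predictor,
#'   responses, n_permutations, ...).
#' @return A list with `probability`, `detections`, `n_replicates`, `se`.
#' @export
detection_probability_cell <- function(factory_i, factory_j, n_replicates,
                                       alpha = 0.05, seed = 1L, ...) {
  det <- 0L
  for (r in seq_len(n_replicates)) {
    target <- factory_i(derive_seed(seed, r, 1L))
    library_j <- factory_j(derive_seed(seed, r, 2L))
    res <- directional_regime_test(target, library_j, alpha = alpha,
                                   seed = derive_seed(seed, r, 3L), ...)
    det <- det + as.integer(res$significant)
  }
  p <- det / n_replicates
  list(probability = p, detections = det, n_replicates = n_replicates,
       se = sqrt(p * (1 - p) / n_replicates))
}

.landscape_result <- function(probability, detections, n_replicates, lengths,
                              axis2, axis2_name, direction, mode) {
  structure(
    list(probability = probability, detections = detections,
         n_replicates = n_replicates, lengths = lengths, axis2 = axis2,
         axis2_name = axis2_name, direction = direction, mode = mode),
    class = "landscape_result"
  )
}

#' @export
print.landscape_result <- function(x, ...) {
  cat(sprintf("<landscape_result> %s | %d lengths x %d %s values | %d replicates/cell\n",
              x$direction, length(x$lengths), length(x$axis2), x$axis2_name,
              x$n_replicates))
  print(round(x$probability, 3))
  invisible(x)
}

#' @export
as.data.frame.landscape_result <- function(x, ...) {
  g <- expand.grid(length = x$lengths, axis2 = x$axis2)
  names(g)[2] <- x$axis2_name
  g$direction <- x$direction
  g$detections <- as.vector(x$detections)
  g$replicates <- x$n_replicates
  g$probability <- as.vector(x$probability)
  g$se <- sqrt(g$probability * (1 - g$probability) / g$replicates)
  g
}

#' Detection-probability landscape for a food-chain regime pair
#'
#' For every combination of series length and observation-noise level, tests
#' target regime `i` against across-library regime `j` over `n_replicates`
#' replicate draws (multivariate mode: the predator's embedding cross-maps
#' the consumer and resource) and records the detection probability. The
#' default grid is 10 lengths x 30 noise levels = 300 cells.
#'
#' @param regime_i Target regime code (`"A"`..`"D"`).
#' @param regime_j Across-library regime code.
#' @param lengths Series lengths (default 10 to 100 in steps of 10).
#' @param noise Observation-noise levels rho (default 0.01 to 0.3 in steps of
#'   0.01).
#' @param n_replicates Replicates per cell (default 100).
#' @param alpha Significance level.
#' @param base_seed Base seed; cell and replicate seeds are derived from it.
#' @param predictor,responses Variables used by the multivariate test.
#' @param n_permutations Permutations per test.
#' @param pool_length Deterministic pool size behind the replicate windows.
#' @return A `landscape_result` whose `probability` matrix is
#'   `length(lengths) x length(noise)`.
#' @export
food_chain_landscape <- function(regime_i, regime_j,
                                 lengths = seq(10L, 100L, by = 10L),
                                 noise = seq(0.01, 0.3, by = 0.01),
                                 n_replicates = 100L, alpha = 0.05,
                                 base_seed = 1L, predictor = "P",
                                 responses = c("C", "R"),
                                 n_permutations = 1000L, pool_length = 500L) {
  prob <- det <- matrix(NA_real_, length(lengths), length(noise),
                        dimnames = list(lengths, noise))
  for (il in seq_along(lengths)) {
    for (ir in seq_along(noise)) {
      fi <- food_chain_replicate_factory(regime_i, noise[ir], lengths[il],
                                         pool_length = pool_length)
      fj <- food_chain_replicate_factory(regime_j, noise[ir], lengths[il],
                                         pool_length = pool_length)
      cell <- detection_probability_cell(
        fi, fj, n_replicates = n_replicates, alpha = alpha,
        seed = derive_seed(base_seed, il, ir),
        mode = "multivariate", predictor = predictor, responses = responses,
        n_permutations = n_permutations
      )
      prob[il, ir] <- cell$probability
      det[il, ir] <- cell$detections
    }
  }
  .landscape_result(prob, det, n_replicates, lengths, noise, "rho",
                    sprintf("%s target vs %s library", regime_i, regime_j),
                    "multivariate")
}

#' Detection-probability landscapes for the stochastic bistable model
#'
#' For every combination of series length and harvest rate `c`, simulates one
#' path per basin (SS1 = overexploited lower state, SS2 = underexploited upper
#' state), standardizes each, and runs the univariate directional test in both
#' directions over `n_replicates` replicate path pairs. The default grid is
#' 11 lengths x 19 harvest rates = 209 cells. Harvest rates outside the
#' skeleton's bistable window are rejected.
#'
#' @param lengths Series lengths (default 50 to 150 in steps of 10).
#' @param harvest Harvest rates (default 1.83 to 2.73 in steps of 0.05).
#' @param n_replicates Replicates per cell (default 100).
#' @param alpha Significance level.
#' @param base_seed Base seed.
#' @param sigma,K,dt Passed to [simulate_ass()].
#' @param n_permutations Permutations per test.
#' @return A list of two `landscape_result`s: `SS1_target` (SS2 library
#'   predicts SS1) and `SS2_target`.
#' @export
ass_landscape <- function(lengths = seq(50L, 150L, by = 10L),
                          harvest = seq(1.83, 2.73, by = 0.05),
                          n_replicates = 100L, alpha = 0.05, base_seed = 1L,
                          sigma = 0.01, K = 11, dt = 0.01,
                          n_permutations = 1000L) {
  folds <- find_fold_points(K)
  bad <- harvest <= folds["lower"] | harvest >= folds["upper"]
  if (any(bad)) {
    stop(sprintf("harvest rates outside the bistable window (%.4f, %.4f): %s",
                 folds["lower"], folds["upper"],
                 paste(harvest[bad], collapse = ", ")))
  }
  dims <- list(lengths, harvest)
  p1 <- d1 <- p2 <- d2 <- matrix(NA_real_, length(lengths), length(harvest),
                                 dimnames = lapply(dims, as.character))
  for (il in seq_along(lengths)) {
    for (ic in seq_along(harvest)) {
      n <- lengths[il]; cc <- harvest[ic]
      det1 <- det2 <- 0L
      for (r in seq_len(n_replicates)) {
        s1 <- standardize(simulate_ass(cc, "lower", n, sigma = sigma, K = K,
                                       dt = dt,
                                       seed = derive_seed(base_seed, il, ic, r, 1L)))
        s2 <- standardize(simulate_ass(cc, "upper", n, sigma = sigma, K = K,
                                       dt = dt,
                                       seed = derive_seed(base_seed, il, ic, r, 2L)))
        t1 <- directional_regime_test(s1, s2, mode = "univariate", alpha = alpha,
                                      n_permutations = n_permutations,
                                      seed = derive_seed(base_seed, il, ic, r, 3L))
        t2 <- directional_regime_test(s2, s1, mode = "univariate", alpha = alpha,
                                      n_permutations = n_permutations,
                                      seed = derive_seed(base_seed, il, ic, r, 4L))
        det1 <- det1 + as.integer(t1$significant)
        det2 <- det2 + as.integer(t2$significant)
      }
      p1[il, ic] <- det1 / n_replicates; d1[il, ic] <- det1
      p2[il, ic] <- det2 / n_replicates; d2[il, ic] <- det2
    }
  }
  list(
    SS1_target = .landscape_result(p1, d1, n_replicates, lengths, harvest,
                                   "c", "SS1 target vs SS2 library", "univariate"),
    SS2_target = .landscape_result(p2, d2, n_replicates, lengths, harvest,
                                   "c", "SS2 target vs SS1 library", "univariate")
  )
}
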