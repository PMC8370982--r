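#' Drift of the harvested-population skeleton
#'
#' Deterministic skeleton of the stochastic alternative-stable-state model:
#' logistic growth minus a saturating (type III) harvesting/grazing term,
#' `f(x) = x (1 - x/K) - c x^2 / (1 + x^2)`. For intermediate harvest rates
#' `c` the skeleton is bistable: an underexploited high-biomass state and an
#' overexploited low-biomass state coexist, separated by an unstable
#' threshold, and each stable branch terminates in a fold (saddle-node)
#' bifurcation.
#'
#' @param x State (non-negative biomass).
#' @param c Harvest rate.
#' @param K Carrying capacity (default 11).
#' @return Drift value(s), vectorized over `x`.
#' @export
ass_drift <- function(x, c, K = 11) {
  x * (1 - x / K) - c * x^2 / (1 + x^2)
}

#' Equilibria of the skeleton
#'
#' All non-negative roots of the skeleton drift for a given harvest rate,
#' each tagged stable or unstable by the sign of the drift derivative.
#' Positive roots are bracketed by a dense sign-change scan and polished with
#' [stats::uniroot()] to 1e-12.
#'
#' @param c Harvest rate (non-negative).
#' @param K Carrying capacity.
#' @return A data frame with columns `x` (root) and `stable` (logical),
#'   ordered by `x`. `x = 0` is always an (unstable) equilibrium.
#' @export
skeleton_equilibria <- function(c, K = 11) {
  if (c < 0 || K <= 0) stop("need c >= 0 and K > 0")
  f <- function(x) ass_drift(x, c, K)
  xs <- seq(1e-8, K * 1.2, length.out = 4000L)
  fx <- f(xs)
  roots <- numeric()
  sgn <- which(fx[-1] * fx[-length(fx)] <= 0 & fx[-length(fx)] != 0)
  for (i in sgn) {
    roots <- c(roots, stats::uniroot(f, c(xs[i], xs[i + 1]), tol = 1e-12)$root)
  }
  roots <- unique(round(c(0, roots), 9))
  h <- 1e-6
  stable <- vapply(roots, function(r) {
    (f(r + h) - f(max(r - h, 0))) / (h + min(h, r)) < 0
  }, TRUE)
  out <- data.frame(x = roots, stable = stable)
  out[order(out$x), , drop = FALSE]
}

#' Fold (saddle-node) bifurcation points of the skeleton
#'
#' The two harvest rates at which the number of positive equilibria changes,
#' i.e. where a stable branch collides with the unstable threshold. Located
#' by bisection on the positive-equilibrium count, to `tol` in `c`. Between
#' the folds the skeleton is bistable.
#'
#' @param K Carrying capacity.
#' @param c_range Harvest-rate interval scanned for the bistable window.
#' @param tol Bisection tolerance in `c`.
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
find_fold_points <- function(K = 11, c_range = c(0.5, 5), tol = 1e-6) {
  n_pos <- function(c) {
    eq <- skeleton_equilibria(c, K)
    sum(eq$x > 1e-8)
  }
  cs <- seq(c_range[1], c_range[2], by = 0.01)
  ns <- vapply(cs, n_pos, 0L)
  bis <- which(ns == 3L)
  if (length(bis) == 0L) stop(sprintf("no bistable window for K = %g", K))
  bisect <- function(lo, hi, want_hi_bistable) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if ((n_pos(mid) == 3L) == want_hi_bistable) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  lower <- bisect(cs[max(1L, bis[1] - 1L)], cs[bis[1]], want_hi_bistable = TRUE)
  upper <- bisect(cs[bis[length(bis)]], cs[min(length(cs), bis[length(bis)] + 1L)],
                  want_hi_bistable = FALSE)
  c(lower = lower, upper = upper)
}

## stable equilibrium of the requested basin, with a clear error outside the
## bistable window
.branch_equilibrium <- function(c, K, branch) {
  eq <- skeleton_equilibria(c, K)
  st <- eq$x[eq$stable & eq$x > 1e-8]
  if (length(st) < 2L) {
    stop(sprintf("harvest rate c = %g is outside the bistable window for K = %g: the %s branch has no equilibrium",
                 c, K, branch))
  }
  if (branch == "lower") min(st) else max(st)
}

#' Simulate the stochastic alternative-stable-state model
#'
#' Euler-Maruyama integration of
#' `dx = [x (1 - x/K) - c x^2/(1 + x^2)] dt + sigma dW` at step `dt`,
#' started exactly at the noise-free skeleton equilibrium of the chosen basin
#' (`branch = "lower"` is the overexploited state SS1, `"upper"` the
#' underexploited state SS2). The noise magnitude is kept small so the path
#' fluctuates inside its basin rather than flickering across the threshold.
#' The state is floored at 1e-12 to preserve non-negativity (a no-op at the
#' default `sigma`). One sample is recorded every `record_step` time units.
#'
#' @param c Harvest rate, inside the bistable window of [find_fold_points()].
#' @param branch `"lower"` (SS1) or `"upper"` (SS2).
#' @param n_samples Number of recorded observations.
#' @param sigma Noise magnitude (default 0.01).
#' @param K Carrying capacity (default 11).
#' @param dt Integration step (default 0.01).
#' @param record_step Recording interval in time units (default 1, i.e. one
#'   sample per 100 integration steps).
#' @param seed Optional integer seed; the path is deterministic given it.
#' @return A [regime_series()] labelled `"SS1"` or `"SS2"`.
#' @export
simulate_ass <- function(c, branch = c("lower", "upper"), n_samples,
                         sigma = 0.01, K = 11, dt = 0.01, record_step = 1,
                         seed = NULL) {
  branch <- match.arg(branch)
  if (n_samples < 1L) stop("n_samples must be at least 1")
  if (sigma < 0 || dt <= 0) stop("need sigma >= 0 and dt > 0")
  steps_per_rec <- round(record_step / dt)
  if (abs(steps_per_rec * dt - record_step) > 1e-9) {
    stop("record_step must be a multiple of dt")
  }
  x0 <- .branch_equilibrium(c, K, branch)
  path <- .with_seed(seed, {
    x <- x0
    out <- numeric(n_samples)
    sq <- sigma * sqrt(dt)
    for (i in seq_len(n_samples)) {
      z <- stats::rnorm(steps_per_rec)
      for (j in seq_len(steps_per_rec)) {
        x <- x + ass_drift(x, c, K) * dt + sq * z[j]
        if (x < 1e-12) x <- 1e-12
      }
      out[i] <- x
    }
    out
  })
  regime_series(path, seq_len(n_samples) * record_step,
                regime = if (branch == "lower") "SS1" else "SS2",
                variable = "x")
}
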