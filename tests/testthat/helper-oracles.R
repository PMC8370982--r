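# Independent brute-force references for the forecasting kernel and the
# permutation test. Deliberately written with plain loops and no shared code
# with the package internals.

oracle_weights <- function(d) {
  if (d[1] == 0) {
    w <- ifelse(d == 0, 1, 0)
    return(w / sum(w))
  }
  u <- exp(-d / d[1])
  u / sum(u)
}

# delay vector anchored at index t (1-based), most recent first
oracle_vec <- function(v, t, E) v[t - 0:(E - 1)]

# One-step simplex forecast by exhaustive search. Returns predictions for
# every target anchor with a full vector and a successor observation.
oracle_simplex <- function(tv, tt, lv, lt, E, exclude_times = TRUE) {
  k <- E + 1
  lib_anchor <- seq(E, length(lv) - 1)   # anchors with a successor
  tar_anchor <- seq(E, length(tv) - 1)
  pred <- obs <- numeric(0)
  for (t in tar_anchor) {
    x <- oracle_vec(tv, t, E)
    cand <- lib_anchor
    if (exclude_times) cand <- cand[abs(lt[cand] - tt[t]) > 1e-9]
    d <- sapply(cand, function(a) sqrt(sum((x - oracle_vec(lv, a, E))^2)))
    ord <- cand[order(d, lt[cand])][1:k]
    dk <- sapply(ord, function(a) sqrt(sum((x - oracle_vec(lv, a, E))^2)))
    w <- oracle_weights(dk)
    pred <- c(pred, sum(w * lv[ord + 1]))
    obs <- c(obs, tv[t + 1])
  }
  list(pred = pred, obs = obs)
}

# Same-time cross-map forecast by exhaustive search.
oracle_cross_map <- function(txv, tyv, tt, lxv, lyv, lt, E,
                             exclude_times = TRUE) {
  k <- E + 1
  lib_anchor <- seq(E, length(lxv))
  tar_anchor <- seq(E, length(txv))
  pred <- obs <- numeric(0)
  for (t in tar_anchor) {
    x <- oracle_vec(txv, t, E)
    cand <- lib_anchor
    if (exclude_times) cand <- cand[abs(lt[cand] - tt[t]) > 1e-9]
    d <- sapply(cand, function(a) sqrt(sum((x - oracle_vec(lxv, a, E))^2)))
    ord <- cand[order(d, lt[cand])][1:k]
    dk <- sapply(ord, function(a) sqrt(sum((x - oracle_vec(lxv, a, E))^2)))
    w <- oracle_weights(dk)
    pred <- c(pred, sum(w * lyv[ord]))
    obs <- c(obs, tyv[t])
  }
  list(pred = pred, obs = obs)
}

# Exact permutation p-value by complete enumeration of group assignments
# (one-sided, alternative mean(across) > mean(within)); no add-one smoothing,
# the full assignment set includes the observed one.
oracle_perm_p <- function(a, w) {
  pool <- c(a, w)
  n <- length(pool)
  na <- length(a)
  d_obs <- mean(a) - mean(w)
  sets <- utils::combn(n, na)
  d_all <- apply(sets, 2, function(ix) mean(pool[ix]) - mean(pool[-ix]))
  mean(d_all >= d_obs - 1e-12)
}

# Equilibria of the harvesting skeleton by dense sign-change scan.
oracle_equilibria <- function(cc, K = 11, n_grid = 200000) {
  f <- function(x) x * (1 - x / K) - cc * x^2 / (1 + x^2)
  xs <- seq(1e-7, K * 1.2, length.out = n_grid)
  fx <- f(xs)
  i <- which(fx[-1] * fx[-n_grid] <= 0)
  (xs[i] + xs[i + 1]) / 2
}

# Small convenience: standardized regime_series from a numeric vector.
make_std <- function(v, regime = "A", variable = "Y", times = seq_along(v)) {
  standardize(regime_series(v, times, regime = regime, variable = variable))
}
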