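#' Delay-embed a series
#'
#' Builds the library of E-dimensional delay vectors (lag 1) from a series:
#' the vector anchored at time index `t` is `<y(t), y(t-1), ..., y(t-(E-1))>`.
#' For a length-n series there are exactly `n - E + 1` vectors.
#'
#' @param series A [regime_series()] or numeric vector.
#' @param E Embedding dimension (positive integer, at most the series length).
#' @return A numeric matrix with `n - E + 1` rows (one delay vector each, most
#'   recent coordinate first) and an `anchor` attribute giving the 1-based
#'   index of each vector's anchor observation.
#' @export
#' @examples
#' embed_series(c(1, 2, 3, 4), E = 2)
embed_series <- function(series, E) {
  v <- if (inherits(series, "regime_series")) series$values else as.numeric(series)
  E <- as.integer(E)
  if (E < 1L) stop("E must be a positive integer")
  n <- length(v)
  if (E > n) stop(sprintf("insufficient data: E = %d exceeds series length %d", E, n))
  if (anyNA(v)) stop("cannot embed a series with missing values")
  m <- stats::embed(v, E)              # row i = <v[E+i-1], ..., v[i]>
  attr(m, "anchor") <- E:n
  m
}

#' Exponential simplex neighbour weights
#'
#' Converts the non-decreasing distances of the E+1 nearest neighbours into
#' simplex-projection weights `w_m = u_m / sum(u)` with
#' `u_m = exp(-d_m / d_1)`, where `d_1` is the distance to the nearest
#' neighbour. If the nearest distance is zero the exponential kernel is
#' undefined; its continuity limit is used: all zero-distance neighbours share
#' the weight equally and positive-distance neighbours get weight 0.
#'
#' @param distances Non-negative, non-decreasing numeric vector.
#' @return Weights of the same length, non-negative, summing to 1.
#' @export
#' @examples
#' neighbor_weights(c(1, 2, 3))
#' neighbor_weights(c(0, 0, 5))
neighbor_weights <- function(distances) {
  d <- as.numeric(distances)
  if (length(d) == 0L) stop("empty distance vector")
  if (any(d < 0) || is.unsorted(d)) {
    stop("distances must be non-negative and sorted ascending")
  }
  if (d[1] == 0) {
    w <- as.numeric(d == 0)
    return(w / sum(w))
  }
  u <- exp(-d / d[1])
  u / sum(u)
}

## Nearest-neighbour simplex kernel shared by the univariate and cross-map
## forecasts. `targets` and `library` are embedding matrices of equal column
## count; `lib_values` holds the value mapped to each library vector (the
## successor observation for simplex projection, the contemporaneous response
## for cross-mapping). Exclusion is by anchor TIME: when `exclude_times` is
## TRUE, library vectors anchored at the target vector's own time are dropped
## from its neighbour search. For a within-regime forecast this is exactly
## leave-one-out self-exclusion; for an across-regime forecast on a shared
## time grid it symmetrically removes the contemporaneous vector, so that
## under a true null (two series of the same process on one grid) within and
## across neighbour pools are exchangeable. Ties at the (E+1)-th neighbour are
## broken by smaller library anchor time so results are deterministic.
.simplex_kernel <- function(targets, target_times, library, lib_times,
                            lib_values, k, exclude_times = FALSE) {
  nt <- nrow(targets); nl <- nrow(library)
  if (nl < k + exclude_times) {
    stop(sprintf("library has %d eligible vectors but %d neighbours are required",
                 nl, k))
  }
  E <- ncol(library)
  pred <- numeric(nt)
  for (i in seq_len(nt)) {
    # direct (x - y)^2 sums: numerically exact ties stay ties, so the
    # anchor-time tie-break is deterministic
    di <- sqrt(rowSums((library - matrix(targets[i, ], nl, E, byrow = TRUE))^2))
    idx <- seq_len(nl)
    if (exclude_times) {
      idx <- which(abs(lib_times - target_times[i]) > 1e-9)
    }
    if (length(idx) < k) {
      stop(sprintf("fewer than %d eligible neighbours after self-exclusion", k))
    }
    ord <- idx[order(di[idx], lib_times[idx])][seq_len(k)]
    w <- neighbor_weights(di[ord])
    pred[i] <- sum(w * lib_values[ord])
  }
  pred
}

.forecast_result <- function(target_times, observed, predicted,
                             library_regime, target_regime, mode, E_used) {
  structure(
    list(target_times = target_times, observed = observed, predicted = predicted,
         library_regime = library_regime, target_regime = target_regime,
         mode = mode, E_used = E_used),
    class = "forecast_result"
  )
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> %s | target %s from library %s | E = %d | n = %d\n",
              x$mode, x$target_regime, x$library_regime, x$E_used,
              length(x$observed)))
  cat(sprintf("  mean |error| = %.4g\n", mean(abs(x$predicted - x$observed))))
  invisible(x)
}

#' Reconstruct an attractor and select its embedding dimension
#'
#' For each candidate dimension `E` in `1:E_max`, makes one-step-ahead
#' leave-one-out simplex forecasts of the series from its own library (the
#' delay vector anchored at the predicted time is excluded from the neighbour
#' search) and scores the Pearson correlation between observations and
#' predictions. The attractor reconstruction at the skill-maximising `E` is
#' returned; ties go to the smallest `E`.
#'
#' @param series A [regime_series()], ideally standardized.
#' @param E_max Largest embedding dimension searched. Default
#'   `min(10, floor(n/2) - 1)`: 10 is the conventional ceiling and the cap
#'   keeps enough library vectors at every candidate `E`.
#' @return An object of class `reconstructed_attractor`: the source series,
#'   the selected `E`, the cross-validated skill `cv_skill` at that `E`, and
#'   the full `skill` profile over candidate dimensions.
#' @export
select_embedding_dimension <- function(series, E_max = NULL) {
  stopifnot(inherits(series, "regime_series"))
  n <- length(series$values)
  if (is.null(E_max)) E_max <- min(10L, floor(n / 2) - 1L)
  E_max <- as.integer(E_max)
  if (E_max < 1L || n < E_max + 2L) {
    stop(sprintf("regime %s: series of length %d is too short for embedding",
                 series$regime, n))
  }
  skill <- rep(NA_real_, E_max)
  for (E in seq_len(E_max)) {
    att <- structure(list(series = series, E = E, cv_skill = NA_real_),
                     class = "reconstructed_attractor")
    fc <- tryCatch(simplex_forecast(series, att, self_exclusion = TRUE),
                   error = function(e) NULL)
    if (is.null(fc)) next
    if (stats::sd(fc$predicted) > 0 && stats::sd(fc$observed) > 0) {
      skill[E] <- stats::cor(fc$observed, fc$predicted)
    }
  }
  if (all(is.na(skill))) {
    stop(sprintf("regime %s, variable %s: degenerate predictions at every E; cannot select an embedding dimension",
                 series$regime, series$variable))
  }
  # smallest E within numerical tolerance of the best skill: a 1-ulp
  # difference between candidate dimensions is a tie, not a winner
  E_best <- which(skill >= max(skill, na.rm = TRUE) - 1e-9)[1]
  structure(
    list(series = series, E = as.integer(E_best), cv_skill = skill[E_best],
         skill = skill),
    class = "reconstructed_attractor"
  )
}

#' @export
print.reconstructed_attractor <- function(x, ...) {
  cat(sprintf("<reconstructed_attractor> regime %s, variable %s | E = %d | cv skill = %.3f\n",
              x$series$regime, x$series$variable, x$E, x$cv_skill))
  invisible(x)
}

#' One-step simplex projection forecast
#'
#' Forecasts a target series one step ahead from a library attractor. Every
#' target delay vector (built with the library's embedding dimension `E`) is
#' matched to its `E + 1` nearest library vectors by Euclidean distance, and
#' the forecast is the exponentially distance-weighted average of the library
#' neighbours' successor observations. Within-regime forecasts (library and
#' target are the same series) must exclude the self vector, otherwise the
#' zero-distance self-match reproduces the observation and the test is
#' meaningless.
#'
#' @param target A [regime_series()] to be predicted.
#' @param library_attractor A [select_embedding_dimension()] reconstruction
#'   providing the library series and its `E`.
#' @param self_exclusion Logical; drop library vectors anchored at the target
#'   vector's own time from its neighbour search. When target and library are
#'   the same series this is leave-one-out self-exclusion; when they are
#'   different series sharing a time grid it removes the contemporaneous
#'   vector, keeping within- and across-library neighbour pools comparable.
#'   Libraries on disjoint time ranges are unaffected.
#' @return A `forecast_result` pairing observed and predicted values at the
#'   forecast times.
#' @export
simplex_forecast <- function(target, library_attractor, self_exclusion = TRUE) {
  stopifnot(inherits(target, "regime_series"),
            inherits(library_attractor, "reconstructed_attractor"))
  lib <- library_attractor$series
  E <- library_attractor$E
  yl <- lib$values; yt <- target$values
  if (length(yt) < E + 1L) {
    stop(sprintf("target regime %s too short for E = %d", target$regime, E))
  }
  lib_m <- embed_series(yl, E)
  lib_anchor <- attr(lib_m, "anchor")
  has_succ <- lib_anchor < length(yl)    # successor observation must exist
  lib_m <- lib_m[has_succ, , drop = FALSE]
  lib_anchor <- lib_anchor[has_succ]
  if (length(lib_anchor) < E + 2L) {
    stop(sprintf("library regime %s has too few vectors with successors for E = %d",
                 lib$regime, E))
  }
  tar_m <- embed_series(yt, E)
  tar_anchor <- attr(tar_m, "anchor")
  ok <- tar_anchor < length(yt)          # need the true value at t+1
  tar_m <- tar_m[ok, , drop = FALSE]
  tar_anchor <- tar_anchor[ok]
  pred <- .simplex_kernel(tar_m, target$times[tar_anchor],
                          lib_m, lib$times[lib_anchor],
                          yl[lib_anchor + 1L], k = E + 1L,
                          exclude_times = isTRUE(self_exclusion))
  .forecast_result(target$times[tar_anchor + 1L], yt[tar_anchor + 1L], pred,
                   lib$regime, target$regime, "univariate", E)
}

#' Cross-map forecast of one variable from another's embedding
#'
#' Predicts a response variable `Y` at time `t` from the delay embedding of a
#' predictor variable `X`: the target's `X` vector is matched to its `E + 1`
#' nearest neighbours among the library regime's `X` vectors, and the forecast
#' is the weighted average of the library's contemporaneous `Y` values at the
#' neighbour times (no one-step shift). When the two variables share an
#' attractor this mapping succeeds; when the library comes from a different
#' attractor it fails, which is what the regime test exploits.
#'
#' @param target_x,target_y Aligned [regime_series()] of the predictor and
#'   response in the target regime.
#' @param library_attractor Reconstruction of the library regime's predictor
#'   variable (its `E` is used for both library and target vectors).
#' @param library_y The library regime's response series, aligned with the
#'   library predictor.
#' @param self_exclusion Logical; exclude library vectors anchored at the
#'   predicted time (see [simplex_forecast()] for the time-based rule).
#' @return A `forecast_result` with `mode = "multivariate"`.
#' @export
cross_map_forecast <- function(target_x, target_y, library_attractor, library_y,
                               self_exclusion = TRUE) {
  stopifnot(inherits(target_x, "regime_series"),
            inherits(target_y, "regime_series"),
            inherits(library_attractor, "reconstructed_attractor"),
            inherits(library_y, "regime_series"))
  lib_x <- library_attractor$series
  E <- library_attractor$E
  if (length(target_x$values) != length(target_y$values)) {
    stop("target predictor and response series must be aligned")
  }
  if (length(lib_x$values) != length(library_y$values)) {
    stop("library predictor and response series must be aligned")
  }
  lib_m <- embed_series(lib_x$values, E)
  lib_anchor <- attr(lib_m, "anchor")
  tar_m <- embed_series(target_x$values, E)
  tar_anchor <- attr(tar_m, "anchor")
  pred <- .simplex_kernel(tar_m, target_x$times[tar_anchor],
                          lib_m, lib_x$times[lib_anchor],
                          library_y$values[lib_anchor], k = E + 1L,
                          exclude_times = isTRUE(self_exclusion))
  .forecast_result(target_y$times[tar_anchor], target_y$values[tar_anchor], pred,
                   lib_x$regime, target_y$regime, "multivariate", E)
}
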