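#' Construct a regime series
#'
#' A `regime_series` holds the observations of one variable within one labelled
#' dynamical regime: a numeric vector of values on a strictly increasing,
#' evenly spaced time index. It is the basic currency passed between the
#' embedding, forecasting and testing functions.
#'
#' @param values Numeric vector of observations. `NA` marks a missing value
#'   (see [impute_missing()]); all non-missing entries must be finite.
#' @param times Numeric vector of observation times, strictly increasing and
#'   evenly spaced (constant spacing to within a relative tolerance of 1e-9).
#'   Defaults to `seq_along(values)`.
#' @param regime Character label of the dynamical regime the segment belongs to.
#' @param variable Character name of the observed variable.
#' @param standardized Logical; `TRUE` asserts the values have mean 0 and
#'   sample standard deviation 1 (checked to 1e-9).
#'
#' @return An object of class `regime_series`: a list with elements `values`,
#'   `times`, `regime`, `variable` and `standardized`.
#' @seealso [standardize()], [split_at_breakpoint()], [embed_series()]
#' @export
#' @examples
#' s <- regime_series(sin(1:40), regime = "pre", variable = "chl")
#' standardize(s)
regime_series <- function(values, times = seq_along(values), regime = "A",
                          variable = "Y", standardized = FALSE) {
  values <- as.numeric(values)
  times <- as.numeric(times)
  if (length(values) < 1L) stop("a regime series needs at least one observation")
  if (length(values) != length(times)) {
    stop("`values` and `times` must have the same length")
  }
  if (anyNA(times) || any(!is.finite(times))) stop("`times` must be finite")
  if (any(!is.finite(values[!is.na(values)]))) {
    stop("non-missing `values` must be finite")
  }
  if (length(times) > 1L) {
    dt <- diff(times)
    if (any(dt <= 0)) stop("`times` must be strictly increasing")
    if (max(dt) - min(dt) > 1e-9 * max(abs(dt))) {
      stop("`times` must be evenly spaced")
    }
  }
  if (isTRUE(standardized)) {
    if (abs(mean(values)) >= 1e-9 || abs(stats::sd(values) - 1) >= 1e-9) {
      stop("`standardized = TRUE` but values do not have mean 0 and sd 1")
    }
  }
  structure(
    list(values = values, times = times, regime = as.character(regime)[1],
         variable = as.character(variable)[1], standardized = isTRUE(standardized)),
    class = "regime_series"
  )
}

#' @export
print.regime_series <- function(x, ...) {
  cat(sprintf("<regime_series> %s | regime %s | n = %d%s\n",
              x$variable, x$regime, length(x$values),
              if (x$standardized) " | standardized" else ""))
  cat(sprintf("  time %g .. %g (step %g)\n", x$times[1],
              x$times[length(x$times)],
              if (length(x$times) > 1) x$times[2] - x$times[1] else NA))
  invisible(x)
}

#' @export
length.regime_series <- function(x) length(x$values)

#' Standardize a regime series to mean 0, sd 1
#'
#' Centres and scales the values using the sample (n-1 denominator) standard
#' deviation. Every series is standardized before regime testing so that
#' prediction errors from different regimes and variables are on a common
#' scale; standardization is idempotent and removes any affine measurement
#' scale.
#'
#' @param series A [regime_series()]. Must contain at least two observations,
#'   no missing values, and have positive variance: a constant series carries
#'   no dynamical information and cannot be embedded or tested.
#' @return The same series with standardized values and the `standardized`
#'   flag set.
#' @export
standardize <- function(series) {
  stopifnot(inherits(series, "regime_series"))
  v <- series$values
  if (anyNA(v)) stop("cannot standardize a series with missing values; impute first")
  if (length(v) < 2L) stop("need at least two observations to standardize")
  s <- stats::sd(v)
  if (!is.finite(s) || s <= 0) {
    stop(sprintf("regime %s, variable %s: zero-variance series cannot be standardized",
                 series$regime, series$variable))
  }
  series$values <- (v - mean(v)) / s
  series$standardized <- TRUE
  series
}

#' Pair two regimes for testing
#'
#' Bundles the two dynamical regimes under comparison. Each side is either a
#' single [regime_series()] (univariate data) or a named list of aligned
#' `regime_series` (multivariate data); the two sides must carry the same
#' variable names and sampling interval.
#'
#' @param regime_a,regime_b A `regime_series` or named list of `regime_series`.
#' @return An object of class `regime_pair` with elements `regime_a`,
#'   `regime_b`.
#' @export
regime_pair <- function(regime_a, regime_b) {
  norm <- function(x, side) {
    if (inherits(x, "regime_series")) x <- stats::setNames(list(x), x$variable)
    if (!is.list(x) || !all(vapply(x, inherits, TRUE, "regime_series"))) {
      stop(side, " must be a regime_series or a named list of regime_series")
    }
    names(x) <- vapply(x, function(s) s$variable, "")
    x
  }
  a <- norm(regime_a, "regime_a")
  b <- norm(regime_b, "regime_b")
  if (!identical(sort(names(a)), sort(names(b)))) {
    stop("the two regimes must share variable names")
  }
  step <- function(x) if (length(x[[1]]$times) > 1) diff(x[[1]]$times[1:2]) else NA_real_
  sa <- step(a); sb <- step(b)
  if (is.finite(sa) && is.finite(sb) && abs(sa - sb) > 1e-9 * max(abs(sa), 1)) {
    stop("the two regimes must share the sampling interval")
  }
  structure(list(regime_a = a[sort(names(a))], regime_b = b[sort(names(b))]),
            class = "regime_pair")
}

#' Split a series into two regimes at a breakpoint
#'
#' Cuts one time series at a pre-chosen breakpoint (from breakpoint analysis or
#' biological knowledge) into a pre-segment (`time <= breakpoint`) and a
#' post-segment, and standardizes each segment independently, ready for
#' [full_regime_test()].
#'
#' @param series A [regime_series()], or a named list of aligned
#'   `regime_series` for multivariate data.
#' @param breakpoint_time Time value strictly inside the observed range.
#' @param labels Character vector of length 2 with the regime labels for the
#'   two segments.
#' @param min_length Minimum admissible segment length (a segment must at
#'   least support an E = 1 embedding with a one-step forecast).
#' @return A [regime_pair()] of independently standardized segments.
#' @export
split_at_breakpoint <- function(series, breakpoint_time,
                                labels = c("pre", "post"), min_length = 4L) {
  if (is.list(series) && !inherits(series, "regime_series")) {
    parts <- lapply(series, split_at_breakpoint, breakpoint_time = breakpoint_time,
                    labels = labels, min_length = min_length)
    return(regime_pair(lapply(parts, function(p) p$regime_a[[1]]),
                       lapply(parts, function(p) p$regime_b[[1]])))
  }
  stopifnot(inherits(series, "regime_series"))
  tt <- series$times
  if (breakpoint_time < tt[1] || breakpoint_time >= tt[length(tt)]) {
    stop("breakpoint must lie strictly inside the observed time range")
  }
  in_a <- tt <= breakpoint_time
  if (sum(in_a) < min_length || sum(!in_a) < min_length) {
    stop(sprintf("each segment needs at least %d observations", min_length))
  }
  seg <- function(keep, lab) {
    standardize(regime_series(series$values[keep], tt[keep], regime = lab,
                              variable = series$variable))
  }
  regime_pair(seg(in_a, labels[1]), seg(!in_a, labels[2]))
}

#' Impute missing values with a local-level Kalman smoother
#'
#' Replaces `NA` entries by the smoothed mean of a linear-Gaussian local-level
#' (random walk plus observation noise) state-space model whose two variances
#' are estimated by maximum likelihood on the observed entries
#' ([stats::StructTS()] followed by [stats::tsSmooth()]). Observed entries are
#' returned unchanged. This is the minimal structural model for smoothing an
#' irregularly gapped abundance series prior to embedding.
#'
#' @param x Numeric vector with `NA` marking missing values, or a
#'   [regime_series()].
#' @return Object of the same type with missing entries filled in.
#' @export
impute_missing <- function(x) {
  if (inherits(x, "regime_series")) {
    x$values <- impute_missing(x$values)
    return(x)
  }
  x <- as.numeric(x)
  obs <- !is.na(x)
  if (!any(obs)) stop("all values are missing")
  if (any(!is.finite(x[obs]))) stop("observed values must be finite")
  if (!anyNA(x)) return(x)
  if (sum(obs) < 10L) stop("need at least 10 observed values to fit the smoother")
  if (stats::sd(x[obs]) == 0) {          # degenerate limit: flat series
    x[!obs] <- x[obs][1]
    return(x)
  }
  sm <- tryCatch({
    fit <- stats::StructTS(stats::ts(x), type = "level")
    as.numeric(stats::tsSmooth(fit)[, 1])
  }, error = function(e) NULL)
  if (is.null(sm) || any(!is.finite(sm[!obs]))) {
    # ML fit can fail on near-degenerate series; fall back to linear
    # interpolation (the smoother's limit as observation noise -> 0)
    warning("local-level fit failed; falling back to linear interpolation")
    sm <- stats::approx(which(obs), x[obs], xout = seq_along(x), rule = 2)$y
  }
  x[!obs] <- sm[!obs]
  x
}
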