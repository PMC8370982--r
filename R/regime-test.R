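#' Absolute prediction errors of a forecast
#'
#' Turns a [simplex_forecast()] or [cross_map_forecast()] result into the set
#' of elementwise absolute prediction errors, labelled "within" when the
#' library and target regimes coincide and "across" otherwise.
#'
#' @param forecast A `forecast_result`.
#' @return An object of class `prediction_error_set` with fields `errors`,
#'   `direction`, `target_regime`, `library_regime`.
#' @export
absolute_errors <- function(forecast) {
  stopifnot(inherits(forecast, "forecast_result"))
  if (length(forecast$observed) == 0L) stop("empty forecast")
  structure(
    list(errors = abs(forecast$predicted - forecast$observed),
         direction = if (identical(forecast$target_regime,
                                   forecast$library_regime)) "within" else "across",
         target_regime = forecast$target_regime,
         library_regime = forecast$library_regime),
    class = "prediction_error_set"
  )
}

#' Mean absolute prediction error
#'
#' The arithmetic mean of a set of absolute prediction errors. The mean
#' absolute error (rather than a squared-error statistic) is used throughout
#' because simplex prediction errors are strongly skewed.
#'
#' @param errors A `prediction_error_set` or non-empty numeric vector.
#' @return A single number.
#' @export
mape <- function(errors) {
  e <- if (inherits(errors, "prediction_error_set")) errors$errors else as.numeric(errors)
  if (length(e) == 0L) stop("empty error set")
  mean(e)
}

## Restore the caller's RNG state on exit so seeded internals do not clobber
## an outer random sequence.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' One-sided permutation test on prediction-error means
#'
#' Tests whether across-regime mean absolute prediction error exceeds the
#' within-regime mean. The observed statistic is
#' `D = mean(across) - mean(within)`; the null distribution pools all errors
#' and randomly reassigns them to two groups of the original sizes. The
#' one-sided p-value uses add-one smoothing,
#' `p = (1 + #\{D_perm >= D_obs\}) / (1 + n_permutations)`, so it is bounded
#' below by `1/(n_permutations + 1)`; at `alpha = 0.05` with 1000 permutations
#' this is the usual "observed difference beyond the 95th percentile of the
#' permuted differences" rule.
#'
#' @param across,within `prediction_error_set`s or numeric error vectors.
#' @param n_permutations Number of random reassignments (default 1000).
#' @param seed Optional integer seed; given the seed the test is
#'   deterministic.
#' @return A list with `p_value`, `observed_difference`, group sizes,
#'   `n_permutations` and `seed`.
#' @export
permutation_test <- function(across, within, n_permutations = 1000L, seed = NULL) {
  a <- if (inherits(across, "prediction_error_set")) across$errors else as.numeric(across)
  w <- if (inherits(within, "prediction_error_set")) within$errors else as.numeric(within)
  if (length(a) == 0L || length(w) == 0L) stop("both error sets must be non-empty")
  if (any(!is.finite(c(a, w))) || any(c(a, w) < 0)) {
    stop("errors must be finite and non-negative")
  }
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop("n_permutations must be at least 1")
  d_obs <- mean(a) - mean(w)
  pool <- c(a, w)
  n <- length(pool); na <- length(a)
  if (diff(range(pool)) == 0) {
    warning("all pooled errors are identical; permutation null is degenerate")
    return(list(p_value = 1, observed_difference = d_obs,
                n_across = na, n_within = length(w),
                n_permutations = n_permutations, seed = seed))
  }
  d_perm <- .with_seed(seed, {
    tot <- sum(pool)
    vapply(seq_len(n_permutations), function(b) {
      sa <- sum(pool[sample.int(n, na)])
      sa / na - (tot - sa) / (n - na)
    }, 0)
  })
  # permuted statistics equal to the observed one count as >=; the tolerance
  # scales with the pooled error range so ties survive round-off and the
  # p-value stays invariant under rescaling of the errors
  tie_tol <- 1e-9 * diff(range(pool))
  p <- (1 + sum(d_perm >= d_obs - tie_tol)) / (1 + n_permutations)
  list(p_value = p, observed_difference = d_obs,
       n_across = na, n_within = length(w),
       n_permutations = n_permutations, seed = seed)
}

.standardize_if_needed <- function(s, do) {
  if (do && !isTRUE(s$standardized)) standardize(s) else s
}

.as_varlist <- function(x, what) {
  if (inherits(x, "regime_series")) return(stats::setNames(list(x), x$variable))
  if (!is.list(x) || !all(vapply(x, inherits, TRUE, "regime_series"))) {
    stop(what, " must be a regime_series or a named list of regime_series")
  }
  stats::setNames(x, vapply(x, function(s) s$variable, ""))
}

#' Directional test for a dynamical difference between two regimes
#'
#' The core test, run in one direction: regime `i` (the target) is forecast
#' both from its own reconstructed attractor (within) and from the contrasting
#' regime `j`'s attractor (across), and the difference in mean absolute
#' prediction error is assessed with [permutation_test()]. A significant
#' result means regime `i`'s dynamics are predicted significantly worse by
#' regime `j`'s attractor than by its own, i.e. the two segments behave as
#' different attractors (as seen from regime `i`).
#'
#' In univariate mode each regime's own series provides both the library and
#' the forecast target (within-regime forecasts exclude the self vector). In
#' multivariate mode the `predictor` variable's embedding is used to cross-map
#' every `response` variable; errors are pooled over responses.
#'
#' @param target Regime `i`: a [regime_series()], or a named list of them in
#'   multivariate mode.
#' @param across_library Regime `j`, same shape as `target`.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param predictor,responses Variable names used in multivariate mode;
#'   `responses` defaults to all non-predictor variables.
#' @param E_max Embedding-dimension search cap, see
#'   [select_embedding_dimension()].
#' @param n_permutations,alpha Permutation count and significance level.
#' @param seed Optional integer seed for the permutation draw.
#' @param standardize_series Standardize inputs first (default TRUE; every
#'   series must be on the mean-0, sd-1 scale before testing).
#' @return An object of class `regime_test_result` with the within/across
#'   MAPEs, the permutation p-value, sample sizes, the embedding dimensions of
#'   both attractors, and the configuration used.
#' @export
directional_regime_test <- function(target, across_library,
                                    mode = c("univariate", "multivariate"),
                                    predictor = NULL, responses = NULL,
                                    E_max = NULL, n_permutations = 1000L,
                                    alpha = 0.05, seed = NULL,
                                    standardize_series = TRUE) {
  mode <- match.arg(mode)
  if (mode == "univariate") {
    ti <- .standardize_if_needed(target, standardize_series)
    lj <- .standardize_if_needed(across_library, standardize_series)
    stopifnot(inherits(ti, "regime_series"), inherits(lj, "regime_series"))
    Mi <- select_embedding_dimension(ti, E_max)
    Mj <- select_embedding_dimension(lj, E_max)
    err_w <- absolute_errors(simplex_forecast(ti, Mi, self_exclusion = TRUE))
    err_a <- absolute_errors(simplex_forecast(ti, Mj, self_exclusion = TRUE))
  } else {
    ti <- lapply(.as_varlist(target, "target"),
                 .standardize_if_needed, do = standardize_series)
    lj <- lapply(.as_varlist(across_library, "across_library"),
                 .standardize_if_needed, do = standardize_series)
    if (is.null(predictor)) stop("multivariate mode needs a `predictor` variable name")
    if (!predictor %in% names(ti) || !predictor %in% names(lj)) {
      stop(sprintf("predictor variable '%s' missing from a regime", predictor))
    }
    if (is.null(responses)) responses <- setdiff(names(ti), predictor)
    if (length(responses) == 0L || !all(responses %in% names(ti)) ||
        !all(responses %in% names(lj))) {
      stop("response variables missing from a regime")
    }
    Mi <- select_embedding_dimension(ti[[predictor]], E_max)
    Mj <- select_embedding_dimension(lj[[predictor]], E_max)
    fc_one <- function(M, lib_vars) {
      lapply(responses, function(r) {
        cross_map_forecast(ti[[predictor]], ti[[r]], M, lib_vars[[r]],
                           self_exclusion = TRUE)
      })
    }
    pool_err <- function(fcs) unlist(lapply(fcs, function(f) absolute_errors(f)$errors))
    within_fc <- fc_one(Mi, ti)
    across_fc <- fc_one(Mj, lj)
    err_w <- structure(list(errors = pool_err(within_fc), direction = "within",
                            target_regime = Mi$series$regime,
                            library_regime = Mi$series$regime),
                       class = "prediction_error_set")
    err_a <- structure(list(errors = pool_err(across_fc), direction = "across",
                            target_regime = Mi$series$regime,
                            library_regime = Mj$series$regime),
                       class = "prediction_error_set")
  }
  pt <- permutation_test(err_a, err_w, n_permutations = n_permutations, seed = seed)
  structure(
    list(target_regime = err_a$target_regime,
         library_regime = err_a$library_regime,
         mape_within = mape(err_w), mape_across = mape(err_a),
         observed_difference = pt$observed_difference,
         p_value = pt$p_value,
         significant = pt$p_value <= alpha,
         alpha = alpha,
         n_within = length(err_w$errors), n_across = length(err_a$errors),
         n_permutations = pt$n_permutations, seed = seed,
         mode = mode, E_within = Mi$E, E_across = Mj$E,
         cv_skill_within = Mi$cv_skill, cv_skill_across = Mj$cv_skill),
    class = "regime_test_result"
  )
}

#' @export
print.regime_test_result <- function(x, ...) {
  cat(sprintf("<regime_test_result> target %s | across library %s | %s mode\n",
              x$target_regime, x$library_regime, x$mode))
  cat(sprintf("  MAPE within = %.4g (n = %d, E = %d) | MAPE across = %.4g (n = %d, E = %d)\n",
              x$mape_within, x$n_within, x$E_within,
              x$mape_across, x$n_across, x$E_across))
  cat(sprintf("  D = MAPE_across - MAPE_within = %.4g | p = %.4g (%d permutations)%s\n",
              x$observed_difference, x$p_value, x$n_permutations,
              if (x$significant) sprintf("  *significant at alpha = %g*", x$alpha) else ""))
  invisible(x)
}

#' Two-directional regime test
#'
#' Runs [directional_regime_test()] with each regime of a pair as the target,
#' the usual way the test is reported: a regime pair can be dynamically
#' different as seen from one side only (e.g. a cyclic regime is badly
#' predicted by a stochastic-equilibrium library, while noise is equally badly
#' predicted from anywhere).
#'
#' @param pair A [regime_pair()], e.g. from [split_at_breakpoint()].
#' @param ... Passed on to [directional_regime_test()].
#' @return An object of class `regime_test_pair`: a list of two
#'   `regime_test_result`s named by target regime.
#' @export
full_regime_test <- function(pair, ...) {
  stopifnot(inherits(pair, "regime_pair"))
  unwrap <- function(x) if (length(x) == 1L) x[[1]] else x
  a <- unwrap(pair$regime_a); b <- unwrap(pair$regime_b)
  res <- list(directional_regime_test(a, b, ...),
              directional_regime_test(b, a, ...))
  names(res) <- vapply(res, `[[`, "", "target_regime")
  structure(res, class = "regime_test_pair")
}

#' @export
print.regime_test_pair <- function(x, ...) {
  for (r in x) print(r)
  invisible(x)
}
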