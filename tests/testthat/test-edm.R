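test_that("delay embedding lays out lagged coordinates most-recent-first", {
  m <- embed_series(c(1, 2, 3, 4), E = 2)
  expect_equal(nrow(m), 3)
  expect_equal(attr(m, "anchor"), 2:4)
  expect_equal(m[1, ], c(2, 1))
  expect_equal(m[3, ], c(4, 3))

  m1 <- embed_series(c(5, 6, 7), E = 1)
  expect_equal(as.vector(m1), c(5, 6, 7))

  expect_error(embed_series(1:4, E = 5), "insufficient")
  expect_error(embed_series(1:4, E = 0), "positive")
})

test_that("neighbour weights follow the exponential kernel with the zero-distance limit", {
  expect_equal(neighbor_weights(rep(2.5, 4)), rep(0.25, 4))
  # hand computation: u = exp(-1), exp(-2), exp(-3)
  expect_equal(neighbor_weights(c(1, 2, 3)),
               c(0.66524, 0.24473, 0.09003), tolerance = 1e-4)
  expect_equal(neighbor_weights(c(0, 0, 5)), c(0.5, 0.5, 0))
  expect_error(neighbor_weights(numeric(0)), "empty")
  expect_error(neighbor_weights(c(2, 1)), "sorted")

  set.seed(7)
  for (i in 1:20) {
    d <- sort(runif(sample(2:8, 1), 0, 5))
    w <- neighbor_weights(d)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(diff(w) <= 1e-15))        # non-increasing in distance
    expect_true(all(w >= 0))
  }
})

test_that("embedding-dimension selection finds perfect skill on a period-2 cycle", {
  s <- make_std(rep(c(1, -1), 15))
  att <- select_embedding_dimension(s, E_max = 5)
  expect_equal(att$cv_skill, 1, tolerance = 1e-9)
  # smallest E already achieves skill 1, ties broken downward
  expect_equal(att$E, which(att$skill >= 1 - 1e-9)[1])
})

test_that("cross-validated skill on white noise is indistinguishable from zero", {
  hits <- 0
  for (seed in 1:200) {
    set.seed(seed)
    s <- make_std(rnorm(60))
    att <- select_embedding_dimension(s)
    hits <- hits + (abs(att$cv_skill) < 0.45)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("series too short for the embedding search are errors", {
  s <- make_std(rnorm(7))
  expect_error(select_embedding_dimension(s, E_max = 6), "too short")
})

test_that("simplex self-forecasts are exact without exclusion and on noise-free cycles", {
  s <- make_std(rep(c(1, -1), 15))
  att <- select_embedding_dimension(s, E_max = 4)

  fc_incl <- simplex_forecast(s, att, self_exclusion = FALSE)
  expect_equal(fc_incl$predicted, fc_incl$observed)  # self-match absorbs all weight

  fc_excl <- simplex_forecast(s, att, self_exclusion = TRUE)
  expect_lt(max(abs(fc_excl$predicted - fc_excl$observed)), 1e-9)
})

test_that("a 4-level cycle library mispredicts a 2-level cycle", {
  tar <- make_std(rep(c(1, -1), 20))
  lib <- make_std(rep(c(1, -0.5, 0.5, -1), 10), regime = "B")
  att <- select_embedding_dimension(lib, E_max = 5)
  fc <- simplex_forecast(tar, att, self_exclusion = TRUE)
  expect_gt(max(abs(fc$predicted - fc$observed)), 0.1)
})

test_that("forecasts are convex combinations of library successor values", {
  set.seed(11)
  for (i in 1:10) {
    tar <- make_std(cumsum(rnorm(25)))
    lib <- make_std(cumsum(rnorm(28)), regime = "B", times = 101:128)
    E <- sample(1:3, 1)
    att <- structure(list(series = lib, E = E, cv_skill = NA_real_),
                     class = "reconstructed_attractor")
    fc <- simplex_forecast(tar, att)
    succ <- lib$values[-seq_len(E)]
    expect_true(all(fc$predicted >= min(succ) - 1e-12))
    expect_true(all(fc$predicted <= max(succ) + 1e-12))
  }
})

test_that("simplex forecasts match the exhaustive-search oracle exactly", {
  set.seed(23)
  for (i in 1:15) {
    n_t <- sample(12:30, 1); n_l <- sample(12:30, 1)
    E <- sample(1:4, 1)
    # rounding creates duplicated values, exercising ties and zero distances
    tv <- round(cumsum(rnorm(n_t)), 1)
    lv <- round(cumsum(rnorm(n_l)), 1)
    tt <- seq_len(n_t); lt <- seq_len(n_l)
    tar <- regime_series(tv, tt, regime = "i")
    lib <- regime_series(lv, lt, regime = "j")
    att <- structure(list(series = lib, E = E, cv_skill = NA_real_),
                     class = "reconstructed_attractor")
    for (excl in c(TRUE, FALSE)) {
      fc <- simplex_forecast(tar, att, self_exclusion = excl)
      ref <- oracle_simplex(tv, tt, lv, lt, E, exclude_times = excl)
      expect_equal(fc$predicted, ref$pred, tolerance = 1e-12)
      expect_equal(fc$observed, ref$obs)
    }
  }
})

test_that("cross-map forecasts match the exhaustive-search oracle exactly", {
  set.seed(29)
  for (i in 1:10) {
    n <- sample(15:30, 1)
    E <- sample(1:3, 1)
    tx <- round(cumsum(rnorm(n)), 1); ty <- round(cumsum(rnorm(n)), 1)
    lx <- round(cumsum(rnorm(n)), 1); ly <- round(cumsum(rnorm(n)), 1)
    tt <- seq_len(n)
    att <- structure(list(series = regime_series(lx, tt, regime = "j", variable = "X"),
                          E = E, cv_skill = NA_real_),
                     class = "reconstructed_attractor")
    fc <- cross_map_forecast(regime_series(tx, tt, regime = "i", variable = "X"),
                             regime_series(ty, tt, regime = "i", variable = "Y"),
                             att, regime_series(ly, tt, regime = "j", variable = "Y"))
    ref <- oracle_cross_map(tx, ty, tt, lx, ly, tt, E)
    expect_equal(fc$predicted, ref$pred, tolerance = 1e-12)
    expect_equal(fc$observed, ref$obs)
  }
})

test_that("cross-mapping a variable onto itself within a noise-free cycle is exact", {
  s <- make_std(rep(c(1, 0, -1, 0), 10), variable = "X")
  att <- select_embedding_dimension(s, E_max = 4)
  fc <- cross_map_forecast(s, s, att, s, self_exclusion = TRUE)
  expect_lt(max(abs(fc$predicted - fc$observed)), 1e-9)
})

test_that("cross-mapping between independent white-noise series shows no skill", {
  hits <- 0
  for (seed in 1:200) {
    set.seed(seed)
    x1 <- make_std(rnorm(100), regime = "i", variable = "X")
    y1 <- make_std(rnorm(100), regime = "i", variable = "Y")
    x2 <- make_std(rnorm(100), regime = "j", variable = "X")
    y2 <- make_std(rnorm(100), regime = "j", variable = "Y")
    att <- select_embedding_dimension(x2, E_max = 5)
    fc <- cross_map_forecast(x1, y1, att, y2)
    hits <- hits + (abs(cor(fc$observed, fc$predicted)) < 0.4)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("the predator cross-maps the consumer within the 2-point-cycle regime", {
  fB <- food_chain_replicate_factory("B", 0.01, 100)
  vars <- fB(404)
  att <- select_embedding_dimension(vars$P)
  fc <- cross_map_forecast(vars$P, vars$C, att, vars$C, self_exclusion = TRUE)
  expect_gt(cor(fc$observed, fc$predicted), 0.9)
})

test_that("forecast errors are invariant to affine maps applied before standardization", {
  set.seed(31)
  x <- cumsum(rnorm(40)); y <- cumsum(rnorm(35))
  base_t <- make_std(x); base_l <- make_std(y, regime = "B", times = 101:135)
  att <- select_embedding_dimension(base_l, E_max = 3)
  fc0 <- simplex_forecast(base_t, att)
  tr_t <- make_std(3.2 * x - 7); tr_l <- make_std(0.5 * y + 11, regime = "B",
                                                  times = 101:135)
  att2 <- select_embedding_dimension(tr_l, E_max = 3)
  fc1 <- simplex_forecast(tr_t, att2)
  expect_equal(fc1$predicted - fc1$observed, fc0$predicted - fc0$observed,
               tolerance = 1e-9)
})
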