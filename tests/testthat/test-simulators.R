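# The four reference attractors of the food chain and the bistable structure
# of the harvesting model. ODE runs are kept as short as classification
# allows; the deterministic pools used elsewhere are cached per session.

test_that("K = 0.78 settles on a point equilibrium", {
  tr <- simulate_food_chain(food_chain_params(0.78), total_time = 3000,
                            burn_in = 2000)
  for (v in c("R", "C", "P")) {
    tail100 <- utils::tail(tr[[v]]$values, 100)
    expect_lt(max(abs(diff(tail100))), 1e-4)
  }
  expect_identical(classify_food_chain_regime(tr$C), "equilibrium")
})

test_that("K = 0.85 and K = 0.92 give two- and four-level limit cycles", {
  trB <- simulate_food_chain(food_chain_params(0.85), total_time = 8000,
                             burn_in = 5000)
  expect_identical(classify_food_chain_regime(trB$C), "cycle_2")

  trC <- simulate_food_chain(food_chain_params(0.92), total_time = 8000,
                             burn_in = 5000)
  expect_identical(classify_food_chain_regime(trC$C), "cycle_4")

  # every-fifth-point sampling of the unit-step cycle: about 10 samples/cycle
  expect_equal(cycle_period(trB$C) / 5, 10, tolerance = 0.2)
  sampled <- sample_series(trB$C, every = 5)
  expect_equal(length(sampled$values), ceiling(length(trB$C$values) / 5))
})

test_that("K = 0.997 is aperiodic with sensitive dependence on initial state", {
  tr1 <- simulate_food_chain(food_chain_params(0.997), total_time = 8000,
                             burn_in = 5000)
  expect_identical(classify_food_chain_regime(tr1$C), "aperiodic")
  tr2 <- simulate_food_chain(food_chain_params(0.997), total_time = 8000,
                             burn_in = 5000,
                             initial_state = c(R = 0.5 + 1e-8, C = 0.3, P = 0.8))
  # twin trajectories diverge to the attractor scale
  expect_gt(max(abs(tr1$C$values - tr2$C$values)), 0.1)
  # but both stay bounded and non-negative
  for (tr in list(tr1, tr2)) {
    st <- cbind(tr$R$values, tr$C$values, tr$P$values)
    expect_true(all(st >= 0))
    expect_true(all(st < 2))
  }
})

test_that("sampled pre-chaotic trajectories are insensitive to the solver tolerance", {
  a <- simulate_food_chain(food_chain_params(0.85), total_time = 2600,
                           burn_in = 2000)
  b <- simulate_food_chain(food_chain_params(0.85), total_time = 2600,
                           burn_in = 2000, rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(a$C$values - b$C$values)), 1e-5)
})

test_that("the regime classifier reads synthetic extremum patterns", {
  expect_identical(classify_food_chain_regime(regime_series(rep(1, 50))),
                   "equilibrium")
  expect_identical(classify_food_chain_regime(regime_series(rep(c(1, -1), 25))),
                   "cycle_2")
  expect_identical(
    classify_food_chain_regime(regime_series(rep(c(1, -0.5, 0.5, -1), 15))),
    "cycle_4")
  expect_error(classify_food_chain_regime(regime_series(c(0, 1, 0, 1, 0))),
               "maxima")
})

test_that("subsampling keeps every k-th point", {
  s <- regime_series(1:10)
  expect_equal(sample_series(s, 1)$values, 1:10)
  expect_equal(sample_series(s, 5)$values, c(1, 6))
  expect_equal(sample_series(s, 5)$times, c(1, 6))
})

test_that("observation noise is seeded, scaled, and mean-preserving", {
  clean <- regime_series(sin(2 * pi * (1:10000) / 50))
  expect_identical(add_observation_noise(clean, 0), clean)

  n1 <- add_observation_noise(clean, 0.2, seed = 5)
  n2 <- add_observation_noise(clean, 0.2, seed = 5)
  expect_identical(n1$values, n2$values)

  # residual sd close to rho * sd(deterministic) by the law of large numbers
  resid <- n1$values - clean$values
  expect_equal(sd(resid), 0.2 * sd(clean$values), tolerance = 0.03)

  # the clean series is the conditional mean: replicate average recovers it
  short <- regime_series(sin(2 * pi * (1:50) / 10))
  reps <- vapply(1:1000, function(s) {
    add_observation_noise(short, 0.3, seed = s)$values
  }, numeric(50))
  dev <- abs(rowMeans(reps) - short$values)
  expect_true(all(dev <= 3 * 0.3 * sd(short$values) / sqrt(1000)))

  expect_error(add_observation_noise(regime_series(rep(1, 10)), 0.1),
               "zero-variance")
})

test_that("skeleton equilibria match the dense-scan oracle across the fold structure", {
  eq0 <- skeleton_equilibria(0, K = 11)
  expect_equal(eq0$x, c(0, 11))
  expect_equal(eq0$stable, c(FALSE, TRUE))

  eq <- skeleton_equilibria(2.2, K = 11)
  pos <- eq[eq$x > 1e-8, ]
  expect_equal(nrow(pos), 3)
  expect_equal(pos$stable, c(TRUE, FALSE, TRUE))
  expect_equal(pos$x, oracle_equilibria(2.2), tolerance = 1e-4)

  eq_hi <- skeleton_equilibria(4, K = 11)
  pos_hi <- eq_hi[eq_hi$x > 1e-8, ]
  expect_equal(nrow(pos_hi), 1)
  expect_true(pos_hi$stable)
  expect_lt(pos_hi$x, 1)              # overexploited low state
})

test_that("fold points bracket the bistable window and match a brute-force scan", {
  folds <- find_fold_points(11)
  expect_lt(folds["lower"], folds["upper"])
  # scan oracle: fold = where the positive-root count changes
  cs <- seq(1.7, 3.0, by = 1e-3)
  npos <- vapply(cs, function(cc) sum(oracle_equilibria(cc, n_grid = 20000) > 1e-6), 0L)
  expect_equal(unname(folds["lower"]), cs[which(npos == 3)[1] - 1], tolerance = 2e-3)
  expect_equal(unname(folds["upper"]), cs[utils::tail(which(npos == 3), 1) + 1],
               tolerance = 2e-3)
  expect_error(find_fold_points(K = 1), "no bistable window")
})

test_that("the stochastic harvesting model stays in its basin and is reproducible", {
  eq <- skeleton_equilibria(2.2, K = 11)
  pos <- eq$x[eq$stable & eq$x > 1e-8]
  x_low <- min(pos)
  threshold <- eq$x[!eq$stable & eq$x > 1e-8]

  # noise-free limit: the path stays at the skeleton equilibrium
  s0 <- simulate_ass(2.2, "lower", 100, sigma = 0, seed = 1)
  expect_lt(max(abs(s0$values - x_low)), 1e-6)

  s1 <- simulate_ass(2.2, "lower", 5000, sigma = 0.01, seed = 42)
  s2 <- simulate_ass(2.2, "lower", 5000, sigma = 0.01, seed = 42)
  expect_identical(s1$values, s2$values)
  expect_lt(abs(mean(s1$values) - x_low) / x_low, 0.05)
  expect_true(all(s1$values < threshold))   # no stochastic flip

  expect_error(simulate_ass(1.0, "lower", 10), "bistable")
})

test_that("branch initialisation picks the matching stable state", {
  lo <- simulate_ass(2.2, "lower", 50, sigma = 0.01, seed = 2)
  hi <- simulate_ass(2.2, "upper", 50, sigma = 0.01, seed = 2)
  expect_identical(lo$regime, "SS1")
  expect_identical(hi$regime, "SS2")
  expect_lt(mean(lo$values), mean(hi$values))
})
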