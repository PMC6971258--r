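test_that("coupled logistic pairs honour the stated recursion", {
  s <- simulate_coupled_logistic(r_x = 3.8, r_y = 3.5, beta_xy = 0.1,
                                 beta_yx = 0.2, lag = 0, n = 100, seed = 1)
  expect_true(all(s$x > 0 & s$x < 1))
  expect_true(all(s$y > 0 & s$y < 1))
  # the recursion holds on the emitted tail
  for (t in 5:99) {
    expect_equal(s$x[t + 1],
                 s$x[t] * (3.8 - 3.8 * s$x[t] - 0.1 * s$y[t]))
    expect_equal(s$y[t + 1],
                 s$y[t] * (3.5 - 3.5 * s$y[t] - 0.2 * s$x[t]))
  }
  s2 <- simulate_coupled_logistic(n = 100, seed = 1, beta_xy = 0.1,
                                  beta_yx = 0.2, r_y = 3.5)
  expect_identical(s$x, s2$x)
  # decoupled: x is a plain logistic map
  s0 <- simulate_coupled_logistic(beta_xy = 0, beta_yx = 0, n = 80,
                                  seed = 2)
  for (t in 5:79) {
    expect_equal(s0$x[t + 1], 3.8 * s0$x[t] * (1 - s0$x[t]))
  }
  expect_error(simulate_coupled_logistic(r_x = 3.2, n = 100))
})

test_that("synthetic climate matches its specification", {
  clim <- simulate_climate(n_days = 800, temp_amplitude = 0,
                           temp_noise_sd = 0, seed = 3)
  expect_true(all(abs(clim$tavg - clim$tavg[1]) < 1e-12))
  expect_equal(clim$tavg, (clim$tmax + clim$tmin) / 2)
  expect_true(all(clim$rain >= 0))

  clim2 <- simulate_climate(n_days = 600, seed = 4)
  clim3 <- simulate_climate(n_days = 600, seed = 4)
  expect_identical(clim2, clim3)

  # expected annual rainfall near the 2000 mm default
  totals <- vapply(1:20, function(i) {
    c4 <- simulate_climate(n_days = 731, seed = 100 + i)
    sum(c4$rain) * 365.25 / 731
  }, numeric(1))
  expect_lt(abs(mean(totals) - 2000) / 2000, 0.1)

  # weak seasonality: within the observed tropical range
  c5 <- simulate_climate(n_days = 1000, seed = 7)
  expect_lt(max(c5$tavg) - min(c5$tavg), 7)
})

test_that("simulation truth validates its coupling structure", {
  expect_error(simulation_truth("x", coupling = data.frame(
    from = "x", to = "z", strength = 0.3, lag = 1)), "unknown")
  expect_error(simulation_truth(c("x", "y"), coupling = data.frame(
    from = "x", to = "y", strength = -1, lag = 0)), "non-negative")
  tr <- simulation_truth(c("starch", "sugar"),
                         coupling = data.frame(from = "starch",
                                               to = "sugar",
                                               strength = 0.3, lag = 2))
  expect_s3_class(tr, "simulation_truth")
})

test_that("simulated studies have the replicate layout of the field study", {
  tr <- simulation_truth(c("V", "starch", "sugar"))
  st <- simulate_study(tr, n_trees = 4, n_months = 42, seed = 11)
  expect_equal(length(st$dates), 42)
  expect_equal(length(unique(st$nsc$tree_id)), 4)
  expect_equal(nrow(st$nsc), 4 * 42 * 3)
  d <- suppressWarnings(trait_dataset(st$organs, st$nsc, st$treatments))
  comp <- composite_from_dataset(d, "starch")
  expect_equal(length(comp$values), 168)
  expect_false(anyNA(d$starch))

  st2 <- simulate_study(tr, n_months = 42, seed = 11)
  expect_identical(st$nsc, st2$nsc)

  stm <- simulate_study(tr, n_months = 42, missing_rate = 0.1, seed = 12)
  dm <- suppressWarnings(trait_dataset(stm$organs, stm$nsc,
                                       stm$treatments))
  expect_true(anyNA(dm$starch) || anyNA(dm$sugar))
})

test_that("preprocessing reproduces the generator's latent V and G", {
  tr <- simulation_truth(c("V", "sugar"))
  st <- simulate_study(tr, n_months = 30, seed = 13)
  d <- trait_dataset(st$organs, st$nsc, st$treatments)
  lat <- st$latent[order(st$latent$tree_id, st$latent$date), ]
  got <- d[order(d$tree_id, d$date), ]
  expect_lt(max(abs(got$V - lat$V) / pmax(abs(lat$V), 1e-12)), 1e-9)
  ok <- !is.na(lat$G)
  expect_lt(max(abs(got$G[ok] - lat$G[ok]) /
                pmax(abs(lat$G[ok]), 1e-12)), 1e-9)
})

test_that("planted direction and lag are recovered from composite replicates", {
  # low observation noise: lag identification requires inverting the
  # map's direct imprint, which heavy noise provably obscures (see the
  # methods vignette on echo lags)
  measure <- function(n_months, nrep, base) {
    res <- sapply(seq_len(nrep), function(i) {
      tr <- simulation_truth(
        c("starch", "sugar"), seasonal_amplitude = 0, noise_sd = 0.1,
        coupling = data.frame(from = "starch", to = "sugar",
                              strength = 0.32, lag = 1))
      st <- simulate_study(tr, n_months = n_months, seed = base + i)
      d <- suppressWarnings(trait_dataset(st$organs, st$nsc,
                                          st$treatments))
      cs <- composite_from_dataset(d, "starch")
      cg <- composite_from_dataset(d, "sugar")
      fwd <- lag_scan(cg, cs, E = 2, lags = -6:6)
      rev <- lag_scan(cs, cg, E = 2, lags = -6:6)
      max(fwd$table$rho) > max(rev$table$rho) && fwd$best_lag == -1
    })
    mean(res)
  }
  expect_gte(measure(42, 15, 52000), 0.6)    # study layout, 4 x 42
  expect_gte(measure(100, 10, 53000), 0.9)   # scaled-up composite
})
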