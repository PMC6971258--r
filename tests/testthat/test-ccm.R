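test_that("self cross mapping of an identical series is near-perfect", {
  # leave-one-out excludes the query's own state, so skill is slightly
  # below 1 on a continuous-valued series and exactly 1 on a periodic one
  x <- composite_series(list(logistic_series(80)))
  cm <- cross_map(x, x, E = 1, tp = 0, lib_sizes = NA)
  expect_gt(cm$rho, 0.99)
  p <- composite_series(list(rep(c(0.2, 0.8, 0.5), 20)))
  expect_equal(cross_map(p, p, E = 1, tp = 0, lib_sizes = NA)$rho, 1)
})

test_that("embedding dimension selection maximises skill, ties go low", {
  s <- simulate_coupled_logistic(n = 300, beta_yx = 0.32, beta_xy = 0,
                                 seed = 5)
  E <- select_E(s$y, s$x, E_range = 2:8)
  expect_true(E %in% 2:3)   # two-species deterministic system
  expect_equal(select_E(s$y, s$x, E_range = 2), 2)
  # perfectly periodic pair: skill 1 for every E, smallest returned
  p <- composite_series(list(rep(c(0, 1, 0.5), 20)))
  expect_equal(select_E(p, p, E_range = 2:5), 2)
  const <- composite_series(list(rep(c(1, 1), 20)))
  expect_error(select_E(p, const, E_range = 2:4), "undefined")
})

test_that("cross mapping recovers the benchmark's causal direction", {
  set.seed(6)
  wins <- vapply(1:10, function(i) {
    s <- simulate_coupled_logistic(n = 400, beta_yx = 0.32, beta_xy = 0,
                                   seed = 600 + i)
    true_dir <- cross_map(s$y, s$x, E = 2, tp = -1, lib_sizes = NA)$rho
    false_dir <- cross_map(s$x, s$y, E = 2, tp = -1, lib_sizes = NA)$rho
    true_dir > false_dir && true_dir > 0.8
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("independent noise pairs stay inside the surrogate band", {
  set.seed(8)
  x <- composite_series(lapply(1:4, function(i) rnorm(42)))
  y <- composite_series(lapply(1:4, function(i) rnorm(42)))
  cm <- cross_map(x, y, E = 2, tp = 0, lib_sizes = NA, surrogates = 200,
                  seed = 9)
  expect_false(cm$significant)
})

test_that("library draws and surrogate ensembles are seed-reproducible", {
  s <- simulate_coupled_logistic(n = 150, seed = 3)
  cm1 <- cross_map(s$y, s$x, E = 2, tp = -1, n_draws = 10,
                   surrogates = 50, seed = 77)
  cm2 <- cross_map(s$y, s$x, E = 2, tp = -1, n_draws = 10,
                   surrogates = 50, seed = 77)
  expect_identical(cm1$draws, cm2$draws)
  expect_identical(cm1$bound_95, cm2$bound_95)
  cm3 <- cross_map(s$y, s$x, E = 2, tp = -1, n_draws = 10,
                   surrogates = 50, seed = 78)
  expect_false(identical(cm3$draws$rho, cm1$draws$rho))
})

test_that("library-size grid is increasing and capped at the vector count", {
  s <- simulate_coupled_logistic(n = 120, seed = 4)
  cm <- cross_map(s$y, s$x, E = 2, tp = -1, n_draws = 5, seed = 1)
  expect_true(all(diff(cm$library_sizes) > 0))
  expect_equal(max(cm$library_sizes), cm$n_vectors)
  expect_equal(min(cm$library_sizes), 2 + 2)
  # skill at the full library size equals the deterministic full fit
  full_rows <- cm$draws[cm$draws$L == cm$n_vectors, ]
  expect_equal(nrow(full_rows), 1)
  expect_equal(full_rows$rho, cm$rho)
})

test_that("convergence flags reflect the skill-vs-library-size trend", {
  up <- data.frame(L = rep(c(10, 20, 40), each = 5),
                   rho = rep(c(0.2, 0.5, 0.8), each = 5))
  expect_true(convergence_check(up))
  flat <- data.frame(L = rep(c(10, 20, 40), each = 5), rho = 0)
  expect_false(convergence_check(flat))
  down <- data.frame(L = rep(c(10, 20, 40), each = 5),
                     rho = rep(c(0.8, 0.5, 0.2), each = 5))
  expect_false(convergence_check(down))
  # a genuinely coupled pair converges
  s <- simulate_coupled_logistic(n = 300, beta_yx = 0.32, beta_xy = 0,
                                 seed = 10)
  cm <- cross_map(s$y, s$x, E = 2, tp = -1, n_draws = 30, seed = 2)
  expect_true(cm$convergent)
})

test_that("lag scans locate a planted transmission delay", {
  expect_error(lag_scan(1:10, 1:10, lags = integer(0)), "empty")
  s <- simulate_coupled_logistic(n = 400, beta_yx = 0.32, beta_xy = 0,
                                 lag = 1, seed = 12)
  sc <- lag_scan(s$y, s$x, E = 2, lags = -6:6)
  expect_equal(sc$best_lag, -2)
  expect_equal(nrow(sc$table), 13)
  single <- lag_scan(s$y, s$x, E = 2, lags = -3)
  expect_equal(single$best_lag, -3)
  # fast path agrees with the generic fitter at every lag
  for (tp in c(-4, 0, 3)) {
    expect_equal(sc$results[[as.character(tp)]]$rho,
                 cross_map(s$y, s$x, E = 2, tp = tp, lib_sizes = NA)$rho)
  }
})

test_that("white-noise pairs reject at no more than chance level", {
  set.seed(13)
  n_sig <- n_tests <- 0
  for (i in 1:5) {
    x <- composite_series(lapply(1:4, function(j) rnorm(42)))
    y <- composite_series(lapply(1:4, function(j) rnorm(42)))
    sc <- lag_scan(x, y, E = 2, lags = -3:3, surrogates = 200,
                   seed = 14 + i)
    n_sig <- n_sig + sum(sc$table$significant)
    n_tests <- n_tests + nrow(sc$table)
  }
  expect_lte(n_sig / n_tests, 0.2)
})
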