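test_that("simplex projection matches the brute-force oracle", {
  set.seed(11)
  for (i in 1:25) {
    lens <- sample(12:25, sample(1:2, 1), replace = TRUE)
    E <- sample(1:4, 1)
    comp <- composite_series(lapply(lens, rnorm))
    emb <- delay_embed(comp, E)
    tp <- sample(-2:2, 1)
    fit <- simplex_predict(emb, comp, tp = tp)
    oracle <- brute_simplex(emb$vectors, emb$source_index, emb$segment,
                            comp$values, tp,
                            lib = seq_len(nrow(emb$vectors)),
                            pred = seq_len(nrow(emb$vectors)),
                            k = E + 1L)
    expect_equal(fit$predictions$query, oracle$pred)
    expect_equal(fit$neighbors, oracle$neighbors)
    expect_equal(fit$weights, oracle$weights)
    expect_equal(fit$predictions$pred, oracle$predictions)
  }
})

test_that("a strictly periodic series is predicted perfectly", {
  comp <- composite_series(list(rep(c(0, 1), 12)))
  fit <- simplex_predict(delay_embed(comp, 2), comp, tp = 0)
  expect_equal(fit$rho, 1)
})

test_that("i.i.d. noise has near-zero self-prediction skill", {
  set.seed(3)
  rhos <- vapply(1:5, function(i) {
    comp <- composite_series(list(rnorm(500)))
    simplex_predict(delay_embed(comp, 2), comp, tp = 1)$rho
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.15)
})

test_that("a single-neighbour library returns that neighbour's target", {
  comp <- composite_series(list(rnorm(20)))
  emb <- delay_embed(comp, 2)
  fit <- simplex_predict(emb, comp, tp = 0, lib = 5L, pred = 10L, k = 1L)
  expect_equal(fit$predictions$pred, comp$values[emb$source_index[5L]])
})

test_that("skill is invariant under affine transformation of the target", {
  set.seed(4)
  lib <- composite_series(list(logistic_series(150)))
  tgt <- rnorm(150) + 0.4 * lib$values
  emb <- delay_embed(lib, 2)
  r1 <- simplex_predict(emb, tgt, tp = 0)$rho
  r2 <- simplex_predict(emb, 3.2 * tgt - 7, tp = 0)$rho
  expect_equal(r1, r2)
})

test_that("zero-distance neighbours share the top weight", {
  # three identical states plus distant ones; ties broken by lower index
  comp <- composite_series(list(c(0, 1, 0, 1, 0, 1, 5, 9, 2, 7, 3, 8)))
  emb <- delay_embed(comp, 2)
  fit <- simplex_predict(emb, comp, tp = 0)
  q <- which(fit$predictions$query == 1)
  w <- fit$weights[q, ]
  d_same <- sum(abs(emb$vectors[fit$neighbors[q, ], 1] -
                    emb$vectors[1, 1]) < 1e-12)
  expect_gte(d_same, 2)
  expect_equal(w[1], w[2])   # equal weight for exact matches
})

test_that("errors are raised for inadequate libraries", {
  comp <- composite_series(list(rnorm(10)))
  emb <- delay_embed(comp, 2)
  expect_error(simplex_predict(emb, comp, tp = 0, lib = 1:2), "fewer than")
})
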