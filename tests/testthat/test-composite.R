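test_that("replicates are standardised independently and concatenated", {
  x <- sin(1:42) + 1:42 / 10
  one <- composite_series(list(x))
  expect_equal(one$values, as.numeric(scale(x)))
  expect_equal(length(unique(one$segment)), 1)

  two <- composite_series(list(a = x, b = x))
  expect_equal(two$values[1:42], two$values[43:84])
  expect_equal(two$segment, rep(1:2, each = 42))

  four <- composite_series(lapply(1:4, function(i) rnorm(42)))
  expect_equal(length(four$values), 168)
  for (s in 1:4) {
    seg <- four$values[four$segment == s]
    expect_lt(abs(mean(seg)), 1e-9)
    expect_lt(abs(sd(seg) - 1), 1e-9)
  }

  const <- composite_series(list(rep(2, 10), rnorm(10)))
  expect_equal(const$constant, c(TRUE, FALSE))
  expect_equal(const$values[1:10], rep(0, 10))

  expect_error(composite_series(list()), "at least one")
  expect_error(composite_series(list(1)), "length >= 2")
})

test_that("delay embedding respects segment boundaries", {
  comp <- composite_series(list(rnorm(10), rnorm(10)))
  e1 <- delay_embed(comp, 1)
  expect_equal(as.numeric(e1$vectors), comp$values)

  one <- composite_series(list(rnorm(10)))
  e3 <- delay_embed(one, 3)
  expect_equal(nrow(e3$vectors), 8)
  expect_equal(e3$source_index, 3:10)

  e <- delay_embed(comp, 3)
  expect_equal(nrow(e$vectors), 16)
  # no vector's coordinates reach back across the junction at index 11
  expect_true(all(e$source_index - 2 >= ifelse(e$segment == 1, 1, 11)))

  # randomized segment layouts: count formula and boundary safety
  set.seed(42)
  for (i in 1:10) {
    lens <- sample(3:20, sample(2:5, 1), replace = TRUE)
    E <- sample(2:4, 1); tau <- sample(1:2, 1)
    comp_r <- composite_series(lapply(lens, rnorm))
    emb <- suppressWarnings(delay_embed(comp_r, E, tau))
    expect_equal(nrow(emb$vectors), sum(pmax(0, lens - (E - 1) * tau)))
    for (j in seq_len(nrow(emb$vectors))) {
      idx <- emb$source_index[j] - (0:(E - 1)) * tau
      expect_true(all(comp_r$segment[idx] == emb$segment[j]))
      expect_equal(emb$vectors[j, ], comp_r$values[idx])
    }
  }
})

test_that("short segments contribute zero vectors with a warning", {
  comp <- composite_series(list(rnorm(3), rnorm(12)))
  expect_warning(emb <- delay_embed(comp, 5), "contributes no vectors")
  expect_equal(nrow(emb$vectors), 8)
  expect_true(all(emb$segment == 2))
})

test_that("vectors containing missing values are dropped", {
  x <- rnorm(20); x[7] <- NA
  emb <- delay_embed(composite_series(list(x)), 3)
  expect_false(any(is.na(emb$vectors)))
  expect_false(any(emb$source_index %in% 7:9))
})
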