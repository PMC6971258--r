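test_that("recurrence structure matches an exhaustive pairwise check", {
  vecs <- matrix(c(0, 0, 1, 0, 0, 1.5, 4, 4,
                   0.2, 0, 1, 0.4, 0, 1.4, 4.1, 4,
                   0, 0.3, 1, 0, 0.5, 1.2, 3.9, 4.2), ncol = 2)
  emb <- structure(list(vectors = vecs, source_index = seq_len(nrow(vecs)),
                        segment = rep(1L, nrow(vecs)),
                        time_segment = rep(1L, nrow(vecs)),
                        E = 2L, tau = 1L, n = nrow(vecs)),
                   class = "delay_embedding")
  rs <- recurrence_structure(emb, 0.25)
  # brute force with explicit loops
  n <- nrow(vecs)
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    D[i, j] <- max(abs(vecs[i, ] - vecs[j, ]))
  }
  thr <- quantile(D[upper.tri(D)], 0.25, names = FALSE)
  expect_equal(rs$threshold, thr)
  expect_equal(unname(rs$matrix), D <= thr)
  expect_true(all(diag(rs$matrix)))
  expect_true(isSymmetric(unname(rs$matrix) * 1))
})

test_that("degenerate all-identical embeddings are rejected", {
  emb <- delay_embed(composite_series(list(rep(c(0, 0), 10))), 1)
  expect_error(recurrence_structure(emb, 0.1), "degenerate")
})

test_that("twins are vectors with identical recurrence columns", {
  # columns 1 and 2 identical -> one twin class of size 2
  m <- diag(4) > 0
  m[1, 2] <- m[2, 1] <- TRUE
  tw <- find_twins(structure(list(matrix = m),
                             class = "recurrence_structure"))
  expect_equal(tw$n_classes, 3)
  expect_equal(tw$class_id[1], tw$class_id[2])
  expect_equal(sort(tw$sizes), c(1, 1, 2))
  # all columns distinct -> all singletons
  m2 <- diag(4) > 0
  m2[1, 2] <- m2[2, 1] <- TRUE
  m2[2, 3] <- m2[3, 2] <- TRUE
  tw2 <- find_twins(structure(list(matrix = m2),
                              class = "recurrence_structure"))
  expect_equal(tw2$n_classes, 4)
  expect_true(all(tw2$sizes == 1))
  # every column equal -> one class
  m3 <- matrix(TRUE, 4, 4)
  tw3 <- find_twins(structure(list(matrix = m3),
                              class = "recurrence_structure"))
  expect_equal(tw3$n_classes, 1)
  expect_equal(tw3$sizes, 4)
})

test_that("a periodic orbit yields twin classes of high multiplicity", {
  x <- rep(c(0.1, 0.9, 0.4, 0.6), 10)          # period 4, length 40
  emb <- delay_embed(composite_series(list(x)), 1)
  tw <- find_twins(recurrence_structure(emb, 0.1))
  expect_equal(tw$n_classes, 4)
  expect_true(all(tw$sizes >= 9))
})

test_that("surrogates have the original length and values", {
  comp <- composite_series(lapply(1:4, function(i) rnorm(42) + sin(1:42)))
  ens <- twin_surrogates(comp, E = 3, n_surrogates = 25, seed = 1)
  expect_equal(dim(ens$series), c(168, 25))
  expect_true(all(ens$series %in% comp$values))
})

test_that("surrogate ensembles are seeded and reproducible", {
  comp <- composite_series(list(logistic_series(120)))
  e1 <- twin_surrogates(comp, E = 2, n_surrogates = 10, seed = 4)
  e2 <- twin_surrogates(comp, E = 2, n_surrogates = 10, seed = 4)
  expect_identical(e1$series, e2$series)
  e3 <- twin_surrogates(comp, E = 2, n_surrogates = 10, seed = 5)
  expect_true(any(e3$series != e1$series))
})

test_that("surrogates preserve the seasonal autocorrelation", {
  set.seed(31)
  diffs_locked <- plain_level <- numeric(5)
  for (i in 1:5) {
    x <- sin(2 * pi * (1:144) / 12) + rnorm(144, 0, 0.4)
    comp <- composite_series(list(x))
    ac12 <- function(s) acf(s, lag.max = 12, plot = FALSE)$acf[13]
    ens <- twin_surrogates(comp, E = 2, n_surrogates = 40, seed = i,
                           period = 12)
    diffs_locked[i] <- mean(apply(ens$series, 2, ac12)) - ac12(comp$values)
    ens0 <- twin_surrogates(comp, E = 2, n_surrogates = 40, seed = i)
    plain_level[i] <- mean(apply(ens0$series, 2, ac12))
  }
  # phase-locked surrogates keep the annual cycle almost exactly
  expect_lt(mean(abs(diffs_locked)), 0.2)
  # plain twin surrogates still carry a clearly positive annual signal
  expect_gt(mean(plain_level), 0.2)
})

test_that("phase-locked surrogates keep the calendar-aligned cycle", {
  seas <- sin(2 * pi * (1:84) / 12)
  comp <- composite_series(lapply(1:2, function(i)
    seas + rnorm(84, 0, 0.3)))
  ens <- twin_surrogates(comp, E = 2, n_surrogates = 50, seed = 2,
                         period = 12)
  # correlation with the shared seasonal cycle stays positive on average
  cors <- apply(ens$series, 2, function(s) cor(s, rep(seas, 2)))
  expect_gt(mean(cors), 0.3)
})

test_that("significance uses the linear-interpolation 95th percentile", {
  skills <- (1:100) / 100
  st <- significance_test(0.99, skills)
  expect_equal(st$bound, 0.9505)
  expect_true(st$significant)
  expect_false(significance_test(median(skills), skills)$significant)
  expect_true(significance_test(2, rnorm(1000))$significant)
})
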