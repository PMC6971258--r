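#' Simplex projection: nearest-neighbour cross prediction
#'
#' For each query delay vector, the `E + 1` nearest library vectors
#' (Euclidean distance) are found; their target values at offset `tp`
#' are combined with exponential weights \eqn{w_i = \exp(-d_i/d_1)}
#' (normalised to sum to one, \eqn{d_1} the nearest distance) to give the
#' prediction. Skill is the Pearson correlation between predictions and
#' observations over all queries.
#'
#' Library vectors sharing a query's source index (including the query
#' itself) are excluded from that query's neighbour search, giving
#' leave-one-out prediction when `lib` and `pred` coincide. If the nearest
#' distance is zero, the smallest positive distance among the neighbours is
#' used in the exponent, so exact matches share the top weight; exact
#' distance ties are broken toward the lower vector index.
#'
#' @param embedding a [delay_embed()] of the library series.
#' @param target numeric vector (or [composite_series()]) of target values
#'   on the same time grid as the library composite.
#' @param tp prediction offset in sampling intervals: the value predicted
#'   for a vector with source index `t` is `target[t + tp]`. Negative `tp`
#'   means the target series leads the library.
#' @param lib,pred integer indices (rows of `embedding$vectors`) used as
#'   library and as queries; default all vectors. Vectors without a defined
#'   target value at offset `tp` are dropped from both roles.
#' @param k number of neighbours (default `E + 1`).
#' @param exclude_self exclude library vectors sharing the query's source
#'   index (default `TRUE`).
#' @return object of class `simplex_fit`: `rho`, `predictions` (data frame
#'   `query`, `source`, `obs`, `pred`), `neighbors` and `nb_source`
#'   (matrices, one row per query), `weights`, plus the call parameters.
#' @export
simplex_predict <- function(embedding, target, tp = 0, lib = NULL,
                            pred = NULL, k = NULL, exclude_self = TRUE) {
  if (inherits(target, "composite_series")) target <- target$values
  stopifnot(length(target) == embedding$n)
  nv <- nrow(embedding$vectors)
  if (is.null(lib)) lib <- seq_len(nv)
  if (is.null(pred)) pred <- seq_len(nv)
  if (is.null(k)) k <- embedding$E + 1L
  lib <- lib[valid_offset(embedding, target, tp, embedding$source_index[lib])]
  if (length(lib) < k) {
    stop("fewer than ", k, " library vectors with a defined target value ",
         "at offset tp = ", tp)
  }
  pred <- pred[valid_offset(embedding, target, tp, embedding$source_index[pred])]
  if (length(pred) == 0L) stop("no query vectors with a defined target value")

  D <- dist_euclid(embedding$vectors[pred, , drop = FALSE],
                   embedding$vectors[lib, , drop = FALSE])
  if (exclude_self) {
    same <- outer(embedding$source_index[pred],
                  embedding$source_index[lib], "==")
    D[same] <- Inf
  }

  nq <- length(pred)
  nb <- nbs <- matrix(NA_integer_, nq, k)
  W <- matrix(NA_real_, nq, k)
  predictions <- rep(NA_real_, nq)
  keep <- rep(TRUE, nq)
  for (q in seq_len(nq)) {
    d <- D[q, ]
    finite <- sum(is.finite(d))
    if (finite < k) { keep[q] <- FALSE; next }
    ord <- order(d, lib)[seq_len(k)]
    dk <- d[ord]
    w <- simplex_weights(dk)
    nb[q, ] <- lib[ord]
    nbs[q, ] <- embedding$source_index[lib[ord]]
    W[q, ] <- w
    predictions[q] <- sum(w * target[nbs[q, ] + tp])
  }
  if (!all(keep)) {
    warning(sum(!keep), " query vector(s) dropped: fewer than ", k,
            " admissible library vectors")
    pred <- pred[keep]
    nb <- nb[keep, , drop = FALSE]
    nbs <- nbs[keep, , drop = FALSE]
    W <- W[keep, , drop = FALSE]
    predictions <- predictions[keep]
  }
  obs <- target[embedding$source_index[pred] + tp]
  rho <- safe_cor(predictions, obs)
  structure(list(rho = rho,
                 predictions = data.frame(
                   query = pred,
                   source = embedding$source_index[pred],
                   obs = obs, pred = predictions),
                 neighbors = nb, nb_source = nbs, weights = W,
                 lib = lib, E = embedding$E, tp = tp, k = k),
            class = "simplex_fit")
}

#' @export
print.simplex_fit <- function(x, ...) {
  cat("Simplex projection: E =", x$E, ", tp =", x$tp,
      ",", nrow(x$predictions), "predictions, rho =",
      format(x$rho, digits = 4), "\n")
  invisible(x)
}

# exponential simplex weights for an ascending distance vector
simplex_weights <- function(dk) {
  d1 <- dk[1L]
  if (d1 == 0) {
    pos <- dk[dk > 0]
    d1 <- if (length(pos) > 0L) min(pos) else 1
  }
  w <- exp(-dk / d1)
  w / sum(w)
}

dist_euclid <- function(P, L) {
  D2 <- outer(rowSums(P^2), rep(1, nrow(L))) +
    outer(rep(1, nrow(P)), rowSums(L^2)) - 2 * tcrossprod(P, L)
  sqrt(pmax(D2, 0))
}

safe_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok])
}

# Precompute per-query candidate orderings for repeated skill evaluation
# against many target series/offsets sharing one library embedding.
knn_precompute <- function(embedding, exclude_self = TRUE) {
  D <- dist_euclid(embedding$vectors, embedding$vectors)
  if (exclude_self) {
    same <- outer(embedding$source_index, embedding$source_index, "==")
    D[same] <- Inf
  }
  nv <- nrow(D)
  ord <- matrix(0L, nv, nv)
  for (q in seq_len(nv)) ord[q, ] <- order(D[q, ], seq_len(nv))
  list(D = D, ord = ord, embedding = embedding)
}

# Neighbour geometry for a given lag: which queries are admissible and
# which k library vectors serve each, for an NA-free target. Depends only
# on the embedding, the lag, and the segment layout, so one geometry can
# score many target series (e.g. all cumulative windows at one lag).
lag_geometry <- function(pre, tp, k) {
  emb <- pre$embedding
  src <- emb$source_index
  ti <- src + tp
  ok <- ti >= 1L & ti <= emb$n
  ok[ok] <- emb$time_segment[ti[ok]] == emb$time_segment[src[ok]]
  qs <- which(ok)
  if (length(qs) < k + 1L) return(NULL)
  nv <- nrow(pre$ord)
  nq <- length(qs)
  nbs <- matrix(NA_integer_, nq, k)
  W <- matrix(NA_real_, nq, k)
  for (i in seq_len(nq)) {
    q <- qs[i]
    row <- pre$ord[q, ]
    m <- min(k + 8L, nv)
    sel <- row[seq_len(m)]
    sel <- sel[ok[sel] & is.finite(pre$D[q, sel])]
    while (length(sel) < k && m < nv) {
      m2 <- min(2L * m, nv)
      ext <- row[(m + 1L):m2]
      sel <- c(sel, ext[ok[ext] & is.finite(pre$D[q, ext])])
      m <- m2
    }
    if (length(sel) < k) next
    sel <- sel[seq_len(k)]
    nbs[i, ] <- src[sel]
    W[i, ] <- simplex_weights(pre$D[q, sel])
  }
  good <- !is.na(nbs[, 1L])
  if (!any(good)) return(NULL)
  list(obs_index = src[qs[good]] + tp,
       nb_target = nbs[good, , drop = FALSE] + tp,
       weights = W[good, , drop = FALSE])
}

# Cross-map skill of an NA-free target series under a fixed lag geometry.
geometry_skill <- function(geo, target) {
  if (inherits(target, "composite_series")) target <- target$values
  preds <- rowSums(geo$weights * matrix(target[geo$nb_target],
                                        nrow(geo$nb_target)))
  safe_cor(preds, target[geo$obs_index])
}

# Full-library leave-one-out cross-map skill from a precomputed kNN
# structure; returns the same neighbour/weight matrices as simplex_predict.
fast_skill <- function(pre, target, tp, k) {
  emb <- pre$embedding
  if (inherits(target, "composite_series")) target <- target$values
  ok <- valid_offset(emb, target, tp)
  qs <- which(ok)
  if (sum(ok) < k + 1L) return(list(rho = NA_real_))
  nq <- length(qs)
  nbs <- matrix(NA_integer_, nq, k)
  W <- matrix(NA_real_, nq, k)
  predictions <- rep(NA_real_, nq)
  nv <- nrow(pre$ord)
  for (i in seq_len(nq)) {
    q <- qs[i]
    row <- pre$ord[q, ]
    # scan the precomputed ordering in chunks until k admissible found
    m <- min(k + 8L, nv)
    sel <- row[seq_len(m)]
    sel <- sel[ok[sel] & is.finite(pre$D[q, sel])]
    while (length(sel) < k && m < nv) {
      m2 <- min(2L * m, nv)
      ext <- row[(m + 1L):m2]
      sel <- c(sel, ext[ok[ext] & is.finite(pre$D[q, ext])])
      m <- m2
    }
    if (length(sel) < k) next
    sel <- sel[seq_len(k)]
    dk <- pre$D[q, sel]
    w <- simplex_weights(dk)
    nbs[i, ] <- emb$source_index[sel]
    W[i, ] <- w
    predictions[i] <- sum(w * target[nbs[i, ] + tp])
  }
  obs <- target[emb$source_index[qs] + tp]
  good <- is.finite(predictions)
  list(rho = safe_cor(predictions, obs),
       obs_index = emb$source_index[qs[good]] + tp,
       nb_target = nbs[good, , drop = FALSE] + tp,
       weights = W[good, , drop = FALSE])
}
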