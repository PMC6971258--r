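#' Recurrence structure of a delay embedding
#'
#' The recurrence matrix marks pairs of delay vectors closer than a
#' threshold distance under the maximum norm; the threshold is chosen as
#' the `target_rate` quantile of all pairwise distances, so roughly that
#' fraction of pairs is recurrent.
#'
#' @param embedding a [delay_embed()] with at least 10 vectors.
#' @param target_rate requested recurrence rate in (0, 1).
#' @return object of class `recurrence_structure`: `threshold`, `matrix`
#'   (logical, symmetric, unit diagonal), `recurrence_rate` (achieved,
#'   off-diagonal), `target_rate`.
#' @export
recurrence_structure <- function(embedding, target_rate = 0.125) {
  stopifnot(target_rate > 0, target_rate < 1)
  V <- embedding$vectors
  nv <- nrow(V)
  if (nv < 10L) stop("need at least 10 vectors for a recurrence structure")
  D <- matrix(0, nv, nv)
  for (j in seq_len(ncol(V))) {
    D <- pmax(D, abs(outer(V[, j], V[, j], "-")))
  }
  off <- D[upper.tri(D)]
  if (all(off == 0)) stop("degenerate structure: all vectors identical")
  threshold <- stats::quantile(off, target_rate, names = FALSE, type = 7)
  R <- D <= threshold
  structure(list(threshold = threshold, matrix = R,
                 recurrence_rate = mean(R[upper.tri(R)]),
                 target_rate = target_rate),
            class = "recurrence_structure")
}

#' Twin classes of a recurrence structure
#'
#' Two delay vectors are twins when their recurrence-matrix columns are
#' identical: the dynamics cannot distinguish them at the chosen
#' resolution, so their futures are exchangeable. Singleton classes are
#' allowed.
#'
#' @param structure a [recurrence_structure()].
#' @return list with `class_id` (integer class label per vector),
#'   `n_classes`, and `sizes` (class sizes).
#' @export
find_twins <- function(structure) {
  R <- structure$matrix
  keys <- apply(R, 2L, function(col) paste(which(col), collapse = ","))
  class_id <- match(keys, unique(keys))
  list(class_id = class_id, n_classes = max(class_id),
       sizes = tabulate(class_id))
}

#' Generate twin surrogates of a (composite) series
#'
#' Twin surrogates are random trajectories on the original attractor: each
#' starts at a uniformly random delay vector and follows the original
#' successor map, except that whenever the current vector has twins the
#' successor is drawn uniformly from the successors of all members of its
#' twin class; when a vector has no successor (segment end) the trajectory
#' restarts at a random vector. The surrogate records the scalar
#' observable, so every surrogate value occurs in the original series and
#' shared dynamics — including seasonality — are preserved while the
#' specific temporal pairing with other series is destroyed. Composite
#' input yields a composite surrogate segment by segment.
#'
#' If no twin class of size >= 2 exists at `target_rate`, the rate is
#' escalated through 0.05, 0.1, 0.15, 0.2. Exact twins can remain absent in
#' short noisy series embedded at high dimension, so if every rate fails the
#' generation embedding falls back to successively smaller dimensions
#' (E - 1, ..., 1), rerunning the rate escalation at each; twins are then
#' found in practice at E <= 3. An error is raised only if every
#' (dimension, rate) combination is twinless. The fallback affects only how
#' surrogate trajectories are generated, not the embedding of the cross map
#' being tested.
#'
#' @param x a [composite_series()] or numeric vector.
#' @param E embedding dimension used for the recurrence structure
#'   (use the same E as the cross-map being tested).
#' @param target_rate requested recurrence rate (default 0.125).
#' @param n_surrogates ensemble size (default 1000).
#' @param seed optional integer seed; identical seeds give identical
#'   ensembles.
#' @param tau embedding step (default 1).
#' @param period optional seasonal period in sampling intervals (12 for
#'   monthly data with annual seasonality). When given, surrogates are
#'   phase-locked: twin exchanges are restricted to states at the same
#'   seasonal phase and trajectories start (and restart) at the calendar
#'   phase of the position being filled, so the surrogate keeps the
#'   original's calendar-aligned seasonal cycle while its anomalies are
#'   shuffled. This is what lets the test discount spurious skill due to a
#'   shared seasonal driver. Without `period`, plain twin surrogates are
#'   generated (random phase).
#' @return object of class `surrogate_ensemble`: `series` (matrix, one
#'   column per surrogate, same length as the original), `rate_used`,
#'   `n_twin_classes`, `seed`, `E`.
#' @export
twin_surrogates <- function(x, E, target_rate = 0.125, n_surrogates = 1000,
                            seed = NULL, tau = 1, period = NULL) {
  stopifnot(n_surrogates >= 1)
  comp <- as_composite(x)

  # calendar phase of each time point: within-segment position mod period
  seg_start <- c(1L, which(diff(comp$segment) != 0) + 1L)
  within_pos <- seq_along(comp$values) -
    seg_start[comp$segment] + 1L
  time_phase <- if (is.null(period)) rep(0L, length(comp$values))
                else (within_pos - 1L) %% period

  rates <- unique(c(target_rate, 0.05, 0.1, 0.15, 0.2))
  twins <- NULL
  rate_used <- E_used <- NA_real_
  for (E_try in seq(E, 1L)) {
    emb <- suppressWarnings(delay_embed(comp, E_try, tau))
    if (nrow(emb$vectors) < 10L) next
    for (r in rates) {
      str <- recurrence_structure(emb, r)
      tw <- find_twins(str)
      if (!is.null(period)) {
        # phase-locked twins: exchangeable only at the same seasonal phase
        keys <- paste(tw$class_id, time_phase[emb$source_index])
        cid <- match(keys, unique(keys))
        tw <- list(class_id = cid, n_classes = max(cid),
                   sizes = tabulate(cid))
      }
      if (any(tw$sizes >= 2L)) {
        twins <- tw; rate_used <- r; E_used <- E_try
        break
      }
    }
    if (!is.null(twins)) break
  }
  if (is.null(twins)) {
    stop("no twins found at recurrence rates ",
         paste(rates, collapse = ", "),
         " for any embedding dimension <= ", E,
         "; cannot build twin surrogates")
  }
  nv <- nrow(emb$vectors)
  vec_phase <- time_phase[emb$source_index]
  Rmat <- str$matrix

  # successor of vector i: the vector one time step later in the same segment
  key <- paste(emb$segment, emb$source_index)
  succ <- match(paste(emb$segment, emb$source_index + 1L), key)
  # candidate successors pooled over each twin class, stored flat
  cand_by_class <- lapply(seq_len(twins$n_classes), function(cl) {
    s <- succ[twins$class_id == cl]
    s[!is.na(s)]
  })
  cand_len <- lengths(cand_by_class)
  cand_start <- c(0L, cumsum(cand_len))[seq_along(cand_len)]
  cand_flat <- unlist(cand_by_class, use.names = FALSE)

  # vectors available as (re)starts, grouped by phase
  start_by_phase <- lapply(sort(unique(time_phase)), function(p) {
    v <- which(vec_phase == p)
    if (length(v) == 0L) seq_len(nv) else v
  })
  names(start_by_phase) <- sort(unique(time_phase))

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }

  draw_start <- function(m, phase) {
    pool <- start_by_phase[[as.character(phase)]]
    if (is.null(pool)) pool <- seq_len(nv)
    pool[sample.int(length(pool), m, replace = TRUE)]
  }

  # When a trajectory reaches a state without a successor (segment end), it
  # continues from the successor of a recurrence-neighbour of that state —
  # a dynamically indistinguishable point — keeping the surrogate's
  # dynamics (and, with phase locking, its calendar phase) continuous;
  # only if no such continuation exists does it restart at a random
  # (phase-matched) vector.
  continue_from <- function(prev, phase) {
    nb <- which(Rmat[prev, ])
    cands <- succ[nb]
    cands <- cands[!is.na(cands)]
    if (!is.null(period)) cands <- cands[vec_phase[cands] == phase]
    if (length(cands) == 0L) draw_start(1L, phase)
    else cands[sample.int(length(cands), 1L)]
  }

  m <- n_surrogates
  out <- matrix(NA_real_, length(comp$values), m)
  seg_lengths <- tabulate(comp$segment)
  row0 <- 0L
  for (s in seq_along(seg_lengths)) {
    cur <- rep(NA_integer_, m)
    prev <- rep(NA_integer_, m)
    for (t in seq_len(seg_lengths[s])) {
      phase_t <- if (is.null(period)) 0L else (t - 1L) %% period
      dead <- which(is.na(cur))
      for (i in dead) {
        cur[i] <- if (is.na(prev[i])) draw_start(1L, phase_t)
                  else continue_from(prev[i], phase_t)
      }
      out[row0 + t, ] <- comp$values[emb$source_index[cur]]
      cls <- twins$class_id[cur]
      len <- cand_len[cls]
      nxt <- rep(NA_integer_, m)
      has <- len > 0L
      if (any(has)) {
        pick <- cand_start[cls[has]] + 1L +
          as.integer(floor(stats::runif(sum(has)) * len[has]))
        nxt[has] <- cand_flat[pick]
      }
      prev <- cur
      cur <- nxt  # NA entries are resolved at the top of the next step
    }
    row0 <- row0 + seg_lengths[s]
  }
  structure(list(series = out, rate_used = rate_used,
                 n_twin_classes = twins$n_classes,
                 twin_class_sizes = twins$sizes,
                 seed = seed, E = E, E_used = E_used, period = period,
                 n_surrogates = m),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat("Twin-surrogate ensemble:", x$n_surrogates, "surrogates of length",
      nrow(x$series), "\n  recurrence rate used:", x$rate_used,
      "; twin classes of size >= 2:", sum(x$twin_class_sizes >= 2), "\n")
  invisible(x)
}

#' Surrogate significance decision
#'
#' Compares an observed cross-map skill with the empirical 95th percentile
#' (linear-interpolation quantile) of the surrogate skill distribution; the
#' skill is significant when it exceeds the bound.
#'
#' @param rho_observed observed cross-map skill.
#' @param ensemble_skills numeric vector of surrogate skills.
#' @param level upper-quantile level (default 0.95).
#' @return list with `significant` (logical) and `bound` (numeric).
#' @export
significance_test <- function(rho_observed, ensemble_skills, level = 0.95) {
  skills <- ensemble_skills[is.finite(ensemble_skills)]
  if (length(skills) == 0L) stop("ensemble_skills is empty")
  bound <- stats::quantile(skills, level, names = FALSE, type = 7)
  list(significant = is.finite(rho_observed) && rho_observed > bound,
       bound = bound)
}
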