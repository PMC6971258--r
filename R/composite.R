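#' Standardise replicate series into one composite (dewdrop-style)
#'
#' Short replicate series (one per tree) are each independently centred and
#' scaled to unit variance and then concatenated, recording where each
#' replicate (segment) begins. Downstream delay embeddings never span a
#' segment boundary, so the replicates contribute library points without
#' fabricating dynamics across trees. Constant replicates are centred only
#' and flagged.
#'
#' @param x a numeric vector (one replicate), or a list of numeric vectors
#'   (one per replicate, each of length >= 2).
#' @param names optional replicate labels.
#' @return object of class `composite_series`: list with `values`
#'   (standardised, concatenated), `segment` (integer replicate label per
#'   observation), `segment_names`, and `constant` (flag per replicate).
#' @examples
#' composite_series(list(t1 = sin(1:42), t2 = cos(1:42)))
#' @export
composite_series <- function(x, names = NULL) {
  if (is.numeric(x)) x <- list(x)
  if (!is.list(x) || length(x) == 0L) stop("need at least one replicate")
  if (any(vapply(x, length, 1L) < 2L)) {
    stop("each replicate must have length >= 2")
  }
  if (is.null(names)) {
    names <- if (!is.null(base::names(x))) base::names(x)
             else paste0("seg", seq_along(x))
  }
  std <- lapply(x, function(v) {
    v <- as.numeric(v)
    m <- mean(v, na.rm = TRUE)
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) list(v = v - m, const = TRUE)
    else list(v = (v - m) / s, const = FALSE)
  })
  structure(list(
    values = unlist(lapply(std, `[[`, "v"), use.names = FALSE),
    segment = rep(seq_along(x), vapply(x, length, 1L)),
    segment_names = names,
    constant = vapply(std, `[[`, logical(1), "const")),
    class = "composite_series")
}

#' @export
print.composite_series <- function(x, ...) {
  cat("Composite series:", length(x$values), "points in",
      length(x$segment_names), "segment(s)\n")
  cat("  segments:", paste(x$segment_names, "(",
      tabulate(x$segment), ")", collapse = ", "), "\n")
  if (any(x$constant)) {
    cat("  constant segments:",
        paste(x$segment_names[x$constant], collapse = ", "), "\n")
  }
  invisible(x)
}

as_composite <- function(x) {
  if (inherits(x, "composite_series")) x else composite_series(x)
}

#' Extract one variable of a trait dataset as a composite series
#'
#' @param dataset a [trait_dataset()].
#' @param variable column name (`"V"`, `"G"`, `"starch"`, `"sugar"`).
#' @param treatment optional filter (`"NAT"` or `"PFT"`).
#' @return a [composite_series()] with one segment per tree. All sampling
#'   dates are kept so composites of different variables stay aligned;
#'   undefined entries (e.g. `G` at each tree's first date) remain `NA` and
#'   are excluded from delay vectors downstream.
#' @export
composite_from_dataset <- function(dataset, variable,
                                   treatment = NULL) {
  stopifnot(variable %in% names(dataset))
  if (!is.null(treatment)) dataset <- dataset[dataset$treatment %in% treatment, ]
  if (nrow(dataset) == 0L) stop("no rows after treatment filter")
  split_by_tree <- split(dataset, dataset$tree_id)
  series <- lapply(split_by_tree, function(d) d[[variable]][order(d$date)])
  composite_series(series, names = names(split_by_tree))
}

#' Segment-aware Takens delay embedding
#'
#' Builds E-dimensional delay vectors \eqn{(x_t, x_{t-\tau}, \ldots,
#' x_{t-(E-1)\tau})} within each segment of a composite series; no vector
#' spans a segment boundary, and vectors containing missing coordinates are
#' dropped.
#'
#' @param x a [composite_series()] or numeric vector.
#' @param E embedding dimension (>= 1).
#' @param tau embedding step in sampling intervals (default 1).
#' @return object of class `delay_embedding`: `vectors` (matrix, one row
#'   per delay vector, most recent coordinate first), `source_index` (time
#'   index of the most recent coordinate), `segment` (per vector),
#'   `time_segment` (per time point), `E`, `tau`, `n` (composite length).
#' @export
delay_embed <- function(x, E, tau = 1) {
  stopifnot(E >= 1, tau >= 1)
  comp <- as_composite(x)
  n <- length(comp$values)
  span <- (E - 1L) * tau
  src <- integer(0)
  for (s in unique(comp$segment)) {
    idx <- which(comp$segment == s)
    if (length(idx) < span + 1L) {
      warning("segment ", comp$segment_names[s],
              " is too short for E = ", E, ", tau = ", tau,
              "; it contributes no vectors")
      next
    }
    src <- c(src, idx[(span + 1L):length(idx)])
  }
  if (length(src) > 0L) {
    vecs <- vapply(0:(E - 1L), function(j) comp$values[src - j * tau],
                   numeric(length(src)))
    vecs <- matrix(vecs, nrow = length(src), ncol = E)
    keep <- !apply(is.na(vecs), 1L, any)
    vecs <- vecs[keep, , drop = FALSE]
    src <- src[keep]
  } else {
    vecs <- matrix(numeric(0), 0L, E)
  }
  structure(list(vectors = vecs, source_index = src,
                 segment = comp$segment[src],
                 time_segment = comp$segment,
                 values = comp$values,
                 E = E, tau = tau, n = n),
            class = "delay_embedding")
}

#' @export
print.delay_embedding <- function(x, ...) {
  cat("Delay embedding: E =", x$E, ", tau =", x$tau, ",",
      nrow(x$vectors), "vectors from", x$n, "points\n")
  invisible(x)
}

# Which source indices have a defined target value at offset tp
# (within series bounds, same segment, not NA)?
valid_offset <- function(embedding, target, tp, src = embedding$source_index) {
  ti <- src + tp
  ok <- ti >= 1L & ti <= embedding$n
  ok[ok] <- embedding$time_segment[ti[ok]] == embedding$time_segment[src[ok]] &
    !is.na(target[ti[ok]])
  ok
}
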