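# Independent oracles, written with plain loops so they share no code path
# with the package internals they check.

# Brute-force simplex projection: all-pairs distances, explicit sort,
# explicit weight rule. Returns neighbours (library row indices), weights
# and predictions for each query.
brute_simplex <- function(vectors, src, segment, target, tp, lib, pred, k) {
  n <- length(target)
  valid <- function(i) {
    ti <- src[i] + tp
    ti >= 1 && ti <= n && !is.na(target[ti]) &&
      segment_of_time(ti) == segment_of_time(src[i])
  }
  # map a time index to its segment via the source/segment pairs
  segment_of_time <- function(ti) seg_by_time[ti]
  seg_by_time <- rep(NA_integer_, n)
  # reconstruct: time points of a segment are contiguous; fill from vectors
  for (i in seq_along(src)) seg_by_time[src[i]] <- segment[i]
  # fill gaps (leading points of each segment share that segment)
  for (t in rev(seq_len(n - 1))) {
    if (is.na(seg_by_time[t]) && !is.na(seg_by_time[t + 1])) {
      seg_by_time[t] <- seg_by_time[t + 1]
    }
  }
  lib <- lib[vapply(lib, valid, logical(1))]
  pred <- pred[vapply(pred, valid, logical(1))]
  out <- list(pred = pred, neighbors = NULL, weights = NULL,
              predictions = numeric(0), obs = numeric(0))
  nb <- matrix(NA_integer_, length(pred), k)
  wt <- matrix(NA_real_, length(pred), k)
  ph <- numeric(length(pred))
  for (qi in seq_along(pred)) {
    q <- pred[qi]
    d <- numeric(length(lib))
    for (li in seq_along(lib)) {
      l <- lib[li]
      if (src[l] == src[q]) { d[li] <- Inf; next }
      d[li] <- sqrt(sum((vectors[q, ] - vectors[l, ])^2))
    }
    ord <- order(d, lib)
    sel <- ord[seq_len(k)]
    dk <- d[sel]
    d1 <- dk[1]
    if (d1 == 0) {
      pos <- dk[dk > 0]
      d1 <- if (length(pos) > 0) min(pos) else 1
    }
    w <- exp(-dk / d1)
    w <- w / sum(w)
    nb[qi, ] <- lib[sel]
    wt[qi, ] <- w
    ph[qi] <- sum(w * target[src[lib[sel]] + tp])
  }
  out$neighbors <- nb
  out$weights <- wt
  out$predictions <- ph
  out$obs <- target[src[pred] + tp]
  out
}

# NOAA-style day length: Spencer declination series + refraction-corrected
# hour angle (zenith 90.833 degrees).
noaa_day_length <- function(lat, date) {
  doy <- as.integer(format(as.Date(date), "%j"))
  g <- 2 * pi / 365 * (doy - 1)
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  phi <- lat * pi / 180
  cosw <- (cos(90.833 * pi / 180) - sin(phi) * sin(decl)) /
    (cos(phi) * cos(decl))
  cosw <- pmin(1, pmax(-1, cosw))
  2 * acos(cosw) * 180 / pi / 15
}

logistic_series <- function(n, r = 3.8, x0 = 0.31) {
  x <- numeric(n)
  x[1] <- x0
  for (t in seq_len(n - 1)) x[t + 1] <- r * x[t] * (1 - x[t])
  x
}

ar1_series <- function(n, phi = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as.numeric(stats::arima.sim(list(ar = phi), n))
}
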