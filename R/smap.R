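#' S-map scan for state-dependent (nonlinear) dynamics
#'
#' Leave-one-out locally weighted linear forecasting of a series one step
#' ahead, across a grid of nonlinearity parameters theta. For each query
#' delay vector, library vectors are weighted by
#' \eqn{w_i = \exp(-\theta d_i / \bar d)} (with \eqn{\bar d} the query's
#' mean distance to the library) and a weighted linear map is fitted by
#' least squares; singular local regressions are solved in the
#' least-squares sense via the pseudo-inverse. At \eqn{\theta = 0} every
#' point gets equal weight, so the forecast reduces to one global linear
#' map; skill improving at \eqn{\theta > 0} signals state dependence, i.e.
#' nonlinear dynamics.
#'
#' @param x a [composite_series()] or numeric vector.
#' @param E embedding dimension.
#' @param theta grid of nonlinearity parameters; must contain 0 and at
#'   least one positive value.
#' @param tau embedding step.
#' @param tp forecast offset (default +1, one step ahead).
#' @return object of class `smap_scan`: `theta`, `rho` (skill per theta),
#'   `rho0` (skill at theta = 0), `delta_rho` (max over theta > 0 of
#'   `rho(theta) - rho(0)`), `nonlinear` (`delta_rho > 0`), `E`.
#' @examples
#' x <- numeric(300); x[1] <- 0.4
#' for (t in 1:299) x[t + 1] <- 3.8 * x[t] * (1 - x[t])
#' smap_scan(x, E = 2)
#' @export
smap_scan <- function(x, E,
                      theta = c(0, 0.1, 0.3, 0.5, 0.75, 1, 1.5, 2, 3, 4,
                                6, 8),
                      tau = 1, tp = 1) {
  if (!0 %in% theta || !any(theta > 0)) {
    stop("theta grid must contain 0 and at least one positive value")
  }
  theta <- sort(unique(theta))
  comp <- as_composite(x)
  emb <- delay_embed(comp, E, tau)
  target <- comp$values
  ok <- valid_offset(emb, target, tp)
  qs <- which(ok)
  if (length(qs) < E + 2L) stop("series too short for S-map at E = ", E)

  D <- dist_euclid(emb$vectors, emb$vectors)
  same <- outer(emb$source_index, emb$source_index, "==")
  y_all <- target[emb$source_index + tp]

  rho <- vapply(theta, function(th) {
    preds <- rep(NA_real_, length(qs))
    for (i in seq_along(qs)) {
      q <- qs[i]
      use <- ok & !same[q, ]
      if (sum(use) < E + 2L) next
      d <- D[q, use]
      dbar <- mean(d)
      w <- if (th == 0 || dbar == 0) rep(1, length(d)) else exp(-th * d / dbar)
      A <- cbind(1, emb$vectors[use, , drop = FALSE])
      coef <- wls_pinv(A, y_all[use], w)
      preds[i] <- sum(c(1, emb$vectors[q, ]) * coef)
    }
    safe_cor(preds, y_all[qs])
  }, numeric(1))

  rho0 <- rho[theta == 0]
  delta_rho <- max(rho[theta > 0], na.rm = TRUE) - rho0
  structure(list(theta = theta, rho = rho, rho0 = rho0,
                 delta_rho = delta_rho,
                 nonlinear = is.finite(delta_rho) && delta_rho > 0,
                 E = E, tp = tp),
            class = "smap_scan")
}

# weighted least squares via SVD pseudo-inverse (rank-deficient safe)
wls_pinv <- function(A, y, w) {
  sw <- sqrt(w)
  Aw <- A * sw
  yw <- y * sw
  sv <- svd(Aw)
  tol <- max(dim(Aw)) * max(sv$d) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  sv$v %*% (dinv * (t(sv$u) %*% yw))
}

#' @export
print.smap_scan <- function(x, digits = 4, ...) {
  cat("S-map scan (E =", x$E, ")\n")
  print(data.frame(theta = x$theta, rho = round(x$rho, digits)),
        row.names = FALSE)
  cat("delta_rho =", format(x$delta_rho, digits = digits),
      if (x$nonlinear) "-> nonlinear" else "-> no nonlinearity detected",
      "\n")
  invisible(x)
}

#' @export
plot.smap_scan <- function(x, ...) {
  plot(x$theta, x$rho, type = "b", xlab = expression(theta),
       ylab = expression(rho), main = "S-map nonlinearity scan", ...)
  abline(h = x$rho0, lty = 2, col = "grey40")
  invisible(x)
}
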