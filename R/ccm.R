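#' Convergent cross mapping between two composite series
#'
#' Fits the cross map from a library series to a target series: delay
#' vectors of the library reconstruct the system state, and simplex
#' projection predicts the target at offset `tp` from each state. High
#' skill (Pearson rho between predictions and observations) that increases
#' ("converges") with library size is evidence that the target variable
#' causally forces the library variable, because the effect's attractor
#' encodes the cause's history.
#'
#' Skill at the full library is computed leave-one-out over all delay
#' vectors. At each sub-maximal library size L, `n_draws` random subsets of
#' L vectors (without replacement, seeded) serve as library; the full set
#' is used deterministically at the largest size. Optionally a twin-
#' surrogate ensemble provides a 95% significance bound.
#'
#' @param library,target [composite_series()] (or numeric vectors / lists
#'   of replicate vectors) on the same time grid.
#' @param E embedding dimension; `NULL` selects it by [select_E()] over
#'   `E_range` at `tp = -1`.
#' @param tp prediction offset in sampling intervals; negative values mean
#'   the target (putative cause) leads the library.
#' @param tau embedding step (default 1).
#' @param lib_sizes increasing library sizes; `NULL` gives 15
#'   logarithmically spaced sizes from `E + 2` to the full vector count;
#'   `NA` skips the library-size scan (full library only).
#' @param n_draws random library draws per sub-maximal size (default 100).
#' @param surrogates twin-surrogate ensemble size for the significance
#'   bound (0 = no test).
#' @param surrogate_rate recurrence rate for the surrogates.
#' @param surrogate_of which series is replaced by surrogates: the
#'   `"target"` (default; destroys the putative causal signal while keeping
#'   its dynamics and seasonality) or the `"library"`.
#' @param surrogate_period seasonal period (sampling intervals) for
#'   phase-locked surrogates; `NULL` for plain twin surrogates. Use 12 for
#'   monthly data with annual seasonality so a shared seasonal driver is
#'   absorbed into the null.
#' @param seed integer seed for library draws and surrogates.
#' @param E_range candidate dimensions for automatic E selection.
#' @param library_name,target_name labels used in printing and tables.
#' @return object of class `ccm` with elements `rho` (full-library skill),
#'   `E`, `tp`, `library_sizes`, `draws` (data frame `L`, `draw`, `rho`),
#'   `bound_95`, `significant`, `surrogate_skills`, `convergent`, and the
#'   series names.
#' @seealso [lag_scan()], [convergence_check()], [significance_test()]
#' @examples
#' sim <- simulate_coupled_logistic(n = 200, beta_yx = 0.32, seed = 1)
#' cross_map(sim$y, sim$x, E = 2, tp = -1, lib_sizes = NA)
#' @export
cross_map <- function(library, target, E = NULL, tp = 0, tau = 1,
                      lib_sizes = NULL, n_draws = 100, surrogates = 0,
                      surrogate_rate = 0.125,
                      surrogate_of = c("target", "library"),
                      surrogate_period = NULL,
                      seed = NULL, E_range = 2:8,
                      library_name = "library", target_name = "target") {
  surrogate_of <- match.arg(surrogate_of)
  lib_comp <- as_composite(library)
  tgt_comp <- as_composite(target)
  if (length(lib_comp$values) != length(tgt_comp$values)) {
    stop("library and target composites must share the same time grid")
  }
  E_selected <- is.null(E)
  if (E_selected) E <- select_E(lib_comp, tgt_comp, E_range, tau = tau)
  emb <- delay_embed(lib_comp, E, tau)
  nv <- nrow(emb$vectors)
  if (nv < E + 2L) stop("composite too short after embedding (", nv,
                        " vectors for E = ", E, ")")

  full <- simplex_predict(emb, tgt_comp, tp = tp)
  rho_full <- full$rho

  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }

  draws <- NULL
  if (is.null(lib_sizes)) lib_sizes <- default_lib_sizes(E, nv)
  if (!anyNA(lib_sizes)) {
    lib_sizes <- sort(unique(pmin(as.integer(lib_sizes), nv)))
    if (any(lib_sizes < E + 2L)) stop("library sizes below E + 2")
    rows <- list()
    for (L in lib_sizes) {
      if (L >= nv) {
        rows[[length(rows) + 1L]] <- data.frame(L = L, draw = 1L,
                                                rho = rho_full)
      } else {
        r <- vapply(seq_len(n_draws), function(d) {
          idx <- sample.int(nv, L)
          tryCatch(simplex_predict(emb, tgt_comp, tp = tp, lib = idx)$rho,
                   error = function(e) NA_real_)
        }, numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(L = L,
                                                draw = seq_len(n_draws),
                                                rho = r)
      }
    }
    draws <- do.call(rbind, rows)
  } else {
    lib_sizes <- nv
  }

  bound <- NA_real_; significant <- NA; skills <- NULL
  if (surrogates > 0L) {
    surr_seed <- if (is.null(seed)) NULL else seed + 1L
    if (surrogate_of == "target") {
      ens <- twin_surrogates(tgt_comp, E = E, target_rate = surrogate_rate,
                             n_surrogates = surrogates, seed = surr_seed,
                             tau = tau, period = surrogate_period)
      # when E was chosen by maximising skill, the null must undergo the
      # same maximisation, or the selection step inflates significance
      skills <- if (E_selected) {
        max_skills_over_E(lib_comp, tgt_comp, E_range, tp, tau,
                          ens$series)
      } else {
        surrogate_skills(full, ens$series)
      }
    } else {
      ens <- twin_surrogates(lib_comp, E = E, target_rate = surrogate_rate,
                             n_surrogates = surrogates, seed = surr_seed,
                             tau = tau, period = surrogate_period)
      skills <- apply(ens$series, 2L, function(s) {
        se <- delay_embed(composite_raw(s, lib_comp), E, tau)
        tryCatch(simplex_predict(se, tgt_comp, tp = tp)$rho,
                 error = function(e) NA_real_)
      })
    }
    st <- significance_test(rho_full, skills)
    bound <- st$bound
    significant <- st$significant
  }

  convergent <- if (!is.null(draws) &&
                    length(unique(draws$L)) >= 3L)
    convergence_check(draws) else NA

  structure(list(library_name = library_name, target_name = target_name,
                 E = E, tp = tp, tau = tau, rho = rho_full,
                 library_sizes = lib_sizes, draws = draws,
                 n_vectors = nv,
                 bound_95 = bound, significant = significant,
                 surrogate_skills = skills, convergent = convergent),
            class = "ccm")
}

# Per-surrogate cross-map skill maximised over the candidate embedding
# dimensions, mirroring data-driven E selection in the null distribution.
max_skills_over_E <- function(lib_comp, tgt_comp, E_range, tp, tau, S) {
  mat <- NULL
  for (Ei in E_range) {
    s <- tryCatch({
      emb <- suppressWarnings(delay_embed(lib_comp, Ei, tau))
      fit <- simplex_predict(emb, tgt_comp, tp = tp)
      surrogate_skills(fit, S)
    }, error = function(e) NULL)
    if (is.null(s)) next
    mat <- rbind(mat, s)
  }
  if (is.null(mat)) stop("surrogate skills undefined for every E")
  apply(mat, 2L, function(col) {
    if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE)
  })
}

# composite with given values but the segment layout of a template
composite_raw <- function(values, template) {
  structure(list(values = values, segment = template$segment,
                 segment_names = template$segment_names,
                 constant = template$constant),
            class = "composite_series")
}

default_lib_sizes <- function(E, nv) {
  lo <- E + 2L
  if (nv <= lo) return(nv)
  sort(unique(round(exp(seq(log(lo), log(nv), length.out = 15L)))))
}

# Cross-map skill against each column of a surrogate matrix, reusing the
# neighbour structure of a full-library simplex fit: predictions are the
# fixed weighted sums evaluated on the surrogate values, observations the
# surrogate values at the original observation indices. `tp` is already
# baked into the fit's indices.
surrogate_skills <- function(fit, S, tp = 0) {
  obs_i <- fit$predictions$source + fit$tp
  nbt <- fit$nb_source + fit$tp
  W <- fit$weights
  P <- matrix(0, nrow(nbt), ncol(S))
  for (j in seq_len(ncol(W))) {
    P <- P + W[, j] * S[nbt[, j], , drop = FALSE]
  }
  O <- S[obs_i, , drop = FALSE]
  col_cor(P, O)
}

col_cor <- function(A, B) {
  cA <- sweep(A, 2L, colMeans(A))
  cB <- sweep(B, 2L, colMeans(B))
  den <- sqrt(colSums(cA^2) * colSums(cB^2))
  out <- colSums(cA * cB) / den
  out[den == 0] <- NA_real_
  out
}

#' Select the embedding dimension by cross-map skill
#'
#' Cross-maps the target from the library at a fixed full library and
#' `tp = -1` for each candidate dimension and returns the E with maximum
#' skill; exact ties break toward the smallest E.
#'
#' @param library,target composite series (or coercibles).
#' @param E_range candidate dimensions (default 2:8).
#' @param tp offset used during selection (default -1).
#' @param tau embedding step.
#' @return the selected E (integer).
#' @export
select_E <- function(library, target, E_range = 2:8, tp = -1, tau = 1) {
  stopifnot(length(E_range) >= 1)
  E_range <- sort(unique(as.integer(E_range)))
  lib_comp <- as_composite(library)
  tgt_comp <- as_composite(target)
  rho <- vapply(E_range, function(E) {
    tryCatch({
      emb <- delay_embed(lib_comp, E, tau)
      simplex_predict(emb, tgt_comp, tp = tp)$rho
    }, error = function(e) NA_real_, warning = function(w) NA_real_)
  }, numeric(1))
  if (all(is.na(rho))) {
    stop("cross-map skill undefined for every E (constant target?)")
  }
  E_range[which.max(rho)]
}

#' Cross mapping over a grid of time lags
#'
#' Runs [cross_map()] at each lag and reports the lag with maximum
#' full-library skill (ties toward the most negative lag). One surrogate
#' ensemble per scan is reused across lags by default, since the surrogate
#' series does not depend on the lag; set `regenerate_per_lag = TRUE` to
#' rebuild it at every lag.
#'
#' @inheritParams cross_map
#' @param lags ordered set of offsets (months), e.g. `-6:6`.
#' @param regenerate_per_lag logical; regenerate the surrogate ensemble at
#'   each lag.
#' @return object of class `ccm_lag_scan`: `results` (list of `ccm`, one
#'   per lag), `table` (data frame `tp`, `rho`, `bound_95`, `significant`),
#'   `best_lag`, `E`.
#' @export
lag_scan <- function(library, target, E = NULL, lags = -6:6, tau = 1,
                     lib_sizes = NA, n_draws = 100, surrogates = 0,
                     surrogate_rate = 0.125,
                     surrogate_of = c("target", "library"),
                     surrogate_period = NULL,
                     regenerate_per_lag = FALSE,
                     seed = NULL, E_range = 2:8,
                     library_name = "library", target_name = "target") {
  if (length(lags) == 0L) stop("empty lag set")
  surrogate_of <- match.arg(surrogate_of)
  lags <- sort(unique(as.integer(lags)))
  lib_comp <- as_composite(library)
  tgt_comp <- as_composite(target)
  E_selected <- is.null(E)
  if (E_selected) E <- select_E(lib_comp, tgt_comp, E_range, tau = tau)

  ens <- NULL
  if (surrogates > 0L && !regenerate_per_lag && surrogate_of == "target") {
    ens <- twin_surrogates(tgt_comp, E = E, target_rate = surrogate_rate,
                           n_surrogates = surrogates,
                           seed = if (is.null(seed)) NULL else seed + 1L,
                           tau = tau, period = surrogate_period)
  }

  if (anyNA(lib_sizes) && (surrogates == 0L || !is.null(ens))) {
    # full-library skill only: share one kNN precomputation across lags
    emb <- delay_embed(lib_comp, E, tau)
    pre <- knn_precompute(emb)
    k <- E + 1L
    # if E was selected by maximising skill, the null mirrors the
    # selection: per-surrogate skills are maximised over the E range
    pres_null <- if (!is.null(ens) && E_selected) {
      lapply(E_range, function(Ei) {
        tryCatch(knn_precompute(suppressWarnings(
          delay_embed(lib_comp, Ei, tau))), error = function(e) NULL)
      })
    } else NULL
    results <- lapply(lags, function(tp) {
      fit <- fast_skill(pre, tgt_comp, tp, k)
      bound <- NA_real_; significant <- NA; skills <- NULL
      if (!is.null(ens) && is.finite(fit$rho)) {
        skills <- if (!is.null(pres_null)) {
          mat <- NULL
          for (j in seq_along(pres_null)) {
            pj <- pres_null[[j]]
            if (is.null(pj)) next
            fj <- fast_skill(pj, tgt_comp, tp, E_range[j] + 1L)
            if (!is.finite(fj$rho)) next
            mat <- rbind(mat, fast_surrogate_skills(fj, ens$series))
          }
          if (is.null(mat)) fast_surrogate_skills(fit, ens$series)
          else apply(mat, 2L, function(col) {
            if (all(is.na(col))) NA_real_ else max(col, na.rm = TRUE)
          })
        } else {
          fast_surrogate_skills(fit, ens$series)
        }
        st <- significance_test(fit$rho, skills)
        bound <- st$bound; significant <- st$significant
      }
      structure(list(library_name = library_name,
                     target_name = target_name,
                     E = E, tp = tp, tau = tau, rho = fit$rho,
                     library_sizes = nrow(emb$vectors), draws = NULL,
                     n_vectors = nrow(emb$vectors),
                     bound_95 = bound, significant = significant,
                     surrogate_skills = skills, convergent = NA),
                class = "ccm")
    })
  } else {
    results <- lapply(lags, function(tp) {
      cm <- cross_map(lib_comp, tgt_comp, E = E, tp = tp, tau = tau,
                      lib_sizes = lib_sizes, n_draws = n_draws,
                      surrogates = if (is.null(ens)) surrogates else 0,
                      surrogate_rate = surrogate_rate,
                      surrogate_of = surrogate_of,
                      surrogate_period = surrogate_period,
                      seed = if (is.null(seed)) NULL else seed + tp,
                      library_name = library_name,
                      target_name = target_name)
      if (!is.null(ens) && !is.na(cm$rho)) {
        emb <- delay_embed(lib_comp, E, tau)
        full <- simplex_predict(emb, tgt_comp, tp = tp)
        skills <- surrogate_skills(full, ens$series)
        st <- significance_test(cm$rho, skills)
        cm$bound_95 <- st$bound
        cm$significant <- st$significant
        cm$surrogate_skills <- skills
      }
      cm
    })
  }
  names(results) <- as.character(lags)
  tab <- data.frame(
    tp = lags,
    rho = vapply(results, function(r) r$rho, numeric(1)),
    bound_95 = vapply(results, function(r) r$bound_95, numeric(1)),
    significant = vapply(results, function(r) isTRUE(r$significant),
                         logical(1)))
  rho_cmp <- ifelse(is.na(tab$rho), -Inf, tab$rho)
  best_lag <- lags[which.max(rho_cmp)]  # lags ascending: ties -> most negative
  structure(list(results = results, table = tab, best_lag = best_lag,
                 E = E, library_name = library_name,
                 target_name = target_name),
            class = "ccm_lag_scan")
}

#' Library-size convergence of cross-map skill
#'
#' A cross map "converges" when skill grows with the amount of library used:
#' the median skill at the largest library must exceed the median at the
#' smallest, and the Kendall rank correlation between library size and
#' median skill must be positive.
#'
#' @param x a `ccm` object or a data frame with columns `L` and `rho`.
#' @return logical flag (`FALSE`, with a warning, on degenerate input).
#' @export
convergence_check <- function(x) {
  draws <- if (inherits(x, "ccm")) x$draws else x
  if (is.null(draws) || !all(c("L", "rho") %in% names(draws))) {
    warning("no library-size draws available; convergence undefined")
    return(FALSE)
  }
  med <- tapply(draws$rho, draws$L, stats::median, na.rm = TRUE)
  L <- as.numeric(names(med))
  if (length(L) < 3L || anyNA(med)) {
    warning("degenerate library-size scan; convergence set to FALSE")
    return(FALSE)
  }
  tau_k <- suppressWarnings(stats::cor(L, as.numeric(med),
                                       method = "kendall"))
  isTRUE(med[[length(med)]] > med[[1L]]) && isTRUE(tau_k > 0)
}

#' @export
print.ccm <- function(x, digits = 4, ...) {
  cat("Convergent cross mapping:", x$library_name, "xmap", x$target_name,
      "\n  E =", x$E, ", tp =", x$tp, ",", x$n_vectors, "vectors\n")
  cat("  full-library rho =", format(x$rho, digits = digits), "\n")
  if (!is.na(x$bound_95)) {
    cat("  95% twin-surrogate bound =", format(x$bound_95, digits = digits),
        "->", if (isTRUE(x$significant)) "significant"
        else "not significant", "\n")
  }
  if (!is.na(x$convergent)) {
    cat("  convergent with library size:", x$convergent, "\n")
  }
  invisible(x)
}

#' @export
summary.ccm <- function(object, ...) {
  med <- if (!is.null(object$draws)) {
    m <- tapply(object$draws$rho, object$draws$L, stats::median, na.rm = TRUE)
    data.frame(L = as.numeric(names(m)), median_rho = as.numeric(m))
  } else NULL
  structure(list(ccm = object, by_size = med), class = "summary.ccm")
}

#' @export
print.summary.ccm <- function(x, ...) {
  print(x$ccm)
  if (!is.null(x$by_size)) {
    cat("  median skill by library size:\n")
    print(x$by_size, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.ccm <- function(x, ...) {
  if (is.null(x$draws)) {
    stop("no library-size scan to plot; rerun with lib_sizes = NULL")
  }
  med <- tapply(x$draws$rho, x$draws$L, stats::median, na.rm = TRUE)
  L <- as.numeric(names(med))
  plot(L, med, type = "b", xlab = "library size L",
       ylab = expression(rho),
       main = paste(x$library_name, "xmap", x$target_name), ...)
  if (!is.na(x$bound_95)) abline(h = x$bound_95, lty = 2, col = "grey40")
  invisible(x)
}

#' @export
print.ccm_lag_scan <- function(x, digits = 3, ...) {
  cat("Lagged cross mapping:", x$library_name, "xmap", x$target_name,
      "(E =", paste0(x$E, ")"), "\n")
  tab <- x$table
  tab$rho <- round(tab$rho, digits)
  tab$bound_95 <- round(tab$bound_95, digits)
  print(tab, row.names = FALSE)
  cat("best lag (max rho):", x$best_lag, "\n")
  invisible(x)
}

#' @export
plot.ccm_lag_scan <- function(x, ...) {
  tab <- x$table
  plot(tab$tp, tab$rho, type = "b", xlab = "time lag tp (months)",
       ylab = expression(rho),
       main = paste(x$library_name, "xmap", x$target_name), ...)
  if (any(is.finite(tab$bound_95))) {
    lines(tab$tp, tab$bound_95, lty = 2, col = "grey40")
  }
  abline(v = x$best_lag, col = "grey70", lty = 3)
  invisible(x)
}
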