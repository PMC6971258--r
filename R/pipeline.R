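#' Analysis configuration
#'
#' Collects every tunable of the full causal analysis. Defaults follow the
#' study design this package implements: biological lags -6..+6 months,
#' climate lags -8..+8 months, cumulative windows 1..60 days, embedding
#' dimensions 2..8 selected at tp = -1, 1000 twin surrogates at recurrence
#' rate 0.125, and 100 random library draws per sub-maximal library size.
#'
#' @param treatment treatment(s) analysed (`"NAT"`, `"PFT"`).
#' @param bio_lags lag grid for trait-trait cross mapping (months).
#' @param climate_lags lag grid for climate-trait cross mapping (months).
#' @param windows cumulative window lengths in days.
#' @param E_range candidate embedding dimensions.
#' @param tau embedding step (sampling intervals).
#' @param n_surrogates twin-surrogate ensemble size (0 disables testing).
#' @param surrogate_rate recurrence rate for twin surrogates.
#' @param surrogate_of `"target"` or `"library"`: which series is
#'   surrogated.
#' @param surrogate_period seasonal period (sampling intervals) for
#'   phase-locked twin surrogates; default 12 (monthly data, annual
#'   seasonality). `NULL` disables phase locking.
#' @param n_draws library draws per sub-maximal size in convergence scans.
#' @param lib_sizes library-size grid (`NULL` = automatic log-spaced grid).
#' @param screen_windows window lengths at which cumulative drivers enter
#'   the S-map nonlinearity screen.
#' @param reference_window window length at which E is selected for
#'   climate cross maps.
#' @param dotted_threshold number of non-significant windows within a term
#'   above which the term's best skill is flagged "dotted" in the summary.
#' @param seed integer seed for all randomised steps.
#' @return object of class `ccm_config` (a validated list).
#' @export
ccm_config <- function(treatment = "NAT", bio_lags = -6:6,
                       climate_lags = -8:8, windows = 1:60,
                       E_range = 2:8, tau = 1, n_surrogates = 1000,
                       surrogate_rate = 0.125,
                       surrogate_of = c("target", "library"),
                       surrogate_period = 12,
                       n_draws = 100, lib_sizes = NULL,
                       screen_windows = c(1, 10, 20, 30, 40, 50, 60),
                       reference_window = 30, dotted_threshold = 5,
                       seed = 1) {
  surrogate_of <- match.arg(surrogate_of)
  stopifnot(length(bio_lags) >= 1, length(climate_lags) >= 1,
            length(windows) >= 1, all(windows >= 1),
            length(E_range) >= 1, n_surrogates >= 0, n_draws >= 1,
            dotted_threshold >= 0)
  structure(list(treatment = treatment,
                 bio_lags = sort(unique(as.integer(bio_lags))),
                 climate_lags = sort(unique(as.integer(climate_lags))),
                 windows = sort(unique(as.integer(windows))),
                 E_range = sort(unique(as.integer(E_range))),
                 tau = tau, n_surrogates = n_surrogates,
                 surrogate_rate = surrogate_rate,
                 surrogate_of = surrogate_of,
                 surrogate_period = surrogate_period, n_draws = n_draws,
                 lib_sizes = lib_sizes,
                 screen_windows = sort(unique(as.integer(screen_windows))),
                 reference_window = as.integer(reference_window),
                 dotted_threshold = dotted_threshold,
                 seed = as.integer(seed)),
            class = "ccm_config")
}

#' @export
print.ccm_config <- function(x, ...) {
  cat("CCM analysis configuration\n")
  cat("  treatment:", paste(x$treatment, collapse = "/"),
      "| E range:", paste(range(x$E_range), collapse = "-"),
      "| tau:", x$tau, "\n")
  cat("  lags: biological", paste(range(x$bio_lags), collapse = ".."),
      ", climate", paste(range(x$climate_lags), collapse = ".."),
      "| windows:", paste(range(x$windows), collapse = ".."), "days\n")
  cat("  surrogates:", x$n_surrogates, "of the", x$surrogate_of,
      "at rate", x$surrogate_rate,
      "| draws per library size:", x$n_draws, "| seed:", x$seed, "\n")
  invisible(x)
}

bio_variables <- c(V = "FRO volume", G = "FRO growth",
                   starch = "Starch in stem", sugar = "Soluble sugar in stem")

#' Pairwise lagged cross mapping among biological traits
#'
#' For every ordered (library, target) pair among FRO volume, FRO growth,
#' stem starch and stem soluble sugar: selects E by cross-map skill at
#' tp = -1 over the configured range, runs the full lag grid with
#' twin-surrogate bounds, flags the per-row maximum-skill lag, and checks
#' library-size convergence at that best lag. Variables failing the S-map
#' nonlinearity screen are flagged and analysed anyway, with a warning.
#'
#' @param dataset a [trait_dataset()].
#' @param config a [ccm_config()].
#' @param variables which trait columns to analyse.
#' @return object of class `bio_ccm`: `table` (one row per pair x lag:
#'   `library, target, E, tp, rho, bound_95, significant, max_in_row`),
#'   `pairs` (per-pair best lag, convergence flag, lag-scan objects), and
#'   `screen` (per-variable S-map results).
#' @export
run_biological_ccm <- function(dataset, config = ccm_config(),
                               variables = c("V", "G", "starch", "sugar")) {
  comps <- lapply(variables, function(v)
    composite_from_dataset(dataset, v, treatment = config$treatment))
  names(comps) <- variables
  usable <- vapply(comps, function(cc) !all(cc$constant), logical(1))
  if (sum(vapply(comps, function(cc)
    sum(!is.na(cc$values)), integer(1)) > 0) < 2) {
    stop("need at least two variables with overlapping dates")
  }

  screen <- lapply(variables, function(v) {
    if (!usable[[v]]) return(NULL)
    E <- select_E(comps[[v]], comps[[v]], config$E_range, tp = 1,
                  tau = config$tau)
    smap_scan(comps[[v]], E = E, tau = config$tau)
  })
  names(screen) <- variables
  for (v in variables) {
    if (!is.null(screen[[v]]) && !screen[[v]]$nonlinear) {
      warning("variable ", v, " shows no S-map nonlinearity; ",
              "its cross maps are flagged")
    }
  }

  pairs <- expand.grid(library = variables, target = variables,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$library != pairs$target, ]
  rows <- list()
  pair_info <- list()
  for (i in seq_len(nrow(pairs))) {
    lv <- pairs$library[i]; tv <- pairs$target[i]
    key <- paste(lv, tv, sep = "->")
    if (!usable[[lv]] || !usable[[tv]]) {
      rows[[key]] <- data.frame(library = lv, target = tv,
                                E = NA_integer_, tp = config$bio_lags,
                                rho = NA_real_, bound_95 = NA_real_,
                                significant = FALSE, max_in_row = FALSE)
      pair_info[[key]] <- list(undefined = TRUE)
      next
    }
    scan <- lag_scan(comps[[lv]], comps[[tv]], lags = config$bio_lags,
                     tau = config$tau, surrogates = config$n_surrogates,
                     surrogate_rate = config$surrogate_rate,
                     surrogate_of = config$surrogate_of,
                     surrogate_period = config$surrogate_period,
                     seed = config$seed + 100L * i,
                     E_range = config$E_range,
                     library_name = bio_variables[[lv]],
                     target_name = bio_variables[[tv]])
    conv <- cross_map(comps[[lv]], comps[[tv]], E = scan$E,
                      tp = scan$best_lag, tau = config$tau,
                      lib_sizes = config$lib_sizes,
                      n_draws = config$n_draws,
                      seed = config$seed + 100L * i + 50L)
    tab <- scan$table
    rows[[key]] <- data.frame(library = lv, target = tv, E = scan$E,
                              tp = tab$tp, rho = tab$rho,
                              bound_95 = tab$bound_95,
                              significant = tab$significant,
                              max_in_row = tab$tp == scan$best_lag)
    pair_info[[key]] <- list(undefined = FALSE, scan = scan,
                             best_lag = scan$best_lag,
                             convergent = conv$convergent,
                             nonlinear_library =
                               isTRUE(screen[[lv]]$nonlinear))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(list(table = out, pairs = pair_info, screen = screen,
                 config = config),
            class = "bio_ccm")
}

#' @export
print.bio_ccm <- function(x, digits = 3, ...) {
  cat("Pairwise biological CCM (", nrow(x$table), "pair x lag cells )\n")
  best <- x$table[x$table$max_in_row, ]
  best$rho <- round(best$rho, digits)
  best$bound_95 <- round(best$bound_95, digits)
  print(best[, c("library", "target", "E", "tp", "rho", "bound_95",
                 "significant")], row.names = FALSE)
  invisible(x)
}

#' Cross mapping from biological traits to cumulative climate drivers
#'
#' For each driver (cumulative temperature CT, cumulative rainfall CR),
#' each biological variable (as library, following the convention that
#' the affected variable's attractor cross-maps its driver), each window
#' length n and each lag: cross-map skill with a twin-surrogate bound.
#' E is selected per variable x driver at the reference window; the
#' surrogate ensemble is regenerated per (driver, n) since the target
#' series changes with the window.
#'
#' @param dataset a [trait_dataset()].
#' @param climate daily climate data frame (`date`, `tavg`, `rain`), gap-
#'   filled; see [fill_missing_temperature()].
#' @param config a [ccm_config()].
#' @param drivers subset of `c("CT", "CR")`.
#' @param variables which trait columns to analyse.
#' @return object of class `climate_ccm`: `surfaces`, a list (per driver x
#'   variable) of class `climate_skill_surface` with `table` (`n`, `tp`,
#'   `rho`, `bound_95`, `significant`), `argmax` (`n`, `tp`, `rho`), `E`;
#'   plus the config.
#' @export
run_climate_ccm <- function(dataset, climate, config = ccm_config(),
                            drivers = c("CT", "CR"),
                            variables = c("V", "G", "starch", "sugar")) {
  dataset <- dataset[dataset$treatment %in% config$treatment, ]
  if (nrow(dataset) == 0L) stop("no rows after treatment filter")
  trees <- sort(unique(dataset$tree_id))
  dates_by_tree <- lapply(trees, function(tr)
    sort(dataset$date[dataset$tree_id == tr]))
  names(dates_by_tree) <- trees

  comps <- lapply(variables, function(v)
    composite_from_dataset(dataset, v, treatment = config$treatment))
  names(comps) <- variables

  # raw (unstandardised per tree) cumulative series per driver x window,
  # evaluated at each tree's own sampling dates, then composited
  driver_comp <- function(driver, n) {
    per_tree <- lapply(dates_by_tree, function(dd)
      cumulative_series(climate, driver, n, dd)$value)
    composite_series(per_tree, names = trees)
  }

  surfaces <- list()
  for (v in variables) {
    comp_v <- comps[[v]]
    if (all(comp_v$constant)) {
      for (drv in drivers) {
        tab <- expand.grid(n = config$windows, tp = config$climate_lags)
        tab$rho <- NA_real_; tab$bound_95 <- NA_real_
        tab$significant <- FALSE
        surfaces[[paste(drv, v, sep = ":")]] <- structure(
          list(driver = drv, variable = v, table = tab,
               argmax = NULL, E = NA_integer_, undefined = TRUE),
          class = "climate_skill_surface")
      }
      next
    }
    for (drv in drivers) {
      ref <- driver_comp(drv, config$reference_window)
      E <- tryCatch(select_E(comp_v, ref, config$E_range, tau = config$tau),
                    error = function(e) NA_integer_)
      if (is.na(E)) {
        tab <- expand.grid(n = config$windows, tp = config$climate_lags)
        tab$rho <- NA_real_; tab$bound_95 <- NA_real_
        tab$significant <- FALSE
        surfaces[[paste(drv, v, sep = ":")]] <- structure(
          list(driver = drv, variable = v, table = tab, argmax = NULL,
               E = NA_integer_, undefined = TRUE),
          class = "climate_skill_surface")
        next
      }
      emb <- delay_embed(comp_v, E, config$tau)
      pre <- knn_precompute(emb)
      k <- E + 1L
      # cumulative targets are NA-free, so the neighbour geometry depends
      # only on the lag; compute it once per lag and reuse over windows
      geos <- lapply(config$climate_lags, function(tp)
        lag_geometry(pre, tp, k))
      names(geos) <- as.character(config$climate_lags)
      rows <- list()
      for (n in config$windows) {
        tgt <- driver_comp(drv, n)
        stopifnot(!anyNA(tgt$values))
        ens <- if (config$n_surrogates > 0L) {
          tryCatch(twin_surrogates(
            tgt, E = E, target_rate = config$surrogate_rate,
            n_surrogates = config$n_surrogates,
            seed = config$seed + 1000L * match(drv, drivers) + n,
            tau = config$tau, period = config$surrogate_period),
            error = function(e) NULL)
        } else NULL
        for (tp in config$climate_lags) {
          geo <- geos[[as.character(tp)]]
          rho <- if (is.null(geo)) NA_real_ else geometry_skill(geo, tgt)
          bound <- NA_real_; sig <- FALSE
          if (!is.null(ens) && !is.null(geo) && is.finite(rho)) {
            skills <- fast_surrogate_skills(geo, ens$series)
            st <- significance_test(rho, skills)
            bound <- st$bound; sig <- st$significant
          }
          rows[[length(rows) + 1L]] <-
            data.frame(n = n, tp = tp, rho = rho, bound_95 = bound,
                       significant = sig)
        }
      }
      tab <- do.call(rbind, rows)
      finite <- which(is.finite(tab$rho))
      argmax <- if (length(finite) > 0L)
        tab[finite[which.max(tab$rho[finite])], c("n", "tp", "rho")]
        else NULL
      surfaces[[paste(drv, v, sep = ":")]] <- structure(
        list(driver = drv, variable = v, table = tab, argmax = argmax,
             E = E, undefined = FALSE),
        class = "climate_skill_surface")
    }
  }
  structure(list(surfaces = surfaces, config = config,
                 variables = variables, drivers = drivers),
            class = "climate_ccm")
}

# surrogate skills for a fast_skill fit (indices already offset by tp)
fast_surrogate_skills <- function(fit, S) {
  W <- fit$weights
  P <- matrix(0, nrow(fit$nb_target), ncol(S))
  for (j in seq_len(ncol(W))) {
    P <- P + W[, j] * S[fit$nb_target[, j], , drop = FALSE]
  }
  col_cor(P, S[fit$obs_index, , drop = FALSE])
}

#' @export
print.climate_skill_surface <- function(x, digits = 3, ...) {
  cat("Climate skill surface:", x$variable, "xmap", x$driver, "\n")
  if (isTRUE(x$undefined)) {
    cat("  undefined (constant or unusable series)\n")
    return(invisible(x))
  }
  cat("  E =", x$E, "| windows",
      paste(range(x$table$n), collapse = ".."), "days | lags",
      paste(range(x$table$tp), collapse = ".."), "\n")
  if (!is.null(x$argmax)) {
    cat("  argmax: n =", x$argmax$n, "days, tp =", x$argmax$tp,
        ", rho =", format(x$argmax$rho, digits = digits), "\n")
  }
  invisible(x)
}

#' @export
print.climate_ccm <- function(x, ...) {
  cat("Climate-window CCM:", length(x$surfaces), "surfaces\n")
  for (s in x$surfaces) print(s, ...)
  invisible(x)
}

#' @export
plot.climate_skill_surface <- function(x, tp = NULL, ...) {
  if (isTRUE(x$undefined)) stop("surface undefined")
  if (is.null(tp)) tp <- if (!is.null(x$argmax)) x$argmax$tp
                         else x$table$tp[1]
  tab <- x$table[x$table$tp == tp, ]
  plot(tab$n, tab$rho, type = "l", xlab = "cumulative days n",
       ylab = expression(rho), ylim = range(c(tab$rho, tab$bound_95),
                                            na.rm = TRUE),
       main = paste(x$variable, "xmap", x$driver, " (tp =", tp, ")"), ...)
  lines(tab$n, tab$bound_95, col = "grey50")
  invisible(x)
}

#' S-map nonlinearity screen of all analysis series
#'
#' Runs [smap_scan()] on each biological composite and, if daily climate is
#' supplied, on the cumulative driver composites at the configured screen
#' windows. Series without detectable nonlinearity are flagged; the screen
#' is advisory (the analysis proceeds with warnings) and is what justifies
#' capping cumulative windows, since long cumulative sums become nearly
#' linear.
#'
#' @param dataset a [trait_dataset()].
#' @param climate optional daily climate data frame.
#' @param config a [ccm_config()].
#' @param variables trait columns to screen.
#' @return data frame of class `nonlinearity_screen`: `series`, `E`,
#'   `rho0`, `delta_rho`, `nonlinear` (NA when undefined).
#' @export
nonlinearity_screen <- function(dataset, climate = NULL,
                                config = ccm_config(),
                                variables = c("V", "G", "starch", "sugar")) {
  dataset <- dataset[dataset$treatment %in% config$treatment, ]
  trees <- sort(unique(dataset$tree_id))
  dates_by_tree <- lapply(trees, function(tr)
    sort(dataset$date[dataset$tree_id == tr]))

  screen_one <- function(name, comp) {
    if (all(comp$constant) || sum(!is.na(comp$values)) < 30L) {
      return(data.frame(series = name, E = NA_integer_, rho0 = NA_real_,
                        delta_rho = NA_real_, nonlinear = NA))
    }
    E <- select_E(comp, comp, config$E_range, tp = 1, tau = config$tau)
    sm <- smap_scan(comp, E = E, tau = config$tau)
    data.frame(series = name, E = E, rho0 = sm$rho0,
               delta_rho = sm$delta_rho, nonlinear = sm$nonlinear)
  }

  out <- lapply(variables, function(v)
    screen_one(v, composite_from_dataset(dataset, v,
                                         treatment = config$treatment)))
  if (!is.null(climate)) {
    for (drv in c("CT", "CR")) {
      for (n in config$screen_windows) {
        per_tree <- lapply(dates_by_tree, function(dd)
          cumulative_series(climate, drv, n, dd)$value)
        comp <- composite_series(per_tree, names = trees)
        out[[length(out) + 1L]] <- screen_one(paste0(drv, "_", n), comp)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  flagged <- res$series[!is.na(res$nonlinear) & !res$nonlinear]
  if (length(flagged) > 0L) {
    warning("no S-map nonlinearity detected for: ",
            paste(flagged, collapse = ", "))
  }
  structure(res, class = c("nonlinearity_screen", "data.frame"))
}

#' Short/mid/long-term summary of a climate skill surface
#'
#' Condenses a (window, lag) skill surface into the three cumulative terms
#' short = 1-20, mid = 21-40 and long = 41-60 days. Within each term, each
#' window's best lag (by skill) is found; the term records the overall best
#' (n, lag), a majority-significance flag (significant at more than half
#' the term's windows), and a "dotted" flag when the best skill coexists
#' with non-significance in more than `dotted_threshold` windows of the
#' term. Terms are ranked within the surface by their best skill.
#'
#' @param surface a `climate_skill_surface` from [run_climate_ccm()].
#' @param config a [ccm_config()] (supplies `dotted_threshold`).
#' @param term_breaks right edges of the terms (default `c(20, 40, 60)`).
#' @return data frame of class `causal_summary`: one row per term with
#'   `driver, variable, term, best_n, best_tp, best_rho, windows,
#'   n_significant, majority_significant, dotted, rank`.
#' @export
summarize_terms <- function(surface, config = ccm_config(),
                            term_breaks = c(20, 40, 60)) {
  stopifnot(inherits(surface, "climate_skill_surface"))
  tab <- surface$table
  lo <- c(1, utils::head(term_breaks, -1) + 1)
  term_names <- c("short", "mid", "long")[seq_along(term_breaks)]
  rows <- list()
  for (i in seq_along(term_breaks)) {
    sub <- tab[tab$n >= lo[i] & tab$n <= term_breaks[i], ]
    windows <- sort(unique(sub$n))
    if (length(windows) == 0L) next
    best_per_n <- do.call(rbind, lapply(windows, function(n) {
      s <- sub[sub$n == n, ]
      if (all(!is.finite(s$rho))) {
        data.frame(n = n, tp = NA_integer_, rho = NA_real_,
                   significant = FALSE)
      } else {
        j <- which.max(ifelse(is.finite(s$rho), s$rho, -Inf))
        data.frame(n = n, tp = s$tp[j], rho = s$rho[j],
                   significant = s$significant[j])
      }
    }))
    n_sig <- sum(best_per_n$significant)
    best_j <- if (all(is.na(best_per_n$rho))) NA_integer_
              else which.max(ifelse(is.na(best_per_n$rho), -Inf,
                                    best_per_n$rho))
    rows[[i]] <- data.frame(
      driver = surface$driver, variable = surface$variable,
      term = term_names[i],
      best_n = if (is.na(best_j)) NA_integer_ else best_per_n$n[best_j],
      best_tp = if (is.na(best_j)) NA_integer_ else best_per_n$tp[best_j],
      best_rho = if (is.na(best_j)) NA_real_ else best_per_n$rho[best_j],
      windows = length(windows),
      n_significant = n_sig,
      majority_significant = n_sig > length(windows) / 2,
      dotted = sum(!best_per_n$significant) > config$dotted_threshold)
  }
  out <- do.call(rbind, rows)
  rk <- rank(-ifelse(is.na(out$best_rho), -Inf, out$best_rho),
             ties.method = "first")
  out$rank <- c("highest", "second", "third")[rk]
  out$rank[!out$majority_significant] <- "non-significant-majority"
  rownames(out) <- NULL
  structure(out, class = c("causal_summary", "data.frame"))
}
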