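#' Coupled logistic-map benchmark pair
#'
#' The standard two-species validation system for cross mapping:
#' \deqn{x_{t+1} = x_t (r_x - r_x x_t - \beta_{xy} y_{t-lag})}
#' \deqn{y_{t+1} = y_t (r_y - r_y y_t - \beta_{yx} x_{t-lag})}
#' so `beta_yx` is the strength with which x forces y and vice versa. A
#' burn-in of 300 steps is discarded. Because the forcing enters the next
#' step, a coupling lag of `lag` corresponds to a transmission delay of
#' `lag + 1` sampling intervals: cross-mapping the effect onto the cause
#' peaks at `tp = -(lag + 1)`.
#'
#' @param r_x,r_y intrinsic growth parameters in `[3.5, 4]`.
#' @param beta_xy,beta_yx coupling strengths in `[0, 1)` (`beta_xy`: effect
#'   of y on x).
#' @param lag coupling lag in steps (>= 0).
#' @param n output length (>= 50).
#' @param seed optional integer seed.
#' @return list with `x`, `y` (numeric, length `n`, values in (0, 1)) and
#'   `truth` (a [simulation_truth()] recording the planted couplings).
#' @export
simulate_coupled_logistic <- function(r_x = 3.8, r_y = 3.5, beta_xy = 0,
                                      beta_yx = 0.32, lag = 0, n = 400,
                                      seed = NULL) {
  stopifnot(r_x >= 3.5, r_x <= 4, r_y >= 3.5, r_y <= 4,
            beta_xy >= 0, beta_xy < 1, beta_yx >= 0, beta_yx < 1,
            lag >= 0, n >= 50)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  burn <- 300L
  total <- burn + n
  for (try in 1:10) {
    x <- y <- numeric(total)
    x[1:(lag + 1L)] <- stats::runif(lag + 1L, 0.2, 0.8)
    y[1:(lag + 1L)] <- stats::runif(lag + 1L, 0.2, 0.8)
    diverged <- FALSE
    for (t in (lag + 1L):(total - 1L)) {
      x[t + 1L] <- x[t] * (r_x - r_x * x[t] - beta_xy * y[t - lag])
      y[t + 1L] <- y[t] * (r_y - r_y * y[t] - beta_yx * x[t - lag])
      if (!is.finite(x[t + 1L]) || !is.finite(y[t + 1L]) ||
          x[t + 1L] <= 0 || x[t + 1L] >= 1 ||
          y[t + 1L] <= 0 || y[t + 1L] >= 1) {
        diverged <- TRUE
        break
      }
    }
    if (!diverged) {
      truth <- simulation_truth(
        variables = c("x", "y"),
        coupling = data.frame(
          from = c("y", "x"), to = c("x", "y"),
          strength = c(beta_xy, beta_yx), lag = lag + 1L))
      return(list(x = x[(burn + 1L):total], y = y[(burn + 1L):total],
                  truth = truth))
    }
  }
  stop("coupled logistic map left (0, 1) after 10 initial conditions")
}

#' Synthetic daily tropical climate
#'
#' Daily average temperature is a weak annual sinusoid plus AR(1) noise
#' (`tmax`/`tmin` are the average plus/minus a fixed diurnal half-range, so
#' their mean recovers `tavg` exactly). Rainfall is a zero-inflated gamma
#' with Markov wet-day persistence, scaled so the expected annual total
#' equals `annual_rain_target`. Defaults emulate a humid equatorial site:
#' mean 27.4 degrees C, seasonal amplitude 1.5 degrees C peaking in late
#' May, annual rainfall about 2000 mm.
#'
#' @param start_date first day.
#' @param n_days number of days (>= 400).
#' @param temp_mean,temp_amplitude,temp_noise_sd annual mean, seasonal
#'   amplitude and AR(1) innovation sd of daily average temperature
#'   (degrees C).
#' @param annual_rain_target expected annual rainfall (mm).
#' @param rain_autocorr lag-1 autocorrelation of the wet/dry indicator.
#' @param wet_fraction stationary fraction of wet days.
#' @param diurnal_half_range half the diurnal temperature range (degrees C).
#' @param peak_doy day of year at which the temperature sinusoid peaks.
#' @param seed optional integer seed.
#' @return data frame `date, tmax, tmin, tavg, rain`.
#' @export
simulate_climate <- function(start_date = as.Date("2012-08-01"),
                             n_days = 1400, temp_mean = 27.4,
                             temp_amplitude = 1.5, temp_noise_sd = 0.4,
                             annual_rain_target = 2000,
                             rain_autocorr = 0.3, wet_fraction = 0.5,
                             diurnal_half_range = 3.5, peak_doy = 140,
                             seed = NULL) {
  stopifnot(n_days >= 400)
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  dates <- seq(as.Date(start_date), by = "day", length.out = n_days)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- temp_amplitude * sin(2 * pi * (doy - peak_doy) / 365 + pi / 2)
  ar <- numeric(n_days)
  phi <- 0.7
  innov_sd <- temp_noise_sd * sqrt(1 - phi^2)
  ar[1] <- stats::rnorm(1, 0, temp_noise_sd)
  for (t in 2:n_days) ar[t] <- phi * ar[t - 1] + stats::rnorm(1, 0, innov_sd)
  tavg <- temp_mean + seasonal + ar

  p_wet_wet <- wet_fraction + rain_autocorr * (1 - wet_fraction)
  p_wet_dry <- wet_fraction * (1 - rain_autocorr)
  wet <- logical(n_days)
  wet[1] <- stats::runif(1) < wet_fraction
  for (t in 2:n_days) {
    p <- if (wet[t - 1]) p_wet_wet else p_wet_dry
    wet[t] <- stats::runif(1) < p
  }
  shape <- 0.8
  scale <- annual_rain_target / (365.25 * wet_fraction * shape)
  rain <- numeric(n_days)
  rain[wet] <- stats::rgamma(sum(wet), shape = shape, scale = scale)

  data.frame(date = dates,
             tmax = tavg + diurnal_half_range,
             tmin = tavg - diurnal_half_range,
             tavg = tavg, rain = rain)
}

#' Ground truth of a synthetic study
#'
#' Records the planted coupling structure against which causal inference is
#' scored: directed couplings between latent variables (strength and lag in
#' months, where lag is the number of months by which the cause leads the
#' effect), a shared seasonal confounder, observation noise, and optionally
#' a dependence of one variable on a cumulative climate window.
#'
#' @param variables character vector of latent variable names.
#' @param coupling data frame `from, to, strength, lag` (possibly 0 rows);
#'   zero strength means no causal path.
#' @param seasonal_amplitude amplitude of the shared seasonal forcing on
#'   the standardised observation scale (0 = none).
#' @param noise_sd sd of i.i.d. tree-level observation noise on the
#'   standardised scale.
#' @param climate_driver optional list
#'   `list(variable =, driver = "CR"|"CT", window =, lag =, strength =)`
#'   planting a dependence of `variable` on the `window`-day cumulative
#'   driver, `lag` months before the observation.
#' @return object of class `simulation_truth`.
#' @export
simulation_truth <- function(variables,
                             coupling = data.frame(from = character(),
                                                   to = character(),
                                                   strength = numeric(),
                                                   lag = integer()),
                             seasonal_amplitude = 0.5, noise_sd = 0.25,
                             climate_driver = NULL) {
  stopifnot(length(variables) >= 1, !anyDuplicated(variables))
  if (nrow(coupling) > 0) {
    unknown <- setdiff(unique(c(coupling$from, coupling$to)), variables)
    if (length(unknown) > 0) {
      stop("coupling references unknown variable(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(coupling$strength < 0) || any(coupling$lag < 0)) {
      stop("coupling strengths and lags must be non-negative")
    }
  }
  if (!is.null(climate_driver)) {
    stopifnot(climate_driver$variable %in% variables,
              climate_driver$driver %in% c("CT", "CR"),
              climate_driver$window >= 1, climate_driver$lag >= 0,
              climate_driver$strength >= 0)
  }
  structure(list(variables = variables, coupling = coupling,
                 seasonal_amplitude = seasonal_amplitude,
                 noise_sd = noise_sd, climate_driver = climate_driver),
            class = "simulation_truth")
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("Simulation truth:", paste(x$variables, collapse = ", "), "\n")
  if (nrow(x$coupling) > 0) {
    act <- x$coupling[x$coupling$strength > 0, ]
    if (nrow(act) > 0) {
      for (i in seq_len(nrow(act))) {
        cat("  ", act$from[i], "->", act$to[i], " strength ",
            act$strength[i], ", lag ", act$lag[i], " month(s)\n", sep = "")
      }
    } else cat("  no active couplings\n")
  } else cat("  no active couplings\n")
  cat("  seasonal amplitude:", x$seasonal_amplitude,
      "; noise sd:", x$noise_sd, "\n")
  if (!is.null(x$climate_driver)) {
    cd <- x$climate_driver
    cat("  climate driver: ", cd$driver, "_", cd$window, " -> ",
        cd$variable, " (strength ", cd$strength, ", lag ", cd$lag,
        ")\n", sep = "")
  }
  invisible(x)
}

#' Simulate a full synthetic study
#'
#' Generates organ, stem-NSC and daily-climate tables with the replicate
#' layout of a monthly tree study (default 4 trees x 42 months) and a
#' known causal structure. Each tree is an independent realisation of the
#' same latent dynamics — coupled logistic maps per the truth's couplings —
#' started from its own initial condition, as the dewdrop composite
#' approach assumes for biological replicates; the seasonal confounder and
#' any planted cumulative-climate forcing are shared across trees and
#' locked to the calendar. Per-tree observations are the tree's latent
#' series plus i.i.d. Gaussian noise on the standardised scale. Organ
#' tables are synthesised so that [fro_volume()]/[fro_growth()] recompute
#' the per-tree volume series exactly (round trip), and NSC values are
#' written identically at the three stem heights so the height average
#' recovers the observation.
#'
#' The latent variables must be named among `V`, `starch`, `sugar`
#' (`G`, FRO growth, is derived from `V` downstream, not simulated).
#'
#' @param truth a [simulation_truth()].
#' @param n_trees number of replicate trees (>= 1).
#' @param n_months number of monthly sampling points per tree (>= 24).
#' @param missing_rate probability that a tree x date NSC observation is
#'   missing.
#' @param seed optional integer seed.
#' @param start_date first sampling date.
#' @param treatment treatment label applied to all trees.
#' @return object of class `synthetic_study`: `organs`, `nsc`, `climate`
#'   data frames (the CSV dialects the readers consume), `treatments`,
#'   `truth`, `latent` (per-tree noiseless-observation tables including the
#'   exact `V` and `G` implied by the organ table), and `dates`.
#' @export
simulate_study <- function(truth, n_trees = 4, n_months = 42,
                           missing_rate = 0, seed = NULL,
                           start_date = as.Date("2012-10-15"),
                           treatment = "NAT") {
  stopifnot(inherits(truth, "simulation_truth"), n_trees >= 1,
            n_months >= 24, missing_rate >= 0, missing_rate < 1)
  vars <- truth$variables
  if (!all(vars %in% c("V", "starch", "sugar"))) {
    stop("latent variables must be among V, starch, sugar")
  }
  if (!is.null(seed)) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed))
      assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
    set.seed(seed)
  }
  dates <- seq(as.Date(start_date), by = "month", length.out = n_months)

  climate <- simulate_climate(start_date = as.Date(start_date) - 70L,
                              n_days = as.integer(max(dates) -
                                                  as.Date(start_date)) + 101L)

  # forcing series from the planted cumulative climate window, mapped to
  # (0, 1) through its empirical CDF (rank-uniform), so heavy-tailed
  # rainfall sums do not compress the effective forcing variance
  forcing <- NULL
  if (!is.null(truth$climate_driver)) {
    cd <- truth$climate_driver
    cum <- cumulative_series(climate, cd$driver, cd$window, dates)$value
    forcing <- if (diff(range(cum)) == 0) rep(0.5, n_months)
               else (rank(cum) - 0.5) / n_months
  }

  # latent monthly dynamics: coupled logistic maps with optional forcing
  r_pool <- c(3.8, 3.6, 3.72, 3.65)
  r <- stats::setNames(r_pool[seq_along(vars)], vars)
  beta <- matrix(0, length(vars), length(vars),
                 dimnames = list(vars, vars))  # beta[u, v]: u forces v
  lagm <- beta
  if (nrow(truth$coupling) > 0) {
    for (i in seq_len(nrow(truth$coupling))) {
      beta[truth$coupling$from[i], truth$coupling$to[i]] <-
        truth$coupling$strength[i]
      lagm[truth$coupling$from[i], truth$coupling$to[i]] <-
        truth$coupling$lag[i]
    }
  }
  max_lag <- max(1L, lagm, if (!is.null(forcing)) truth$climate_driver$lag)
  burn <- 300L
  total <- burn + n_months

  # one independent latent trajectory of the coupled maps per tree;
  # the climate forcing (calendar-locked) is common to all trees
  simulate_tree_latent <- function() {
    lat <- matrix(NA_real_, total, length(vars),
                  dimnames = list(NULL, vars))
    for (attempt in 1:10) {
      lat[1:max_lag, ] <- stats::runif(max_lag * length(vars), 0.2, 0.8)
      ok <- TRUE
      for (t in max_lag:(total - 1L)) {
        for (v in vars) {
          force_v <- 0
          for (u in vars) {
            if (beta[u, v] > 0) {
              # cause leads effect by lagm months: value at t+1 uses u at
              # t + 1 - lag
              force_v <- force_v + beta[u, v] * lat[t + 1L - lagm[u, v], u]
            }
          }
          if (!is.null(forcing) && truth$climate_driver$variable == v) {
            ft <- t + 1L - burn - truth$climate_driver$lag
            f <- if (ft >= 1L && ft <= n_months) forcing[ft] else 0.5
            force_v <- force_v + truth$climate_driver$strength * f
          }
          nxt <- lat[t, v] * (r[v] - r[v] * lat[t, v] - force_v)
          # strong forcing can push the map below 0; clamp into (0, 1)
          # (near-extinction bounce, standard for forced ecological maps)
          lat[t + 1L, v] <- min(max(nxt, 0.001), 0.999)
        }
        if (any(!is.finite(lat[t + 1L, ]))) {
          ok <- FALSE
          break
        }
      }
      if (ok) return(scale(lat[(burn + 1L):total, , drop = FALSE]))
    }
    stop("latent dynamics diverged; reduce coupling strengths")
  }

  seasonal <- truth$seasonal_amplitude *
    sin(2 * pi * seq_len(n_months) / 12)

  tree_ids <- sprintf("tree%02d", seq_len(n_trees))
  organs <- nsc <- list()
  latent_tables <- list()
  for (k in seq_len(n_trees)) {
    std <- simulate_tree_latent()
    obs <- sapply(vars, function(v) {
      std[, v] + seasonal + stats::rnorm(n_months, 0, truth$noise_sd)
    })
    obs <- matrix(obs, n_months, length(vars), dimnames = list(NULL, vars))
    # FRO volume: positive transform, then one ellipsoid organ per date
    V_pos <- if ("V" %in% vars) 100 * exp(0.4 * obs[, "V"])
             else rep(NA_real_, n_months)
    if ("V" %in% vars) {
      dim_abc <- (V_pos / (4 / 3 * pi))^(1 / 3)
      organs[[k]] <- data.frame(tree_id = tree_ids[k], date = dates,
                                organ_id = paste0(tree_ids[k], "_o1"),
                                stage = "immature",
                                a = dim_abc, b = dim_abc, c = dim_abc)
      # exact V implied by the written organ dimensions
      V_pos <- vapply(seq_len(n_months), function(i)
        fro_volume(dim_abc[i], dim_abc[i], dim_abc[i]), numeric(1))
    }
    starch_v <- if ("starch" %in% vars) obs[, "starch"]
                else rep(NA_real_, n_months)
    sugar_v <- if ("sugar" %in% vars) obs[, "sugar"]
               else rep(NA_real_, n_months)
    if (missing_rate > 0) {
      starch_v[stats::runif(n_months) < missing_rate] <- NA
      sugar_v[stats::runif(n_months) < missing_rate] <- NA
    }
    nsc[[k]] <- data.frame(
      tree_id = tree_ids[k],
      date = rep(dates, each = 3L),
      height = rep(c("top", "middle", "bottom"), n_months),
      starch = rep(starch_v, each = 3L),
      sugar = rep(sugar_v, each = 3L))
    G <- c(NA_real_, (V_pos[-1L] - V_pos[-n_months]) /
             as.numeric(diff(dates)))
    latent_tables[[k]] <- data.frame(tree_id = tree_ids[k], date = dates,
                                     V = V_pos, G = G,
                                     starch = starch_v, sugar = sugar_v)
  }
  structure(list(
    organs = if (length(organs) > 0) do.call(rbind, organs)
             else data.frame(tree_id = character(), date = as.Date(character()),
                             organ_id = character(), stage = character(),
                             a = numeric(), b = numeric(), c = numeric()),
    nsc = do.call(rbind, nsc),
    climate = climate,
    treatments = stats::setNames(rep(treatment, n_trees), tree_ids),
    truth = truth,
    latent = do.call(rbind, latent_tables),
    dates = dates),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", length(unique(x$nsc$tree_id)), "trees x",
      length(x$dates), "monthly sampling points\n")
  print(x$truth)
  invisible(x)
}
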