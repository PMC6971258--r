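#' Total female reproductive organ (FRO) volume at one date
#'
#' Each organ is measured as a three-dimensional size triplet (width `a`,
#' depth `b`, height `c`, all cm) and treated as an ellipsoid with volume
#' \eqn{\frac{4}{3}\pi a b c}; the tree-level value is the sum over all
#' living organs. The three measurements enter the formula as given, with
#' no halving. An empty collection (no living FROs) has volume 0.
#'
#' @param a,b,c numeric vectors of equal length: width, depth and height of
#'   each organ in cm.
#' @param organ_id optional identifiers used in error messages.
#' @return total volume in cm^3 (length-1 numeric).
#' @examples
#' fro_volume(1, 1, 1)              # 4*pi/3
#' fro_volume(c(1, 2), c(2, 2), c(3, 2))
#' @export
fro_volume <- function(a, b, c, organ_id = NULL) {
  if (length(a) == 0L) return(0)
  stopifnot(length(a) == length(b), length(b) == length(c))
  if (is.null(organ_id)) organ_id <- seq_along(a)
  bad <- which(a < 0 | b < 0 | c < 0)
  if (length(bad) > 0L) {
    stop("negative dimension for organ(s): ",
         paste(organ_id[bad], collapse = ", "))
  }
  sum(4 / 3 * pi * a * b * c)
}

#' FRO growth rate between two sampling dates
#'
#' Growth is the change in total FRO volume divided by the actual number of
#' days between the two sampling dates (cm^3/day). Negative values are
#' meaningful (bunch drop).
#'
#' @param v_now,v_prev total volumes (cm^3) at the current and previous date.
#' @param d_now,d_prev the corresponding calendar dates (`Date`).
#' @return growth in cm^3/day.
#' @export
fro_growth <- function(v_now, v_prev, d_now, d_prev) {
  d_now <- as.Date(d_now); d_prev <- as.Date(d_prev)
  dt <- as.numeric(d_now - d_prev)
  if (any(dt <= 0)) stop("d_now must be strictly later than d_prev")
  (v_now - v_prev) / dt
}

#' Whole-stem NSC content from three sampling heights
#'
#' Stem cores are taken at top, middle and bottom heights; the whole-stem
#' value is their arithmetic mean. If one or two heights are missing the
#' mean of the present ones is used with a warning, so isolated gaps do not
#' propagate into the composite series. All three missing yields `NA`.
#'
#' @param top,middle,bottom assay values (same units), possibly `NA`.
#' @return mean content; vectorised over dates.
#' @export
stem_nsc_average <- function(top, middle, bottom) {
  m <- cbind(top, middle, bottom)
  n_present <- rowSums(!is.na(m))
  partial <- n_present > 0L & n_present < 3L
  if (any(partial)) {
    warning(sum(partial), " date(s) with only partial stem-height data; ",
            "averaging the present heights")
  }
  out <- rowMeans(m, na.rm = TRUE)
  out[n_present == 0L] <- NA_real_
  out
}

#' Fill gaps in daily temperature records
#'
#' Missing `tmax`/`tmin` entries (single days or runs of days) are replaced
#' by the mean of the nearest present value before and the nearest present
#' value after the gap; present values are never altered, and `tavg` is
#' recomputed as `(tmax + tmin)/2`. The operation is idempotent.
#'
#' @param climate data frame with columns `date`, `tmax`, `tmin` and
#'   optionally others (e.g. `rain`), one row per day.
#' @return the same data frame with temperature gaps filled and a `tavg`
#'   column.
#' @export
fill_missing_temperature <- function(climate) {
  stopifnot(all(c("date", "tmax", "tmin") %in% names(climate)))
  climate$tmax <- fill_gaps(climate$tmax, "tmax")
  climate$tmin <- fill_gaps(climate$tmin, "tmin")
  climate$tavg <- (climate$tmax + climate$tmin) / 2
  climate
}

# bridge NA runs with the mean of the flanking present values
fill_gaps <- function(x, channel = "value") {
  if (!anyNA(x)) return(x)
  n <- length(x)
  if (is.na(x[1L]) || is.na(x[n])) {
    stop("unfillable gap: ", channel, " is missing at a series boundary")
  }
  miss <- which(is.na(x))
  present <- which(!is.na(x))
  for (i in miss) {
    before <- max(present[present < i])
    after <- min(present[present > i])
    x[i] <- (x[before] + x[after]) / 2
  }
  x
}

#' Cumulative climate series over an n-day window
#'
#' The cumulative temperature \eqn{CT_n} (or rainfall \eqn{CR_n}) at a
#' sampling date t is the sum of the daily average temperature (or daily
#' rainfall) over the n days ending on, and including, t.
#'
#' @param daily data frame with a `date` column and the daily values:
#'   `tavg` for `variable = "CT"`, `rain` for `"CR"`.
#' @param variable `"CT"` or `"CR"`.
#' @param n window length in days (>= 1).
#' @param sample_dates the biological sampling dates at which to evaluate.
#' @return data frame of class `cumulative_series` with columns
#'   `variable`, `n`, `date`, `value`.
#' @export
cumulative_series <- function(daily, variable = c("CT", "CR"), n,
                              sample_dates) {
  variable <- match.arg(variable)
  stopifnot(n >= 1)
  col <- if (variable == "CT") "tavg" else "rain"
  if (!col %in% names(daily)) {
    stop("daily record lacks column '", col, "' required for ", variable)
  }
  dates <- as.Date(daily$date)
  sample_dates <- as.Date(sample_dates)
  needed <- seq(min(sample_dates) - n + 1L, max(sample_dates), by = "day")
  missing_days <- needed[!(needed %in% dates[!is.na(daily[[col]])])]
  if (length(missing_days) > 0L) {
    stop("daily ", variable, " coverage is insufficient; missing dates: ",
         paste(utils::head(format(missing_days), 10L), collapse = ", "),
         if (length(missing_days) > 10L) " ...")
  }
  ord <- order(dates)
  dates <- dates[ord]
  vals <- daily[[col]][ord]
  cs <- cumsum(vals)
  idx <- match(sample_dates, dates)
  lo <- match(sample_dates - n, dates)  # day before the window starts
  value <- cs[idx] - ifelse(is.na(lo), 0, cs[lo])
  structure(
    data.frame(variable = variable, n = n, date = sample_dates,
               value = value),
    class = c("cumulative_series", "data.frame"))
}

#' Day length from solar geometry
#'
#' Hours between sunrise and sunset for a given latitude and date, using
#' the Forsythe et al. daylength model with the standard refraction-
#' corrected zenith (sun centre at -0.833 degrees). Day length is an input
#' variable for cross mapping only.
#'
#' @param latitude in decimal degrees; must satisfy `abs(latitude) < 66.5`.
#' @param date calendar date(s).
#' @return day length in hours.
#' @export
day_length <- function(latitude, date) {
  if (abs(latitude) >= 66.5) {
    stop("unsupported latitude: ", latitude,
         " (polar day/night not handled)")
  }
  doy <- as.integer(format(as.Date(date), "%j"))
  geosphere::daylength(latitude, doy)
}

#' Assemble per-tree monthly trait series
#'
#' Combines an organ-measurement table and a stem-NSC table into one
#' aligned per-tree series of FRO volume `V` (cm^3), FRO growth `G`
#' (cm^3/day, undefined at each tree's first date), and whole-stem starch
#' and soluble-sugar contents. Sampling dates are each tree's recorded NSC
#' dates; `G` uses the actual day gaps between consecutive dates.
#'
#' @param organs data frame `tree_id, date, organ_id, stage, a, b, c`
#'   (one row per living organ per date). Trees/dates present in `nsc` but
#'   absent here are treated per `empty_fro`.
#' @param nsc data frame `tree_id, date, height, starch, sugar` with
#'   `height` in `top`/`middle`/`bottom`.
#' @param treatments named character vector mapping `tree_id` to
#'   `"NAT"`/`"PFT"`; unnamed default `"NAT"`.
#' @param empty_fro value recorded when a tree has no living organs at a
#'   date: `0` (default; an observed absence) or `NA`.
#' @return data frame of class `trait_dataset` with columns
#'   `tree_id, treatment, date, V, G, starch, sugar`, sorted by tree and
#'   date.
#' @export
trait_dataset <- function(organs, nsc, treatments = NULL, empty_fro = 0) {
  nsc$date <- as.Date(nsc$date)
  if (nrow(organs) > 0L) organs$date <- as.Date(organs$date)
  trees <- sort(unique(nsc$tree_id))
  rows <- lapply(trees, function(tr) {
    sub <- nsc[nsc$tree_id == tr, ]
    dates <- sort(unique(sub$date))
    if (any(duplicated(dates)) || length(dates) < 1L) {
      stop("invalid sampling dates for tree ", tr)
    }
    starch <- sugar <- numeric(length(dates))
    for (i in seq_along(dates)) {
      d <- sub[sub$date == dates[i], ]
      get_h <- function(col, h) {
        v <- d[[col]][d$height == h]
        if (length(v) == 0L) NA_real_ else v[1L]
      }
      starch[i] <- stem_nsc_average(get_h("starch", "top"),
                                    get_h("starch", "middle"),
                                    get_h("starch", "bottom"))
      sugar[i] <- stem_nsc_average(get_h("sugar", "top"),
                                   get_h("sugar", "middle"),
                                   get_h("sugar", "bottom"))
    }
    V <- vapply(dates, function(d) {
      o <- organs[organs$tree_id == tr & organs$date == d, , drop = FALSE]
      if (nrow(o) == 0L) as.numeric(empty_fro)
      else fro_volume(o$a, o$b, o$c, o$organ_id)
    }, numeric(1))
    G <- c(NA_real_,
           if (length(dates) > 1L)
             fro_growth(V[-1L], V[-length(V)], dates[-1L],
                        dates[-length(dates)]))
    data.frame(tree_id = tr,
               treatment = if (!is.null(treatments) &&
                               tr %in% names(treatments))
                 treatments[[tr]] else "NAT",
               date = dates, V = V, G = G, starch = starch, sugar = sugar)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("trait_dataset", "data.frame"))
}
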