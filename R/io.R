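#' Column mapping for external CSV layouts
#'
#' Binds the logical fields the readers need to the column names of a
#' particular deposit, so external layouts are absorbed in configuration
#' rather than code. Unmapped extra columns in the files are ignored with
#' a notice.
#'
#' @param organs,nsc,climate named character vectors mapping logical field
#'   names (`tree_id, date, organ_id, stage, a, b, c`;
#'   `tree_id, date, height, starch, sugar`; `date, tmax, tmin, rain`) to
#'   source column names. Defaults are the identity mapping.
#' @return object of class `column_mapping`.
#' @export
column_mapping <- function(organs = NULL, nsc = NULL, climate = NULL) {
  defaults <- list(
    organs = c(tree_id = "tree_id", date = "date", organ_id = "organ_id",
               stage = "stage", a = "a", b = "b", c = "c"),
    nsc = c(tree_id = "tree_id", date = "date", height = "height",
            starch = "starch", sugar = "sugar"),
    climate = c(date = "date", tmax = "tmax", tmin = "tmin",
                rain = "rain"))
  override <- list(organs = organs, nsc = nsc, climate = climate)
  for (tb in names(defaults)) {
    ov <- override[[tb]]
    if (!is.null(ov)) {
      unknown <- setdiff(names(ov), names(defaults[[tb]]))
      if (length(unknown) > 0L) {
        stop("unknown logical field(s) in ", tb, " mapping: ",
             paste(unknown, collapse = ", "))
      }
      defaults[[tb]][names(ov)] <- ov
    }
  }
  structure(defaults, class = "column_mapping")
}

read_mapped_csv <- function(path, mapping, date_fields = "date",
                            date_format = "%Y-%m-%d") {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         check.names = FALSE)
  missing_cols <- setdiff(unname(mapping), names(raw))
  if (length(missing_cols) > 0L) {
    stop("file ", path, " lacks mapped column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), unname(mapping))
  if (length(extra) > 0L) {
    message("ignoring unmapped column(s) in ", basename(path), ": ",
            paste(extra, collapse = ", "))
  }
  out <- raw[, unname(mapping), drop = FALSE]
  names(out) <- names(mapping)
  for (f in intersect(date_fields, names(out))) {
    parsed <- as.Date(as.character(out[[f]]), format = date_format)
    bad <- which(is.na(parsed) & !is.na(out[[f]]) & out[[f]] != "")
    if (length(bad) > 0L) {
      stop("unparseable date(s) in ", basename(path), " at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
    out[[f]] <- parsed
  }
  out
}

#' Read a study dataset from CSV files
#'
#' Reads and validates the organ-measurement, stem-NSC and daily-climate
#' tables, assembles the per-tree trait series, and gap-fills the
#' temperature record.
#'
#' @param organs_path,nsc_path,climate_path file paths (CSV, header row,
#'   ISO-8601 dates unless `date_format` says otherwise).
#' @param mapping a [column_mapping()].
#' @param treatments named character vector `tree_id -> NAT/PFT`.
#' @param date_format date parsing format (default ISO-8601).
#' @param empty_fro see [trait_dataset()].
#' @return list with `dataset` (a [trait_dataset()]) and `climate`
#'   (gap-filled daily data frame with `tavg`).
#' @export
read_dataset <- function(organs_path, nsc_path, climate_path,
                         mapping = column_mapping(), treatments = NULL,
                         date_format = "%Y-%m-%d", empty_fro = 0) {
  organs <- read_mapped_csv(organs_path, mapping$organs,
                            date_format = date_format)
  dup <- duplicated(organs[, c("tree_id", "date", "organ_id")])
  if (any(dup)) {
    stop("duplicated (tree, date, organ) row(s) in ",
         basename(organs_path), ": row(s) ",
         paste(utils::head(which(dup), 5L), collapse = ", "))
  }
  if (any(organs$a < 0 | organs$b < 0 | organs$c < 0, na.rm = TRUE)) {
    stop("negative organ dimension(s) in ", basename(organs_path))
  }
  nsc <- read_mapped_csv(nsc_path, mapping$nsc, date_format = date_format)
  bad_h <- !nsc$height %in% c("top", "middle", "bottom")
  if (any(bad_h)) {
    stop("invalid stem height label(s) in ", basename(nsc_path),
         " at row(s): ",
         paste(utils::head(which(bad_h), 5L), collapse = ", "))
  }
  climate <- read_mapped_csv(climate_path, mapping$climate,
                             date_format = date_format)
  neg_rain <- which(climate$rain < 0)
  if (length(neg_rain) > 0L) {
    stop("negative rainfall in ", basename(climate_path), " at row(s): ",
         paste(utils::head(neg_rain, 5L), collapse = ", "))
  }
  climate <- fill_missing_temperature(climate)
  message("read ", nrow(organs), " organ rows, ", nrow(nsc),
          " NSC rows, ", nrow(climate), " climate days (",
          format(min(climate$date)), " to ", format(max(climate$date)), ")")
  list(dataset = trait_dataset(organs, nsc, treatments,
                               empty_fro = empty_fro),
       climate = climate)
}

#' Write a synthetic study to the CSV dialects the readers consume
#'
#' @param study a [simulate_study()] result.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the paths written (`organs.csv`, `nsc.csv`,
#'   `climate.csv`, `truth.json`, `treatments.csv`).
#' @export
write_study <- function(study, out_dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(out_dir, c("organs.csv", "nsc.csv", "climate.csv",
                                "truth.json", "treatments.csv"))
  write_fixed_csv(format_numeric(study$organs), paths[1])
  write_fixed_csv(format_numeric(study$nsc), paths[2])
  climate <- study$climate[, c("date", "tmax", "tmin", "rain")]
  write_fixed_csv(format_numeric(climate), paths[3])
  truth <- study$truth
  jsonlite::write_json(
    list(variables = truth$variables, coupling = truth$coupling,
         seasonal_amplitude = truth$seasonal_amplitude,
         noise_sd = truth$noise_sd,
         climate_driver = truth$climate_driver),
    paths[4], auto_unbox = TRUE, digits = NA, null = "null")
  write_fixed_csv(data.frame(tree_id = names(study$treatments),
                             treatment = unname(study$treatments)),
                  paths[5])
  invisible(paths)
}

format_numeric <- function(df, digits = 10) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]]) && !inherits(df[[j]], "Date")) {
      df[[j]] <- ifelse(is.na(df[[j]]), "",
                        formatC(df[[j]], digits = digits, format = "g"))
    }
  }
  df
}

write_fixed_csv <- function(df, path) {
  if (inherits(df$date, "Date")) df$date <- format(df$date)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

#' Write analysis results and a run manifest
#'
#' Serialises pipeline results to CSVs with a fixed numeric format
#' (6 decimal places), deterministic column order and row sort, plus a
#' JSON manifest recording the configuration, its hash, the seed and the
#' package version; rerunning with identical inputs yields byte-identical
#' files.
#'
#' @param results named list; recognised elements: `bio` (a `bio_ccm`),
#'   `climate` (a `climate_ccm`), `screen` (a `nonlinearity_screen`),
#'   `summary` (a `causal_summary` or list of them), `trait_dataset`
#'   (a [trait_dataset()]).
#' @param out_dir output directory.
#' @param config the [ccm_config()] used (stored in the manifest).
#' @return invisibly, the paths written.
#' @export
write_results <- function(results, out_dir, config = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    for (j in seq_along(df)) {
      if (is.double(df[[j]]) && !inherits(df[[j]], "Date")) {
        df[[j]] <- ifelse(is.na(df[[j]]), "",
                          sprintf("%.6f", df[[j]]))
      }
    }
    df
  }
  paths <- character(0)
  if (!is.null(results$trait_dataset)) {
    d <- results$trait_dataset
    d <- d[order(d$tree_id, d$date), ]
    p <- file.path(out_dir, "traits.csv")
    write_fixed_csv(fmt(d), p)
    paths <- c(paths, p)
  }
  if (!is.null(results$bio)) {
    tab <- results$bio$table
    tab <- tab[order(tab$library, tab$target, tab$tp), ]
    p <- file.path(out_dir, "bio_ccm.csv")
    write_fixed_csv(fmt(tab), p)
    paths <- c(paths, p)
  }
  if (!is.null(results$climate)) {
    long <- do.call(rbind, lapply(results$climate$surfaces, function(s) {
      cbind(data.frame(driver = s$driver, variable = s$variable,
                       E = s$E), s$table)
    }))
    long <- long[order(long$driver, long$variable, long$n, long$tp), ]
    p <- file.path(out_dir, "climate_ccm.csv")
    write_fixed_csv(fmt(long), p)
    paths <- c(paths, p)
  }
  if (!is.null(results$screen)) {
    p <- file.path(out_dir, "nonlinearity_screen.csv")
    write_fixed_csv(fmt(as.data.frame(results$screen)), p)
    paths <- c(paths, p)
  }
  if (!is.null(results$summary)) {
    s <- results$summary
    if (!is.data.frame(s)) s <- do.call(rbind, s)
    p <- file.path(out_dir, "term_summary.csv")
    write_fixed_csv(fmt(as.data.frame(s)), p)
    paths <- c(paths, p)
  }
  manifest <- list(
    package = "palmccm",
    version = as.character(utils::packageVersion("palmccm")),
    seed = if (!is.null(config)) config$seed else NA,
    config = if (!is.null(config)) unclass(config) else NULL,
    config_hash = if (!is.null(config)) config_hash(config) else NA,
    outputs = basename(paths),
    float_format = "%.6f",
    quantile_type = 7)
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(c(paths, mp))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE,
                       digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}
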