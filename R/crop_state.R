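# Daily crop-state container, CSV I/O, validation and thermal-time.

#' Canonical crop-state CSV columns
#'
#' Column names (and order) of the daily crop-state table consumed by the
#' simulators. `gdd` is optional on input and recomputed when absent.
#'
#' @format Character vector of column names.
#' @export
CROP_STATE_COLUMNS <- c("day_index", "tavg", "topwt", "vwt", "gna",
                        "ta", "tp", "anp", "cnp", "mnp", "gdd")

#' Canonical quality-series CSV columns
#'
#' Column names (and order) of the daily simulated grain-quality outputs.
#'
#' @format Character vector of column names.
#' @export
QUALITY_COLUMNS <- c("day_index", "gdd", "fw", "fn", "npf", "gpa",
                     "gcp", "gct", "gca", "f_gdd", "f_t", "eact",
                     "istr", "igsa", "gsa", "ra", "gasa", "gapa")

#' Construct a crop-state series
#'
#' Bundles the per-day driver table with the scenario scalars needed by the
#' grain-quality modules: panicle (spike) density `sp`, grains per spike
#' `ng`, and the anthesis-to-maturity thermal time `gdd_am`.
#'
#' @param days data.frame with columns `day_index, tavg, topwt, vwt, gna,
#'   ta, tp, anp, cnp, mnp, gdd`; one row per day from anthesis (day 0)
#'   to maturity.
#' @param sp panicle number, spikes/ha.
#' @param ng grain number, grains/spike.
#' @param gdd_am thermal time anthesis to maturity, degree-days. Defaults to
#'   the last day's `gdd`.
#' @param scenario_meta optional named list of free-form labels
#'   (treatment, year, ...).
#' @param check validate the series and stop on violations (default TRUE).
#' @return An object of class `crop_state_series`: a list with elements
#'   `days`, `sp`, `ng`, `gdd_am`, `scenario_meta`.
#' @export
crop_state_series <- function(days, sp, ng, gdd_am = NULL,
                              scenario_meta = list(), check = TRUE) {
  stopifnot(is.data.frame(days))
  missing_cols <- setdiff(setdiff(CROP_STATE_COLUMNS, "gdd"), names(days))
  if (length(missing_cols) > 0L) {
    stop("crop-state table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  days <- days[order(days$day_index), , drop = FALSE]
  rownames(days) <- NULL
  if (!"gdd" %in% names(days)) {
    days$gdd <- compute_gdd(days$tavg)
  }
  days <- days[, CROP_STATE_COLUMNS]
  if (is.null(gdd_am)) gdd_am <- days$gdd[nrow(days)]
  x <- structure(list(days = days, sp = sp, ng = ng, gdd_am = gdd_am,
                      scenario_meta = scenario_meta),
                 class = "crop_state_series")
  if (check) {
    rep <- validate_series(x)
    if (!rep$ok) {
      stop("invalid crop-state series:\n",
           paste(sprintf("  row %s, %s: %s", rep$issues$row,
                         rep$issues$field, rep$issues$message),
                 collapse = "\n"))
    }
  }
  x
}

#' @export
print.crop_state_series <- function(x, ...) {
  cat(sprintf(paste0("<crop_state_series> %d days (anthesis to maturity), ",
                     "sp = %g spikes/ha, ng = %g grains/spike, ",
                     "gdd_am = %.1f degree-days\n"),
              nrow(x$days), x$sp, x$ng, x$gdd_am))
  invisible(x)
}

#' Accumulated thermal time since anthesis
#'
#' Growing degree days with the day-0 (anthesis) value fixed at zero:
#' `gdd[i] = gdd[i-1] + max(0, tavg[i] - gdd_base)` for i >= 1. Daily
#' increments below the base temperature contribute nothing; there is no
#' upper cutoff.
#'
#' @param tavg_series daily mean air temperature, degrees C, starting at
#'   anthesis (day 0).
#' @param gdd_base base temperature, degrees C (default 10, the CERES
#'   convention for millet).
#' @return Numeric vector of accumulated degree-days, same length as input;
#'   nondecreasing, starts at 0.
#' @examples
#' compute_gdd(c(22, 20, 25), gdd_base = 10)  # 0, 10, 25
#' @export
compute_gdd <- function(tavg_series, gdd_base = 10) {
  if (length(tavg_series) == 0L) stop("empty temperature series")
  stopifnot(gdd_base >= 0)
  inc <- pmax(0, tavg_series - gdd_base)
  inc[1] <- 0  # day 0 carries no accumulation
  cumsum(inc)
}

#' Read a crop-state series from a canonical CSV
#'
#' Reads the daily driver table (comma-separated, `.` decimal, header row)
#' and attaches the scenario scalars. If the optional `gdd` column is
#' absent it is computed with [compute_gdd()].
#'
#' @param path CSV file path.
#' @param sp panicle number, spikes/ha.
#' @param ng grain number, grains/spike.
#' @param gdd_base base temperature for thermal time, degrees C.
#' @param scenario_meta optional named list of labels.
#' @return A validated [crop_state_series()].
#' @export
read_crop_state_csv <- function(path, sp, ng, gdd_base = 10,
                                scenario_meta = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  mandatory <- setdiff(CROP_STATE_COLUMNS, "gdd")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols) > 0L) {
    stop("crop-state CSV is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  present <- intersect(CROP_STATE_COLUMNS, names(df))
  for (col in present) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                     !is.na(df[[col]]))
      stop(sprintf("non-numeric value in column '%s' (row %s)", col,
                   if (length(bad)) bad[1] else "?"))
    }
  }
  df <- df[order(df$day_index), , drop = FALSE]
  if (!"gdd" %in% names(df)) df$gdd <- compute_gdd(df$tavg, gdd_base)
  crop_state_series(df, sp = sp, ng = ng, scenario_meta = scenario_meta)
}

#' Validate a crop-state series
#'
#' Checks every series invariant row-wise and reports all violations, not
#' only the first: `topwt >= vwt >= 0`, `gna >= 0`, `ta, tp >= 0`,
#' `cnp > mnp`, `gdd >= 0` and nondecreasing, consecutive `day_index`
#' starting at 0, last `gdd` equal to `gdd_am`, and `sp, ng > 0`.
#'
#' @param series a [crop_state_series()].
#' @return A list of class `validation_report`: `ok` (logical) and
#'   `issues`, a data.frame with columns `row`, `field`, `message`
#'   (zero rows when `ok`).
#' @export
validate_series <- function(series) {
  stopifnot(inherits(series, "crop_state_series"))
  d <- series$days
  n <- nrow(d)
  issues <- list()
  add <- function(row, field, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, field = field, message = message,
      stringsAsFactors = FALSE)
  }

  if (n == 0L) {
    add(NA_integer_, "days", "series is empty")
  } else {
    if (!isTRUE(all.equal(d$day_index, seq_len(n) - 1))) {
      bad <- which(d$day_index != seq_len(n) - 1)
      add(bad[1], "day_index",
          "day_index values must be consecutive integers starting at 0")
    }
    for (i in which(d$vwt < 0)) add(i, "vwt", "vwt must be >= 0")
    for (i in which(d$topwt < d$vwt)) {
      add(i, "vwt", "vwt exceeds topwt (vegetative exceeds total aboveground)")
    }
    for (i in which(d$gna < 0)) add(i, "gna", "gna must be >= 0")
    for (i in which(d$ta < 0)) add(i, "ta", "ta must be >= 0")
    for (i in which(d$tp < 0)) add(i, "tp", "tp must be >= 0")
    for (i in which(d$cnp <= d$mnp)) {
      add(i, "cnp", "critical N concentration must exceed minimum (cnp > mnp)")
    }
    for (i in which(d$gdd < 0)) add(i, "gdd", "gdd must be >= 0")
    if (n > 1L) {
      for (i in which(diff(d$gdd) < 0) + 1L) {
        add(i, "gdd", "gdd must be nondecreasing")
      }
    }
    if (abs(d$gdd[n] - series$gdd_am) > 1e-6) {
      add(n, "gdd", sprintf("last-day gdd (%.6g) differs from gdd_am (%.6g)",
                            d$gdd[n], series$gdd_am))
    }
  }
  if (!isTRUE(series$sp > 0)) add(NA_integer_, "sp", "sp must be > 0")
  if (!isTRUE(series$ng > 0)) add(NA_integer_, "ng", "ng must be > 0")

  issues <- if (length(issues)) {
    do.call(rbind, issues)
  } else {
    data.frame(row = integer(), field = character(), message = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(ok = nrow(issues) == 0L, issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$ok) {
    cat("<validation_report> ok, 0 issues\n")
  } else {
    cat(sprintf("<validation_report> %d issue(s):\n", nrow(x$issues)))
    print(x$issues)
  }
  invisible(x)
}

#' Write a quality series to CSV
#'
#' One row per day with the canonical column order (`QUALITY_COLUMNS`);
#' values survive a write/read round trip to 1e-9.
#'
#' @param qs quality series data.frame as returned by [simulate_quality()].
#' @param path output file path.
#' @export
write_quality_csv <- function(qs, path) {
  stopifnot(is.data.frame(qs))
  if (nrow(qs) == 0L) stop("quality series is empty; nothing to write")
  missing_cols <- setdiff(QUALITY_COLUMNS, names(qs))
  if (length(missing_cols) > 0L) {
    stop("quality series is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(format(qs[, QUALITY_COLUMNS], digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}

#' Read a quality series from CSV
#'
#' @param path CSV written by [write_quality_csv()].
#' @return data.frame with the canonical quality columns.
#' @export
read_quality_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(QUALITY_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("quality CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df[, QUALITY_COLUMNS]
}

#' Write a crop-state series to CSV
#'
#' Inverse of [read_crop_state_csv()] for the per-day table (the scalar
#' `sp`/`ng` travel in config, not the CSV).
#'
#' @param series a [crop_state_series()].
#' @param path output file path.
#' @export
write_crop_state_csv <- function(series, path) {
  stopifnot(inherits(series, "crop_state_series"))
  utils::write.csv(format(series$days, digits = 15, trim = TRUE,
                          scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
}
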