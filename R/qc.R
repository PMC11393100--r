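#' Quality-control filters for raw sonde records
#'
#' Applies the standard cleaning rules for optical-sonde water-quality
#' series, in order:
#' \enumerate{
#'   \item duplicated timestamps: keep the first occurrence
#'     (rule `duplicate_timestamp`);
#'   \item conductivity rows declared to be in mS/cm are multiplied by
#'     1000 (a unit conversion, not a removal);
#'   \item DO above 25 mg/L is physically implausible for natural waters
#'     and removed (rule `do_gt_25`);
#'   \item non-positive DO, conductivity, pH, ammonium or turbidity
#'     removed (rule `nonpositive_value`);
#'   \item rows inside caller-supplied exclusion intervals (e.g. an
#'     artificial oxygenation episode) removed (rule `excluded_interval`);
#'   \item any salinity column is dropped (duplicates conductivity).
#' }
#' Missing values (`NA`) are retained — a missing reading is distinct from
#' a reading removed by rule. Timestamps are never modified. The operation
#' is idempotent: re-running it on its own output removes nothing.
#'
#' @param raw data frame with a `timestamp` column (POSIXct) and at least
#'   `do_mgl`; recognised indicator columns are `do_mgl`, `temp_c`,
#'   `cond_uscm`, `ph`, `ammonium_mgl`, `turbidity_ntu`.
#' @param exclusion_intervals optional data frame with `start`, `end`
#'   (POSIXct, inclusive) and optionally `reason`.
#' @param cond_unit declared conductivity unit for this file: `"us/cm"`
#'   (no conversion) or `"ms/cm"` (multiply by 1000). Explicit declaration
#'   is required rather than magnitude heuristics, which silently corrupt
#'   borderline values.
#' @return list with `data` (the clean tibble, timestamps strictly
#'   increasing) and `report` (a `qc_report`: `rows_in`, `rows_out`,
#'   `rows_removed_by_rule`, `unit_conversions`, `excluded_intervals`).
#' @export
#' @examples
#' raw <- tibble::tibble(
#'   timestamp = as.POSIXct("2020-01-01", tz = "UTC") + 900 * 0:3,
#'   do_mgl = c(10, 26, 8, -1)
#' )
#' qc <- apply_qc_filters(raw)
#' qc$report$rows_removed_by_rule
apply_qc_filters <- function(raw, exclusion_intervals = NULL,
                             cond_unit = c("us/cm", "ms/cm")) {
  if (!"timestamp" %in% names(raw)) {
    stop("`raw` must have a `timestamp` column", call. = FALSE)
  }
  if (!"do_mgl" %in% names(raw)) {
    stop("`raw` must have a `do_mgl` column", call. = FALSE)
  }
  cond_unit <- match.arg(cond_unit)
  x <- tibble::as_tibble(raw)
  rows_in <- nrow(x)
  removed <- c(duplicate_timestamp = 0L, do_gt_25 = 0L,
               nonpositive_value = 0L, excluded_interval = 0L)
  conversions <- 0L

  x <- dplyr::arrange(x, .data$timestamp)
  dup <- duplicated(x$timestamp)
  removed[["duplicate_timestamp"]] <- sum(dup)
  x <- x[!dup, ]

  if (cond_unit == "ms/cm" && "cond_uscm" %in% names(x)) {
    conv <- !is.na(x$cond_uscm)
    x$cond_uscm[conv] <- x$cond_uscm[conv] * 1000
    conversions <- sum(conv)
  }

  bad_do <- !is.na(x$do_mgl) & x$do_mgl > 25
  removed[["do_gt_25"]] <- sum(bad_do)
  x <- x[!bad_do, ]

  pos_cols <- intersect(c("do_mgl", "cond_uscm", "ph", "ammonium_mgl",
                          "turbidity_ntu"), names(x))
  nonpos <- Reduce(`|`, lapply(pos_cols, function(cl) {
    !is.na(x[[cl]]) & x[[cl]] <= 0
  }), rep(FALSE, nrow(x)))
  removed[["nonpositive_value"]] <- sum(nonpos)
  x <- x[!nonpos, ]

  excluded <- list()
  if (!is.null(exclusion_intervals) && nrow(exclusion_intervals)) {
    stopifnot(all(c("start", "end") %in% names(exclusion_intervals)))
    inside <- rep(FALSE, nrow(x))
    for (i in seq_len(nrow(exclusion_intervals))) {
      s <- exclusion_intervals$start[i]; e <- exclusion_intervals$end[i]
      inside <- inside | (x$timestamp >= s & x$timestamp <= e)
      excluded[[i]] <- list(
        start = s, end = e,
        reason = exclusion_intervals$reason[i] %||% "excluded"
      )
    }
    removed[["excluded_interval"]] <- sum(inside)
    x <- x[!inside, ]
  }

  sal <- grep("^sal", names(x), ignore.case = TRUE)
  if (length(sal)) x <- x[, -sal]

  report <- structure(list(
    rows_in = rows_in, rows_out = nrow(x),
    rows_removed_by_rule = as.list(removed),
    unit_conversions = conversions,
    excluded_intervals = excluded
  ), class = "qc_report")
  stopifnot(report$rows_in - sum(removed) == report$rows_out)
  list(data = x, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC: %d rows in, %d rows out\n", x$rows_in, x$rows_out))
  for (nm in names(x$rows_removed_by_rule)) {
    cat(sprintf("  removed by %s: %d\n", nm, x$rows_removed_by_rule[[nm]]))
  }
  cat(sprintf("  unit conversions: %d\n", x$unit_conversions))
  invisible(x)
}

#' Broadcast daily rainfall onto a 15-minute series
#'
#' Every row receives the rainfall of its calendar date. Dates absent from
#' the rainfall table yield `NA`, never a silent zero. Choosing the
#' nearest rainfall station is the caller's duty.
#'
#' @param series tibble with a `timestamp` column.
#' @param rain data frame with `date` (Date) and `rainfall_mm` columns;
#'   duplicate dates are an error.
#' @return `series` with a `rainfall_mm` column added (replaced if present).
#' @export
pair_rainfall <- function(series, rain) {
  stopifnot("timestamp" %in% names(series),
            all(c("date", "rainfall_mm") %in% names(rain)))
  if (anyDuplicated(rain$date)) {
    stop("duplicate dates in the rainfall table", call. = FALSE)
  }
  dates <- as.Date(series$timestamp, tz = "UTC")
  series$rainfall_mm <- rain$rainfall_mm[match(dates, as.Date(rain$date))]
  series
}

#' Read a raw sensor CSV with a column-name mapping
#'
#' @param path CSV file with a header and ISO-8601 timestamps.
#' @param col_map named character vector mapping canonical names
#'   (`timestamp`, `do_mgl`, ...) to the file's column names; defaults to
#'   identity for any canonical column present.
#' @return tibble with canonical column names.
#' @export
read_sensor_csv <- function(path, col_map = NULL) {
  x <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(col_map)) {
    missing <- setdiff(unname(col_map), names(x))
    if (length(missing)) {
      stop("columns not found in file: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    x <- dplyr::rename(x, !!!rlang::set_names(col_map, names(col_map)))
  }
  if (!"timestamp" %in% names(x)) {
    stop("no `timestamp` column after mapping", call. = FALSE)
  }
  if (!inherits(x$timestamp, "POSIXct")) {
    x$timestamp <- lubridate::ymd_hms(x$timestamp, tz = "UTC")
  }
  x
}

#' Write a QC report as JSON
#'
#' @param report a `qc_report` from [apply_qc_filters()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  stopifnot(inherits(report, "qc_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       POSIXt = "ISO8601", pretty = TRUE)
  invisible(path)
}
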