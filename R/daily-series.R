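#' Validate a daily city series
#'
#' A daily series is a tibble with one row per calendar day carrying the
#' mean/min/max temperature (degrees C), the daily death count, and
#' optionally mean relative humidity (%). `daily_series()` checks the
#' contract every downstream function relies on: strictly consecutive
#' dates, `tmin <= tmean <= tmax`, and non-negative integer counts.
#'
#' @param data A data frame with columns `date` (Date), `tmean`, and
#'   optionally `tmin`, `tmax`, `deaths`, `humidity`.
#' @param city_label Free-text label attached as the `"city_label"`
#'   attribute.
#' @return A tibble of class `daily_series`, rows ordered by date.
#' @export
daily_series <- function(data, city_label = NULL) {
  data <- tibble::as_tibble(data)
  if (!"date" %in% names(data)) abort("`data` must have a `date` column.")
  if (!"tmean" %in% names(data)) abort("`data` must have a `tmean` column.")
  data$date <- as.Date(data$date)
  if (anyNA(data$date)) abort("`date` contains unparseable values.")
  data <- dplyr::arrange(data, .data$date)
  if (anyDuplicated(data$date)) {
    abort(paste0("Duplicate dates: ", paste(head(data$date[duplicated(data$date)], 3), collapse = ", ")))
  }
  # fill calendar gaps with all-missing rows so dates step by exactly 1 day
  if (nrow(data) > 1) {
    full <- tibble::tibble(date = seq(min(data$date), max(data$date), by = "day"))
    data <- dplyr::left_join(full, data, by = "date")
  }
  for (col in intersect(c("tmin", "tmax", "deaths", "humidity"), names(data))) {
    if (!is.numeric(data[[col]])) abort(sprintf("Column `%s` must be numeric.", col))
  }
  if (all(c("tmin", "tmax") %in% names(data))) {
    bad <- which(!is.na(data$tmin) & !is.na(data$tmax) & data$tmin > data$tmax)
    if (length(bad)) {
      abort(sprintf("tmin > tmax on %s", paste(data$date[head(bad, 3)], collapse = ", ")))
    }
    bad <- which(!is.na(data$tmin) & !is.na(data$tmax) & !is.na(data$tmean) &
                   (data$tmean < data$tmin - 1e-8 | data$tmean > data$tmax + 1e-8))
    if (length(bad)) {
      abort(sprintf("tmean outside [tmin, tmax] on %s", paste(data$date[head(bad, 3)], collapse = ", ")))
    }
  }
  if ("deaths" %in% names(data)) {
    d <- data$deaths[!is.na(data$deaths)]
    if (any(d < 0) || any(d != round(d))) {
      abort("`deaths` must be non-negative integers.")
    }
  }
  structure(data, class = c("daily_series", class(data)),
            city_label = city_label %||% attr(data, "city_label"))
}

#' Read a daily series from CSV
#'
#' Reads a comma-separated file (header row, '.' decimal, UTF-8) and maps
#' its columns onto the daily-series contract. Calendar gaps are filled
#' with missing rows; rows whose date does not parse are dropped with a
#' warning.
#'
#' @param path Path to a CSV file.
#' @param column_map Named character vector mapping the canonical names
#'   (`date`, `tmean`, `tmin`, `tmax`, `deaths`, `humidity`) to the file's
#'   column names. Entries other than `date` and `tmean` are optional.
#' @param city_label Optional label stored on the result.
#' @return A [daily_series] tibble.
#' @export
read_daily_series <- function(path,
                              column_map = c(date = "date", tmean = "tmean",
                                             tmin = "tmin", tmax = "tmax",
                                             deaths = "deaths"),
                              city_label = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("date", "tmean")
  for (nm in required) {
    if (!nm %in% names(column_map)) abort(sprintf("column_map must map `%s`.", nm))
  }
  present <- column_map[column_map %in% names(raw)]
  missing_req <- setdiff(required, names(present))
  if (length(missing_req)) {
    abort(sprintf("Mapped column(s) not in file: %s",
                  paste(column_map[missing_req], collapse = ", ")))
  }
  out <- raw[, unname(present), drop = FALSE]
  names(out) <- names(present)
  dates <- if (inherits(out$date, "Date")) out$date else
    as.Date(as.character(out$date), format = "%Y-%m-%d")
  if (anyNA(dates)) {
    warn(sprintf("Dropping %d row(s) with unparseable dates.", sum(is.na(dates))))
    out <- out[!is.na(dates), , drop = FALSE]
    dates <- dates[!is.na(dates)]
  }
  out$date <- dates
  daily_series(out, city_label = city_label)
}

#' @export
print.daily_series <- function(x, ...) {
  lab <- attr(x, "city_label")
  cat(sprintf("<daily_series>%s %d days: %s to %s\n",
              if (is.null(lab)) "" else paste0(" [", lab, "]"),
              nrow(x), format(min(x$date)), format(max(x$date))))
  NextMethod()
}
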