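#' Read pipeline CSV inputs
#'
#' Readers for the plain-text formats written by [write_study_csv()] (and
#' matching real exports with the same headers): reports, region table,
#' adjacency edge list, site metadata and long-format measurements.
#'
#' @param path CSV file path.
#' @return A tibble with parsed columns.
#' @name read_inputs
NULL

#' @rdname read_inputs
#' @export
read_reports_csv <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  assert_columns(df, c("user_id", "timestamp", "region_id",
                       "nose", "eyes", "breathing", "taken_meds"),
                 "reports CSV")
  parse_report_timestamps(df)
}

#' @rdname read_inputs
#' @export
read_regions_csv <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE,
                           colClasses = "character"))
  assert_columns(df, c("region_id", "category"), "regions CSV")
  df
}

#' @rdname read_inputs
#' @export
read_adjacency_csv <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  assert_columns(df, c("region_a", "region_b"), "adjacency CSV")
  df
}

#' @rdname read_inputs
#' @export
read_sites_csv <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  assert_columns(df, c("site_id", "variable", "region_id", "site_type"),
                 "sites CSV")
  df
}

#' @rdname read_inputs
#' @export
read_measurements_csv <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  assert_columns(df, c("site_id", "timestamp", "value"), "measurements CSV")
  ts <- lubridate::ymd_hms(df$timestamp, tz = "UTC", quiet = TRUE)
  only_date <- is.na(ts)
  if (any(only_date)) {
    ts[only_date] <- lubridate::ymd(df$timestamp[only_date], tz = "UTC")
  }
  if (any(is.na(ts))) {
    abort(sprintf("malformed timestamp at row %d of %s",
                  which(is.na(ts))[1], path))
  }
  df$timestamp <- ts
  df
}
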