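#' Derive a 2016-style user identifier
#'
#' Early-cohort exports carried no user identifier, so one is improvised by
#' concatenating year of birth, gender and region with a fixed separator.
#' The mapping is deterministic and injective on its inputs (the separator
#' cannot occur inside the fields).
#'
#' @param year_of_birth,gender,region_id Non-empty scalars (vectorised).
#' @return Character vector of identifiers like `"1980|F|M13"`.
#' @export
#' @examples
#' derive_user_id(1980, "F", "M13")
derive_user_id <- function(year_of_birth, gender, region_id) {
  check_field <- function(x, name) {
    if (any(is.na(x)) || any(!nzchar(as.character(x)))) {
      abort(sprintf("derive_user_id: field '%s' is missing or empty", name))
    }
  }
  check_field(year_of_birth, "year_of_birth")
  check_field(gender, "gender")
  check_field(region_id, "region_id")
  paste(year_of_birth, gender, region_id, sep = "|")
}

#' Maximum symptom score
#'
#' `max_score` is the maximum of the three reported ordinal scores.
#'
#' @param nose,eyes,breathing Integer scores in `{0,1,2,3}` (vectorised).
#' @return Integer vector of maxima.
#' @export
#' @examples
#' compute_max_score(2, 1, 0)
compute_max_score <- function(nose, eyes, breathing) {
  for (s in list(nose, eyes, breathing)) {
    if (any(is.na(s)) || any(!(s %in% 0:3))) {
      abort("symptom scores must be integers in {0, 1, 2, 3}")
    }
  }
  as.integer(pmax(nose, eyes, breathing))
}

#' Label a region category as urban or rural
#'
#' ONS 2011 rural-urban classification: categories A1, B1, C1 and C2
#' (England and Wales) and 1, 2 and 3 (Scotland) are urban; every other
#' category is rural. Codes outside the known ONS scheme are treated as
#' rural with a warning, since the scheme enumerates the urban codes
#' explicitly.
#'
#' @param category Character vector of category codes.
#' @return Character vector, `"urban"` or `"rural"`.
#' @export
#' @examples
#' label_land_use(c("A1", "2", "E1"))
label_land_use <- function(category) {
  if (any(is.na(category)) || any(!nzchar(category))) {
    abort("category codes must be non-empty")
  }
  unknown <- setdiff(unique(category), c(.urban_categories, .rural_categories))
  if (length(unknown) > 0) {
    warn(sprintf(
      "unknown ONS category code(s) treated as rural: %s",
      paste(unknown, collapse = ", ")
    ))
  }
  ifelse(category %in% .urban_categories, "urban", "rural")
}

#' Report filtering policy
#'
#' The three report-level filters applied before any analysis: restrict to
#' a month window (March-September by default, the pollen season), keep
#' only the latest report per user per calendar day, and drop users who
#' reported on fewer than `min_report_days` distinct days.
#'
#' @param months Set of calendar month numbers to keep.
#' @param min_report_days Minimum distinct reporting days per retained
#'   user.
#' @param latest_per_day Keep only the latest report per user-day.
#' @param min_days_before_window If `TRUE`, count a user's reporting days
#'   on the unfiltered calendar (before the month window) when applying
#'   `min_report_days`; the default counts days inside the window.
#' @return An object of class `filter_policy`.
#' @export
filter_policy <- function(months = 3:9, min_report_days = 10,
                          latest_per_day = TRUE,
                          min_days_before_window = FALSE) {
  if (!all(months %in% 1:12)) abort("months must be a subset of 1..12")
  if (min_report_days < 1) abort("min_report_days must be >= 1")
  structure(
    list(
      months = as.integer(sort(unique(months))),
      min_report_days = as.integer(min_report_days),
      latest_per_day = isTRUE(latest_per_day),
      min_days_before_window = isTRUE(min_days_before_window)
    ),
    class = "filter_policy"
  )
}

parse_report_timestamps <- function(reports) {
  ts <- reports$timestamp
  if (!inherits(ts, "POSIXct")) {
    parsed <- lubridate::ymd_hms(as.character(ts), tz = "UTC", quiet = TRUE)
    # fall back to date-only rows
    only_date <- is.na(parsed) & !is.na(lubridate::ymd(as.character(ts), quiet = TRUE))
    parsed[only_date] <- lubridate::ymd(as.character(ts)[only_date], tz = "UTC")
    if (any(is.na(parsed) & !is.na(ts))) {
      bad <- which(is.na(parsed) & !is.na(ts))[1]
      abort(sprintf("malformed timestamp at row %d: '%s'", bad, as.character(ts)[bad]))
    }
    if (any(is.na(parsed))) {
      abort(sprintf("missing timestamp at row %d", which(is.na(parsed))[1]))
    }
    reports$timestamp <- parsed
  }
  reports
}

#' Apply the report-level filters
#'
#' In order: (1) drop reports outside the policy's month window; (2) keep
#' only the latest report per user per calendar day (ties on the timestamp
#' keep the later input row); (3) drop every report from users with fewer
#' than `min_report_days` distinct retained days. Output rows are ordered
#' by user then timestamp. The operation is idempotent.
#'
#' @param reports Tibble with at least `user_id` and `timestamp` columns;
#'   character timestamps are parsed as ISO-8601.
#' @param policy A [filter_policy()].
#' @return The filtered tibble, with a `date` column added.
#' @export
filter_reports <- function(reports, policy = filter_policy()) {
  assert_columns(reports, c("user_id", "timestamp"), "reports")
  reports <- parse_report_timestamps(as_tibble(reports))
  reports$date <- as.Date(reports$timestamp, tz = "UTC")

  if (policy$min_days_before_window) {
    day_counts <- reports %>%
      group_by(.data$user_id) %>%
      summarise(n_days = n_distinct(.data$date), .groups = "drop")
    keep_users <- day_counts$user_id[day_counts$n_days >= policy$min_report_days]
    reports <- filter(reports, .data$user_id %in% keep_users)
  }

  out <- filter(reports, lubridate::month(.data$date) %in% policy$months)

  if (policy$latest_per_day) {
    out <- out %>%
      mutate(.row = row_number()) %>%
      group_by(.data$user_id, .data$date) %>%
      # latest timestamp wins; ties keep the later input row
      arrange(.data$timestamp, .data$.row, .by_group = TRUE) %>%
      slice(n()) %>%
      ungroup() %>%
      select(-".row")
  }

  if (!policy$min_days_before_window) {
    day_counts <- out %>%
      group_by(.data$user_id) %>%
      summarise(n_days = n_distinct(.data$date), .groups = "drop")
    keep_users <- day_counts$user_id[day_counts$n_days >= policy$min_report_days]
    out <- filter(out, .data$user_id %in% keep_users)
  }

  arrange(out, .data$user_id, .data$timestamp)
}

#' Preprocess raw reports for analysis
#'
#' Applies [filter_reports()], attaches the region category, labels each
#' report urban or rural and derives `max_score`.
#'
#' @param reports Raw reports tibble (`user_id`, `timestamp`, `region_id`,
#'   `nose`, `eyes`, `breathing`, `taken_meds`).
#' @param regions Tibble with `region_id` and `category` (ONS-style code).
#' @param policy A [filter_policy()].
#' @return Filtered tibble with `date`, `max_score` and `land_use` columns.
#' @export
#' @examples
#' study <- simulate_study(simulation_config(n_users = 40, n_regions = 6,
#'                                           variables = "grass",
#'                                           sites_per_variable = 1, seed = 7))
#' pp <- preprocess_reports(study$reports, study$region_map$regions)
#' table(pp$land_use)
preprocess_reports <- function(reports, regions, policy = filter_policy()) {
  assert_columns(reports, c("user_id", "timestamp", "region_id",
                            "nose", "eyes", "breathing"), "reports")
  assert_columns(regions, c("region_id", "category"), "regions")
  out <- filter_reports(reports, policy)
  out <- left_join(out, regions[, c("region_id", "category")], by = "region_id")
  if (any(is.na(out$category))) {
    abort(sprintf(
      "report region '%s' not present in the region table",
      out$region_id[which(is.na(out$category))[1]]
    ))
  }
  out$land_use <- label_land_use(out$category)
  out$max_score <- compute_max_score(out$nose, out$eyes, out$breathing)
  out
}
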