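#' Aggregate hourly sensor measurements to daily means and maxima
#'
#' Pollutant and meteorological series are hourly; a site-day is kept only
#' when at least `min_completeness * 24` hourly values are present, and its
#' daily mean and maximum are taken over the valid hours. Pollen variables
#' are daily grain counts and pass through unchanged (the count becomes
#' `mean_value`, `max_value` is `NA`).
#'
#' @param measurements Tibble: `site_id`, `timestamp`, `value`.
#' @param sites Tibble: `site_id`, `variable` (and usually `region_id`,
#'   `site_type`).
#' @param min_completeness Minimum fraction of the 24 hours that must be
#'   valid, in `(0, 1]`. Defaults to 0.75, a transparent completeness
#'   threshold used in place of hourly imputation.
#' @return Tibble: `site_id`, `variable`, `date`, `mean_value`,
#'   `max_value`, `n_hours`.
#' @export
daily_aggregate <- function(measurements, sites, min_completeness = 0.75) {
  if (min_completeness <= 0 || min_completeness > 1) {
    abort("min_completeness must lie in (0, 1]")
  }
  assert_columns(measurements, c("site_id", "timestamp", "value"), "measurements")
  assert_columns(sites, c("site_id", "variable"), "sites")
  m <- as_tibble(measurements) %>%
    left_join(sites[, c("site_id", "variable")], by = "site_id")
  if (any(is.na(m$variable))) {
    abort("measurements reference site_id values absent from the site table")
  }
  m$date <- as.Date(m$timestamp, tz = "UTC")

  pollen <- filter(m, is_pollen_var(.data$variable))
  if (any(pollen$value < 0, na.rm = TRUE)) {
    abort("negative pollen counts are invalid")
  }
  hourly <- filter(m, !is_pollen_var(.data$variable))

  empty_daily <- tibble(
    site_id = character(), variable = character(),
    date = as.Date(character()), mean_value = numeric(),
    max_value = numeric(), n_hours = integer()
  )

  out_hourly <- if (nrow(hourly) == 0) empty_daily else hourly %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$site_id, .data$variable, .data$date) %>%
    summarise(
      mean_value = mean(.data$value),
      max_value = max(.data$value),
      n_hours = n(),
      .groups = "drop"
    ) %>%
    filter(.data$n_hours >= min_completeness * 24)

  out_pollen <- if (nrow(pollen) == 0) empty_daily else pollen %>%
    filter(!is.na(.data$value)) %>%
    group_by(.data$site_id, .data$variable, .data$date) %>%
    summarise(
      mean_value = mean(.data$value),
      n_hours = n(),
      .groups = "drop"
    ) %>%
    mutate(max_value = NA_real_)

  bind_rows(out_hourly, out_pollen[, names(out_hourly)]) %>%
    arrange(.data$variable, .data$site_id, .data$date)
}

# Edge tibble -> named list of neighbour vectors (symmetric closure).
adjacency_neighbours <- function(adjacency, regions) {
  nb <- setNames(vector("list", length(regions)), regions)
  for (r in regions) nb[[r]] <- character()
  if (nrow(adjacency) > 0) {
    for (i in seq_len(nrow(adjacency))) {
      a <- adjacency$region_a[i]
      b <- adjacency$region_b[i]
      if (a == b) next
      nb[[a]] <- c(nb[[a]], b)
      nb[[b]] <- c(nb[[b]], a)
    }
    nb <- lapply(nb, unique)
  }
  nb
}

#' Concentric rings around a region
#'
#' Ring 0 is the region itself; ring k contains the regions at graph
#' distance exactly k along the adjacency relation. Built by breadth-first
#' expansion, stopping at `max_ring` or when the reachable component is
#' exhausted. The rings partition the reachable regions.
#'
#' @param region_id Query region.
#' @param adjacency Edge tibble with columns `region_a`, `region_b`.
#' @param regions Character vector of all region identifiers.
#' @param max_ring Largest ring index to expand to (`Inf` = unbounded).
#' @return List of character vectors; element k+1 is ring k.
#' @export
#' @examples
#' adj <- tibble::tibble(region_a = c("A", "B"), region_b = c("B", "C"))
#' build_rings("A", adj, c("A", "B", "C"))
build_rings <- function(region_id, adjacency, regions, max_ring = Inf) {
  if (!region_id %in% regions) {
    abort(sprintf("unknown region '%s'", region_id))
  }
  if (max_ring < 0) abort("max_ring must be >= 0")
  nb <- adjacency_neighbours(adjacency, regions)
  rings <- list(region_id)
  seen <- region_id
  k <- 0
  while (k < max_ring) {
    frontier <- unique(unlist(nb[rings[[k + 1]]], use.names = FALSE))
    frontier <- setdiff(frontier, seen)
    if (length(frontier) == 0) break
    frontier <- sort(frontier)
    rings[[k + 2]] <- frontier
    seen <- c(seen, frontier)
    k <- k + 1
  }
  rings
}

# Graph distance from every region to every other, by repeated ring
# expansion. Rows = source regions; unreachable pairs are Inf.
region_distances <- function(adjacency, regions) {
  n <- length(regions)
  d <- matrix(Inf, n, n, dimnames = list(regions, regions))
  for (r in regions) {
    rings <- build_rings(r, adjacency, regions)
    for (k in seq_along(rings)) d[r, rings[[k]]] <- k - 1
  }
  d
}

#' Estimate a region-day environmental value via concentric rings
#'
#' Searches outward from the region: if one or more sites measuring the
#' variable have a value for that date in the region itself (ring 0), their
#' mean is used; otherwise the directly adjacent regions (ring 1) are
#' searched, then the next ring, until sites with data are found or
#' `max_ring` is exceeded.
#'
#' @param region_id Query region.
#' @param date Query date.
#' @param variable Environmental variable name.
#' @param daily_site_values Output of [daily_aggregate()], joined with
#'   site regions (columns `site_id`, `variable`, `region_id`, `date`,
#'   `mean_value`, `max_value`).
#' @param adjacency Edge tibble.
#' @param regions All region identifiers.
#' @param max_ring Search bound (`Inf` = whole component).
#' @param statistic `"mean"` to average the sites' daily means, `"max"`
#'   for their daily maxima.
#' @param max_combine How to combine the winning ring's site maxima:
#'   `"mean"` (default) or `"max"`.
#' @return One-row tibble (`region_id`, `variable`, `date`, `mean_value`,
#'   `max_value`, `ring_used`, `n_sites`) or a zero-row tibble when no
#'   ring within reach has data. Missing is a value, not an error.
#' @export
estimate_region_value <- function(region_id, date, variable,
                                  daily_site_values, adjacency, regions,
                                  max_ring = Inf,
                                  max_combine = c("mean", "max")) {
  max_combine <- match.arg(max_combine)
  date <- as.Date(date)
  rings <- build_rings(region_id, adjacency, regions, max_ring)
  cand <- filter(
    daily_site_values,
    .data$variable == !!variable, .data$date == !!date
  )
  for (k in seq_along(rings)) {
    hit <- filter(cand, .data$region_id %in% rings[[k]])
    if (nrow(hit) > 0) {
      return(tibble(
        region_id = region_id, variable = variable, date = date,
        mean_value = mean(hit$mean_value),
        max_value = if (all(is.na(hit$max_value))) NA_real_ else {
          if (max_combine == "mean") mean(hit$max_value, na.rm = TRUE)
          else max(hit$max_value, na.rm = TRUE)
        },
        ring_used = k - 1L, n_sites = nrow(hit)
      ))
    }
  }
  tibble(
    region_id = character(), variable = character(),
    date = as.Date(character()), mean_value = numeric(),
    max_value = numeric(), ring_used = integer(), n_sites = integer()
  )
}

#' Estimate environmental values for every region, variable and date
#'
#' Vectorised concentric-regions estimation: for each region the sites at
#' the minimum graph distance holding data on a date supply the estimate
#' (mean of their daily means; maxima combined per `max_combine`).
#' Equivalent to calling [estimate_region_value()] over the full grid.
#'
#' @inheritParams estimate_region_value
#' @param sites Site table with `site_id` and `region_id` (used when
#'   `daily_site_values` lacks a `region_id` column).
#' @return Tibble of estimates, one row per (region, variable, date) with
#'   data within reach: `region_id`, `variable`, `date`, `mean_value`,
#'   `max_value`, `ring_used`, `n_sites`.
#' @export
estimate_region_values <- function(daily_site_values, sites, adjacency,
                                   regions, max_ring = Inf,
                                   max_combine = c("mean", "max")) {
  max_combine <- match.arg(max_combine)
  dsv <- as_tibble(daily_site_values)
  if (!"region_id" %in% names(dsv)) {
    dsv <- left_join(dsv, sites[, c("site_id", "region_id")], by = "site_id")
  }
  assert_columns(dsv, c("site_id", "variable", "region_id", "date",
                        "mean_value", "max_value"), "daily_site_values")
  if (nrow(dsv) == 0) {
    return(tibble(
      region_id = character(), variable = character(),
      date = as.Date(character()), mean_value = numeric(),
      max_value = numeric(), ring_used = integer(), n_sites = integer()
    ))
  }
  dist <- region_distances(adjacency, regions)
  combine_max <- if (max_combine == "mean") {
    function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  } else {
    function(x) if (all(is.na(x))) NA_real_ else max(x, na.rm = TRUE)
  }
  out <- vector("list", length(regions))
  for (i in seq_along(regions)) {
    r <- regions[i]
    d_here <- dist[r, dsv$region_id]
    rows <- dsv[is.finite(d_here) & d_here <= max_ring, ]
    if (nrow(rows) == 0) next
    rows$.dist <- dist[r, rows$region_id]
    out[[i]] <- rows %>%
      group_by(.data$variable, .data$date) %>%
      filter(.data$.dist == min(.data$.dist)) %>%
      summarise(
        mean_value = mean(.data$mean_value),
        max_value = combine_max(.data$max_value),
        ring_used = as.integer(.data$.dist[1]),
        n_sites = n(),
        .groups = "drop"
      ) %>%
      mutate(region_id = r)
  }
  bind_rows(out) %>%
    select("region_id", "variable", "date", "mean_value", "max_value",
           "ring_used", "n_sites") %>%
    arrange(.data$region_id, .data$variable, .data$date)
}

#' Link reports to regional environmental estimates
#'
#' Left-joins each report's (region, date) onto the regional estimates,
#' adding one column per environmental variable. Pollutant and
#' meteorological variables contribute both a `<var>_mean` and a
#' `<var>_max` column; pollen variables contribute a single daily-count
#' column named after the taxon. Reports without an estimate keep their
#' row with missing linked values.
#'
#' @param reports Preprocessed reports (with `region_id` and `date`).
#' @param estimates Output of [estimate_region_values()].
#' @param matching `"concentric"` links every estimate; `"same_region"`
#'   first restricts the estimates to `ring_used == 0`, i.e. regions with
#'   their own sensors, and is recorded in the `matching` attribute.
#' @return The reports tibble with the linked environmental columns.
#' @export
match_reports_to_environment <- function(reports, estimates,
                                         matching = c("concentric",
                                                      "same_region")) {
  matching <- match.arg(matching)
  assert_columns(reports, c("region_id", "date"), "reports")
  # every variable present before ring filtering keeps its column, so
  # same-region matching yields all-missing columns rather than dropping
  # variables without in-region sensors
  all_vars <- unique(estimates$variable)
  expected_cols <- unlist(lapply(all_vars, function(v) {
    if (is_pollen_var(v)) v else paste0(v, c("_mean", "_max"))
  }))
  if (matching == "same_region" && nrow(estimates) > 0) {
    estimates <- filter(estimates, .data$ring_used == 0L)
  }
  if (nrow(estimates) == 0) {
    out <- as_tibble(reports)
    for (col in expected_cols) out[[col]] <- NA_real_
    attr(out, "matching") <- matching
    return(out)
  }
  wide <- estimates %>%
    mutate(
      value_mean = .data$mean_value,
      value_max = .data$max_value
    ) %>%
    select("region_id", "date", "variable", "value_mean", "value_max") %>%
    tidyr::pivot_longer(
      c("value_mean", "value_max"),
      names_to = "stat", names_prefix = "value_", values_to = "value"
    ) %>%
    filter(!(is_pollen_var(.data$variable) & .data$stat == "max")) %>%
    mutate(col = ifelse(
      is_pollen_var(.data$variable), .data$variable,
      paste0(.data$variable, "_", .data$stat)
    )) %>%
    select("region_id", "date", "col", "value") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "value")
  out <- left_join(as_tibble(reports), wide, by = c("region_id", "date"))
  for (col in setdiff(expected_cols, names(out))) out[[col]] <- NA_real_
  attr(out, "matching") <- matching
  out
}
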