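period_key <- function(date, frequency) {
  switch(frequency,
    daily = as.character(date),
    weekly = sprintf("%d-W%02d", lubridate::isoyear(date),
                     lubridate::isoweek(date)),
    monthly = format(date, "%Y-%m"),
    yearly = format(date, "%Y"),
    abort(sprintf("unknown frequency '%s'", frequency))
  )
}

#' Aggregate a daily series to period means
#'
#' Periods are ISO calendar weeks, calendar months or calendar years; each
#' (year, period) combination is a distinct observation, so July 2016 and
#' July 2017 are separate points.
#'
#' @param series Tibble with columns `date` and `value`.
#' @param frequency One of `"daily"`, `"weekly"`, `"monthly"`, `"yearly"`.
#' @return Tibble: `period`, `value` (mean of available daily values),
#'   `n_days`.
#' @export
#' @examples
#' s <- tibble::tibble(date = as.Date("2016-03-01") + 0:5, value = 1:6)
#' aggregate_period(s, "monthly")
aggregate_period <- function(series, frequency) {
  assert_columns(series, c("date", "value"), "series")
  series %>%
    mutate(period = period_key(.data$date, frequency)) %>%
    group_by(.data$period) %>%
    summarise(
      value = mean(.data$value, na.rm = TRUE),
      n_days = sum(!is.na(.data$value)),
      .groups = "drop"
    )
}

#' Pearson correlation with a two-tailed p-value
#'
#' Pearson product-moment correlation on pairwise-complete observations,
#' with the two-tailed p-value from the t transform on n - 2 degrees of
#' freedom. Spearman's rank correlation is available for sensitivity
#' analyses.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List: `r`, `p_two_tailed`, `n`.
#' @export
#' @examples
#' correlate(1:5, c(2, 4, 6, 8, 10))$r
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) abort("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 3) abort("correlate needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlate undefined: zero variance in a series")
  }
  ct <- suppressWarnings(cor.test(x, y, method = method))
  list(r = unname(ct$estimate), p_two_tailed = ct$p.value, n = length(x))
}

env_candidate_stats <- function(variables) {
  rows <- list()
  for (v in variables) {
    if (is_pollen_var(v)) {
      rows[[length(rows) + 1]] <- tibble(variable = v, statistic = "count")
    } else {
      rows[[length(rows) + 1]] <- tibble(variable = v,
                                         statistic = c("mean", "max"))
    }
  }
  bind_rows(rows)
}

# Daily UK-wide env value: mean over the selected sites' daily values.
ukwide_env_daily <- function(daily_site_values, site_ids, statistic) {
  col <- if (statistic == "max") "max_value" else "mean_value"
  daily_site_values %>%
    filter(.data$site_id %in% site_ids) %>%
    group_by(.data$date) %>%
    summarise(value = mean(.data[[col]], na.rm = TRUE), .groups = "drop") %>%
    filter(!is.na(.data$value))
}

select_sites <- function(sites, variable, sensor_filter, stratum) {
  s <- filter(sites, .data$variable == !!variable)
  if (!variable %in% .pollutant_vars) return(s$site_id)
  switch(sensor_filter,
    all_background = s$site_id[s$site_type %in%
                                 c("urban_background", "rural_background")],
    stratified = s$site_id[s$site_type ==
                             paste0(stratum, "_background")],
    all_types = s$site_id,
    abort(sprintf("unknown sensor_filter '%s'", sensor_filter))
  )
}

#' UK-wide symptom-environment correlations by land-use stratum
#'
#' For each land-use stratum, symptom measure and environmental variable
#' and statistic: the symptom series is the period mean of the stratum's
#' daily mean scores; the environmental series is the period mean of the
#' UK-wide daily value over the selected sites. Pollutant sites are
#' filtered by `sensor_filter` (`"all_background"` keeps urban and rural
#' background sites, the configuration behind UK-wide tables;
#' `"stratified"` pairs urban reports with urban-background and rural
#' reports with rural-background sensors, pollutants only; `"all_types"`
#' keeps every site). Pollen and meteorology sites are unclassified and
#' always included except in `"stratified"` mode, which is restricted to
#' pollutants. Only rows with `p <= alpha` are returned, ordered by
#' significance then absolute correlation.
#'
#' @param reports Preprocessed reports.
#' @param daily_site_values Output of [daily_aggregate()].
#' @param sites Site table.
#' @param sensor_filter See above.
#' @param frequency Aggregation period (default `"monthly"`).
#' @param measures Symptom measures to correlate.
#' @param alpha Significance threshold for inclusion (default 0.05; set to
#'   1 to keep every row).
#' @param method Correlation method, see [correlate()].
#' @return Tibble: `stratum`, `env_variable`, `statistic`,
#'   `symptom_measure`, `sensor_filter`, `aggregation`, `r`,
#'   `p_two_tailed`, `n_points`.
#' @export
ukwide_correlations <- function(reports, daily_site_values, sites,
                                sensor_filter = c("all_background",
                                                  "stratified", "all_types"),
                                frequency = "monthly",
                                measures = symptom_measures(),
                                alpha = 0.05,
                                method = "pearson") {
  sensor_filter <- match.arg(sensor_filter)
  variables <- sort(unique(sites$variable))
  if (sensor_filter == "stratified") {
    variables <- intersect(variables, .pollutant_vars)
  }
  cand <- env_candidate_stats(variables)
  rows <- list()
  for (stratum in c("urban", "rural")) {
    symptom_period <- list()
    for (m in measures) {
      dm <- daily_group_means(reports, m)
      dm <- dm[dm$land_use == stratum, c("date", "value")]
      if (nrow(dm) == 0) next
      symptom_period[[m]] <- aggregate_period(dm, frequency)
    }
    for (i in seq_len(nrow(cand))) {
      v <- cand$variable[i]
      st <- cand$statistic[i]
      ids <- select_sites(sites, v, sensor_filter, stratum)
      if (length(ids) == 0) next
      env_daily <- ukwide_env_daily(
        daily_site_values, ids, if (st == "count") "mean" else st
      )
      if (nrow(env_daily) == 0) next
      env_period <- aggregate_period(env_daily, frequency)
      for (m in names(symptom_period)) {
        joined <- inner_join(
          symptom_period[[m]], env_period,
          by = "period", suffix = c("_sym", "_env")
        )
        if (nrow(joined) < 3) next
        res <- tryCatch(
          correlate(joined$value_sym, joined$value_env, method),
          error = function(e) NULL
        )
        if (is.null(res)) next
        rows[[length(rows) + 1]] <- tibble(
          stratum = stratum, env_variable = v, statistic = st,
          symptom_measure = m, sensor_filter = sensor_filter,
          aggregation = frequency, r = res$r,
          p_two_tailed = res$p_two_tailed, n_points = res$n
        )
      }
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out %>%
    filter(.data$p_two_tailed <= alpha) %>%
    arrange(.data$p_two_tailed, -abs(.data$r))
}

#' Regional symptom-environment correlations
#'
#' Correlates report-level symptom scores with the environmental estimate
#' linked to each report's (region, date) — concentric-regions estimates,
#' or same-region-only estimates obtained by filtering to `ring_used == 0`
#' before linking. At the daily frequency each report is one pair; at
#' weekly/monthly/yearly frequencies symptom and environment are first
#' averaged per (region, period) (set `average = "report"` to keep
#' report-level pairs with period-averaged environment instead). Only rows
#' with `p <= alpha` are returned.
#'
#' @param linked_reports Output of [match_reports_to_environment()].
#' @param env_columns Environmental columns to correlate (e.g. `"grass"`,
#'   `"so2_mean"`); defaults to every linked column found.
#' @param frequency Aggregation period.
#' @param measures Symptom measures.
#' @param alpha Significance threshold (default 0.05).
#' @param average `"region"` or `"report"`, see above.
#' @param method Correlation method.
#' @return Tibble: `env_variable`, `symptom_measure`, `aggregation`,
#'   `matching`, `r`, `p_two_tailed`, `n_points`. The `matching` column is
#'   filled with `attr(linked_reports, "matching")` when present, else
#'   `"concentric"`.
#' @export
regional_correlations <- function(linked_reports, env_columns = NULL,
                                  frequency = "daily",
                                  measures = symptom_measures(),
                                  alpha = 0.05,
                                  average = c("region", "report"),
                                  method = "pearson") {
  average <- match.arg(average)
  matching <- attr(linked_reports, "matching") %||% "concentric"
  known_cols <- c(
    .pollen_vars,
    paste0(c(.pollutant_vars, .met_vars), "_mean"),
    paste0(c(.pollutant_vars, .met_vars), "_max")
  )
  if (is.null(env_columns)) {
    env_columns <- intersect(known_cols, names(linked_reports))
  }
  rows <- list()
  lr <- linked_reports %>%
    mutate(period = period_key(.data$date, frequency))
  for (v in env_columns) {
    for (m in measures) {
      if (frequency == "daily" || average == "report") {
        pairs <- lr %>%
          select(sym = all_of(m), env = all_of(v),
                 region_id = "region_id", period = "period")
        if (average == "report" && frequency != "daily") {
          env_period <- lr %>%
            group_by(.data$region_id, .data$period) %>%
            summarise(env = mean(.data[[v]], na.rm = TRUE), .groups = "drop")
          pairs <- lr %>%
            select(sym = all_of(m), region_id = "region_id",
                   period = "period") %>%
            left_join(env_period, by = c("region_id", "period"))
        }
      } else {
        pairs <- lr %>%
          group_by(.data$region_id, .data$period) %>%
          summarise(
            sym = mean(.data[[m]], na.rm = TRUE),
            env = mean(.data[[v]], na.rm = TRUE),
            .groups = "drop"
          )
      }
      res <- tryCatch(correlate(pairs$sym, pairs$env, method),
                      error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1]] <- tibble(
        env_variable = v, symptom_measure = m, aggregation = frequency,
        matching = matching, r = res$r,
        p_two_tailed = res$p_two_tailed, n_points = res$n
      )
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) return(out)
  out %>%
    filter(.data$p_two_tailed <= alpha) %>%
    arrange(.data$p_two_tailed, -abs(.data$r))
}

#' Inter-sensor correlation diagnostics
#'
#' How well sites measuring the same variable agree, as a check on whether
#' a sparse network can represent regional conditions. For each variable:
#' the within-region row reports, over regions holding at least two sites
#' with at least one significantly correlated pair (daily series,
#' `p <= alpha`), the median of the regions' median pairwise correlations,
#' plus the count of such regions; the UK-wide row reports the median
#' significant pairwise correlation over all site pairs.
#'
#' @param daily_site_values Output of [daily_aggregate()].
#' @param sites Site table.
#' @param variables Variables to report (default: all present).
#' @param alpha Significance threshold on pairwise correlations.
#' @return Tibble: `variable`, `scope` (`"within_region"` / `"ukwide"`),
#'   `region_count_with_pairs`, `median_pairwise_r`, `n_pairs`. The
#'   within-region row is present (with a zero count and missing median)
#'   even when no region has a qualifying pair, mirroring the pollen
#'   pattern of single-site regions.
#' @export
intersensor_correlations <- function(daily_site_values, sites,
                                     variables = NULL, alpha = 0.05) {
  dsv <- as_tibble(daily_site_values)
  if (!"region_id" %in% names(dsv)) {
    dsv <- left_join(dsv, sites[, c("site_id", "region_id")], by = "site_id")
  }
  if (is.null(variables)) variables <- sort(unique(dsv$variable))
  rows <- list()
  for (v in variables) {
    sv <- filter(dsv, .data$variable == !!v)
    ids <- sort(unique(sv$site_id))
    if (length(ids) < 2) next
    wide <- sv %>%
      select("site_id", "date", "mean_value") %>%
      tidyr::pivot_wider(names_from = "site_id", values_from = "mean_value")
    site_region <- sites$region_id[match(ids, sites$site_id)]
    pair_rows <- list()
    for (i in seq_len(length(ids) - 1)) {
      for (j in (i + 1):length(ids)) {
        res <- tryCatch(
          correlate(wide[[ids[i]]], wide[[ids[j]]]),
          error = function(e) NULL
        )
        if (is.null(res)) next
        pair_rows[[length(pair_rows) + 1]] <- tibble(
          site_a = ids[i], site_b = ids[j],
          same_region = site_region[i] == site_region[j],
          region_id = ifelse(site_region[i] == site_region[j],
                             site_region[i], NA_character_),
          r = res$r, p = res$p_two_tailed
        )
      }
    }
    pairs <- bind_rows(pair_rows)
    if (nrow(pairs) == 0) next
    sig <- filter(pairs, .data$p <= alpha)

    within <- sig %>%
      filter(.data$same_region) %>%
      group_by(.data$region_id) %>%
      summarise(region_median = median(.data$r), .groups = "drop")
    rows[[length(rows) + 1]] <- tibble(
      variable = v, scope = "within_region",
      region_count_with_pairs = nrow(within),
      median_pairwise_r = if (nrow(within) > 0) median(within$region_median)
        else NA_real_,
      n_pairs = sum(sig$same_region)
    )
    rows[[length(rows) + 1]] <- tibble(
      variable = v, scope = "ukwide",
      region_count_with_pairs = NA_integer_,
      median_pairwise_r = if (nrow(sig) > 0) median(sig$r) else NA_real_,
      n_pairs = nrow(sig)
    )
  }
  bind_rows(rows)
}
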