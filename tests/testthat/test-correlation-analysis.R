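test_that("period aggregation follows the ISO calendar", {
  s <- tibble::tibble(date = as.Date("2016-03-05") + 0:20, value = 3)
  expect_true(all(aggregate_period(s, "monthly")$value == 3))

  two <- tibble::tibble(date = as.Date(c("2016-03-01", "2016-03-20")),
                        value = c(1, 3))
  expect_equal(aggregate_period(two, "monthly")$value, 2)

  wk <- tibble::tibble(
    date = as.Date(c("2016-03-07", "2016-03-13", "2016-03-14")),
    value = c(1, 2, 9)
  )
  out <- aggregate_period(wk, "weekly")
  expect_equal(nrow(out), 2)  # Mon 7th + Sun 13th share an ISO week
  expect_equal(sort(out$value), c(1.5, 9))

  # July 2016 and July 2017 are distinct observations
  yrs <- tibble::tibble(
    date = as.Date(c("2016-07-01", "2017-07-01")), value = c(1, 5)
  )
  expect_equal(nrow(aggregate_period(yrs, "monthly")), 2)
  expect_error(aggregate_period(yrs, "fortnightly"), "unknown frequency")
})

test_that("Pearson correlation matches the closed form", {
  expect_equal(correlate(1:5, 2 * (1:5) + 1)$r, 1)
  expect_equal(correlate(1:5, -(1:5))$r, -1)
  expect_equal(correlate(c(1, 2, 3), c(1, 3, 2))$r, 0.5)
  expect_error(correlate(c(1, 2), c(1, 2)), "at least 3")
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "zero variance")

  # exhaustive small-case oracle: every 3-point integer sample over 0..3
  grid <- expand.grid(a = 0:3, b = 0:3, c = 0:3)
  triples <- lapply(seq_len(nrow(grid)), function(i) as.numeric(grid[i, ]))
  for (x in triples) {
    if (sd(x) == 0) next
    for (y in triples[seq(1, length(triples), by = 7)]) {
      if (sd(y) == 0) next
      closed <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(correlate(x, y)$r, closed)
    }
  }
})

small_env_study <- function(seed, pollen_effect = 1.2, urban_offset = 0.6) {
  simulate_study(simulation_config(
    n_users = 80, n_regions = 8, sites_per_variable = 1,
    variables = c("grass", "so2", "o3"),
    pollen_effect = pollen_effect, urban_offset = urban_offset,
    seed = seed
  ))
}

test_that("a planted linear relationship yields r = 1 and survives filters", {
  study <- small_env_study(61)
  pp <- preprocess_reports(study$reports, study$region_map$regions,
                           filter_policy(min_report_days = 5))
  dsv <- daily_aggregate(study$network$measurements, study$network$sites)

  # plant: make one site's series equal the urban daily mean of max_score
  dm <- daily_group_means(pp, "max_score")
  urban <- dm[dm$land_use == "urban", ]
  plant <- tibble::tibble(
    site_id = "so2_s01", variable = "so2", date = urban$date,
    mean_value = urban$value, max_value = urban$value, n_hours = 24L
  )
  dsv2 <- dplyr::bind_rows(dsv[dsv$variable != "so2", ], plant)
  sites2 <- study$network$sites
  sites2$site_type[sites2$site_id == "so2_s01"] <- "urban_background"

  uk <- ukwide_correlations(pp, dsv2, sites2, "all_background", "monthly")
  planted <- uk[uk$env_variable == "so2" & uk$statistic == "mean" &
                  uk$symptom_measure == "max_score" &
                  uk$stratum == "urban", ]
  expect_equal(planted$r, 1)

  # the significance filter lets no p > 0.05 row through, and ordering is
  # by significance
  expect_true(all(uk$p_two_tailed <= 0.05))
  expect_true(!is.unsorted(uk$p_two_tailed))
})

test_that("pollen-driven symptoms correlate with grass in both strata", {
  study <- small_env_study(71)
  pp <- preprocess_reports(study$reports, study$region_map$regions,
                           filter_policy(min_report_days = 5))
  dsv <- daily_aggregate(study$network$measurements, study$network$sites)
  uk <- ukwide_correlations(pp, dsv, study$network$sites,
                            "all_background", "monthly")
  for (g in c("urban", "rural")) {
    row <- uk[uk$env_variable == "grass" & uk$symptom_measure == "max_score" &
                uk$stratum == g, ]
    expect_equal(nrow(row), 1)
    expect_gt(row$r, 0)
  }
})

test_that("regional correlations respect the matching mode", {
  study <- small_env_study(81)
  pp <- preprocess_reports(study$reports, study$region_map$regions,
                           filter_policy(min_report_days = 5))
  dsv <- daily_aggregate(study$network$measurements, study$network$sites)
  regions <- study$region_map$regions$region_id

  # a site in every region: concentric and same-region linking coincide
  dsv0 <- dsv[dsv$variable == "grass", ]
  full <- dplyr::bind_rows(lapply(seq_along(regions), function(i) {
    d <- dsv0[dsv0$site_id == dsv0$site_id[1], ]
    d$site_id <- paste0("g", i)
    d$mean_value <- d$mean_value + i
    d
  }))
  sites_full <- tibble::tibble(
    site_id = paste0("g", seq_along(regions)), variable = "grass",
    region_id = regions, site_type = "unclassified"
  )
  est <- estimate_region_values(full, sites_full, study$region_map$adjacency,
                                regions)
  expect_true(all(est$ring_used == 0L))
  conc <- regional_correlations(
    match_reports_to_environment(pp, est), frequency = "daily",
    measures = "max_score", alpha = 1
  )
  same <- regional_correlations(
    match_reports_to_environment(pp, est, "same_region"),
    frequency = "daily", measures = "max_score", alpha = 1
  )
  expect_equal(conc$r, same$r)
  expect_equal(conc$matching, "concentric")
  expect_equal(same$matching, "same_region")

  # no in-region sensors anywhere: same-region output is empty
  est1 <- est
  est1$ring_used <- 1L
  empty <- regional_correlations(
    match_reports_to_environment(pp, est1, "same_region"),
    frequency = "daily", measures = "max_score"
  )
  expect_equal(nrow(empty), 0)

  # the pollen driver shows up as a positive significant daily correlation
  est_real <- estimate_region_values(dsv, study$network$sites,
                                     study$region_map$adjacency, regions)
  rc <- regional_correlations(
    match_reports_to_environment(pp, est_real), frequency = "daily",
    measures = "max_score"
  )
  grass_row <- rc[rc$env_variable == "grass", ]
  expect_equal(nrow(grass_row), 1)
  expect_gt(grass_row$r, 0)
  expect_lte(grass_row$p_two_tailed, 0.05)
})

test_that("planted relationships survive aggregation coarsening", {
  # noiseless linear link: |r| = 1 at every frequency
  dates <- seq(as.Date("2016-03-01"), as.Date("2016-09-30"), by = "day")
  env <- tibble::tibble(date = dates, value = seq_along(dates))
  sym <- tibble::tibble(date = dates, value = 2 * seq_along(dates) + 3)
  for (f in c("daily", "weekly", "monthly")) {
    e <- aggregate_period(env, f)
    s <- aggregate_period(sym, f)
    expect_equal(correlate(e$value, s$value)$r, 1)
  }
})

test_that("inter-sensor medians summarise site agreement", {
  dates <- as.Date("2019-03-01") + 0:119
  base <- sin(seq_along(dates) / 9) * 10 + 20
  mk <- function(id, region, values) {
    tibble::tibble(site_id = id, variable = "pm25", region_id = region,
                   date = dates, mean_value = values, max_value = values)
  }
  sites <- tibble::tibble(
    site_id = c("a", "b", "c"), variable = "pm25",
    region_id = c("R1", "R1", "R2"), site_type = "urban_background"
  )
  dsv <- dplyr::bind_rows(
    mk("a", "R1", base), mk("b", "R1", base), mk("c", "R2", rev(base))
  )
  out <- intersensor_correlations(dsv, sites)
  within <- out[out$scope == "within_region", ]
  expect_equal(within$region_count_with_pairs, 1L)
  expect_equal(within$median_pairwise_r, 1)

  # single site per region everywhere: zero-count within-region row
  sites1 <- sites
  sites1$region_id <- c("R1", "R2", "R3")
  dsv1 <- dplyr::bind_rows(
    mk("a", "R1", base), mk("b", "R2", base + rnorm(120)),
    mk("c", "R3", base + rnorm(120))
  )
  out1 <- intersensor_correlations(dsv1, sites1)
  w1 <- out1[out1$scope == "within_region", ]
  expect_equal(w1$region_count_with_pairs, 0L)
  expect_true(is.na(w1$median_pairwise_r))
  expect_false(is.na(out1$median_pairwise_r[out1$scope == "ukwide"]))
})

test_that("the UK-wide inter-sensor median tracks the generator mixing", {
  rm <- generate_region_map(8, 0.5, seed = 5)
  net <- generate_sensor_network(rm, "pm25", 6, 0.8,
                                 c("2019-01-01", "2019-06-30"), seed = 15)
  dsv <- daily_aggregate(net$measurements, net$sites)
  out <- intersensor_correlations(dsv, net$sites)
  uk <- out[out$scope == "ukwide", ]
  expect_lt(abs(uk$median_pairwise_r - 0.8), 0.15)
})
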