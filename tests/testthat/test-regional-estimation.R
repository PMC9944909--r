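hourly_sites <- function() {
  tibble::tibble(
    site_id = "s1", variable = "so2", region_id = "A",
    site_type = "urban_background"
  )
}

hourly_measurements <- function(values, date = as.Date("2019-05-01")) {
  tibble::tibble(
    site_id = "s1",
    timestamp = as.POSIXct(date, tz = "UTC") + (seq_along(values) - 1) * 3600,
    value = values
  )
}

test_that("daily aggregation computes means, maxima and the completeness cut", {
  const <- daily_aggregate(hourly_measurements(rep(5, 24)), hourly_sites())
  expect_equal(const$mean_value, 5)
  expect_equal(const$max_value, 5)

  ramp <- daily_aggregate(hourly_measurements(0:23), hourly_sites())
  expect_equal(ramp$mean_value, 11.5)  # 276 / 24
  expect_equal(ramp$max_value, 23)

  short <- daily_aggregate(hourly_measurements(rep(1, 10)), hourly_sites(),
                           min_completeness = 0.75)
  expect_equal(nrow(short), 0)
  # 18 of 24 hours meets the 0.75 threshold
  kept <- daily_aggregate(hourly_measurements(rep(1, 18)), hourly_sites())
  expect_equal(nrow(kept), 1)
})

test_that("pollen counts pass through daily aggregation unchanged", {
  sites <- tibble::tibble(site_id = "g1", variable = "grass",
                          region_id = "A", site_type = "unclassified")
  meas <- tibble::tibble(
    site_id = "g1",
    timestamp = as.POSIXct(as.Date("2019-06-01") + 0:2, tz = "UTC"),
    value = c(10, 0, 55)
  )
  out <- daily_aggregate(meas, sites)
  expect_equal(out$mean_value, c(10, 0, 55))
  expect_true(all(is.na(out$max_value)))
  meas$value[2] <- -1
  expect_error(daily_aggregate(meas, sites), "negative pollen")
})

line_adjacency <- tibble::tibble(region_a = c("A", "B"),
                                 region_b = c("B", "C"))

test_that("rings partition the graph outward from the query region", {
  rings <- build_rings("A", line_adjacency, c("A", "B", "C"))
  expect_equal(rings, list("A", "B", "C"))
  # isolated region: only ring 0
  iso <- build_rings("D", line_adjacency[0, ], c("D"))
  expect_equal(iso, list("D"))
  # partition property on a random map
  rm <- generate_region_map(15, 0.5, seed = 3)
  rg <- build_rings("R005", rm$adjacency, rm$regions$region_id)
  expect_equal(sort(unlist(rg)), sort(rm$regions$region_id))
  expect_equal(anyDuplicated(unlist(rg)), 0L)
  expect_error(build_rings("nope", line_adjacency, c("A", "B", "C")),
               "unknown region")
})

toy_daily <- function(rows) {
  tibble::tibble(
    site_id = rows$site_id, variable = "so2", region_id = rows$region_id,
    date = as.Date("2019-05-01"), mean_value = rows$mean_value,
    max_value = rows$mean_value
  )
}

test_that("concentric estimation finds the nearest ring with data", {
  regions <- c("A", "B", "C")
  d0 <- toy_daily(tibble::tibble(site_id = "s1", region_id = "A",
                                 mean_value = 7))
  e0 <- estimate_region_value("A", "2019-05-01", "so2", d0,
                              line_adjacency, regions)
  expect_equal(e0$mean_value, 7)
  expect_equal(e0$ring_used, 0L)

  d1 <- toy_daily(tibble::tibble(site_id = c("s1", "s2"),
                                 region_id = c("B", "B"),
                                 mean_value = c(2, 4)))
  e1 <- estimate_region_value("A", "2019-05-01", "so2", d1,
                              line_adjacency, regions)
  expect_equal(e1$mean_value, 3)
  expect_equal(e1$n_sites, 2L)

  d2 <- toy_daily(tibble::tibble(site_id = "s9", region_id = "C",
                                 mean_value = 9))
  e2 <- estimate_region_value("A", "2019-05-01", "so2", d2,
                              line_adjacency, regions)
  expect_equal(e2$mean_value, 9)
  expect_equal(e2$ring_used, 2L)

  # missing is a value, not an error
  none <- estimate_region_value("A", "2019-05-01", "so2", d2,
                                line_adjacency, regions, max_ring = 1)
  expect_equal(nrow(none), 0)
})

random_site_day_values <- function(rm, n_sites, seed) {
  set.seed(seed)
  regions <- rm$regions$region_id
  tibble::tibble(
    site_id = sprintf("s%02d", seq_len(n_sites)),
    variable = "so2",
    region_id = sample(regions, n_sites, replace = TRUE),
    date = as.Date("2019-05-01"),
    mean_value = round(runif(n_sites, 0, 50), 1),
    max_value = round(runif(n_sites, 50, 100), 1)
  )
}

test_that("ring search agrees with a shortest-path oracle on random maps", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(3:30, 1)
    rm <- generate_region_map(n, 0.5, seed = seed,
                              connected = seed %% 4 != 0)
    regions <- rm$regions$region_id
    dsv <- random_site_day_values(rm, sample(1:6, 1), seed + 100)
    dist <- igraph_distances(rm$adjacency, regions)
    est <- estimate_region_values(dsv, NULL, rm$adjacency, regions)
    for (r in regions) {
      d_sites <- dist[r, dsv$region_id]
      row <- est[est$region_id == r, ]
      if (all(is.infinite(d_sites))) {
        expect_equal(nrow(row), 0)
      } else {
        at_min <- dsv[d_sites == min(d_sites), ]
        expect_equal(row$mean_value, mean(at_min$mean_value))
        expect_equal(row$max_value, mean(at_min$max_value))
        expect_equal(row$ring_used, as.integer(min(d_sites)))
        expect_equal(row$n_sites, nrow(at_min))
        # the one-query variant agrees with the vectorised sweep
        single <- estimate_region_value(r, "2019-05-01", "so2", dsv,
                                        rm$adjacency, regions)
        expect_equal(single$mean_value, row$mean_value)
        expect_equal(single$ring_used, row$ring_used)
      }
    }
  }
})

test_that("with a site in every region all estimates use ring 0", {
  rm <- generate_region_map(8, 0.5, seed = 4)
  regions <- rm$regions$region_id
  dsv <- tibble::tibble(
    site_id = paste0("s", seq_along(regions)), variable = "so2",
    region_id = regions, date = as.Date("2019-05-01"),
    mean_value = seq_along(regions) * 1.0,
    max_value = seq_along(regions) * 2.0
  )
  est <- estimate_region_values(dsv, NULL, rm$adjacency, regions)
  expect_true(all(est$ring_used == 0L))
  expect_equal(est$mean_value[match(regions, est$region_id)],
               dsv$mean_value)
})

test_that("growing max_ring only adds estimates, never changes early rings", {
  rm <- generate_region_map(20, 0.5, seed = 6)
  regions <- rm$regions$region_id
  dsv <- random_site_day_values(rm, 3, seed = 42)
  prev <- estimate_region_values(dsv, NULL, rm$adjacency, regions,
                                 max_ring = 0)
  for (mr in 1:4) {
    cur <- estimate_region_values(dsv, NULL, rm$adjacency, regions,
                                  max_ring = mr)
    expect_true(all(prev$region_id %in% cur$region_id))
    shared <- dplyr::inner_join(
      prev, cur, by = c("region_id", "variable", "date")
    )
    expect_equal(shared$mean_value.x, shared$mean_value.y)
    expect_equal(shared$ring_used.x, shared$ring_used.y)
    prev <- cur
  }
})

test_that("report-environment linking is a left join per region-day", {
  est <- tibble::tibble(
    region_id = "R", variable = c("grass", "so2"),
    date = as.Date("2019-06-10"),
    mean_value = c(12, 3.5), max_value = c(NA, 8),
    ring_used = c(1L, 0L), n_sites = c(1L, 2L)
  )
  reports <- tibble::tibble(
    user_id = c("u1", "u2"), region_id = "R",
    date = as.Date(c("2019-06-10", "2019-06-11")),
    max_score = c(2L, 1L)
  )
  linked <- match_reports_to_environment(reports, est)
  expect_equal(nrow(linked), nrow(reports))
  expect_equal(linked$grass, c(12, NA))
  expect_equal(linked$so2_mean, c(3.5, NA))
  expect_equal(linked$so2_max, c(8, NA))
  expect_false("grass_max" %in% names(linked))

  same <- match_reports_to_environment(reports, est, "same_region")
  expect_true(is.na(same$grass[1]))     # grass came from ring 1
  expect_equal(same$so2_mean[1], 3.5)   # so2 is in-region
  expect_equal(attr(same, "matching"), "same_region")
})
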