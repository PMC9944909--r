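#' Configuration for the synthetic symptom-diary study
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' a single March-September season of a UK-style citizen-science hay fever
#' study: a few hundred sporadically reporting users anchored to home
#' regions, zero-inflated ordinal symptom scores driven by grass pollen
#' seasonality, and a latent-scale urban severity offset.
#'
#' Ordinal scores arise from a latent-Gaussian threshold model: each
#' user-day has latent severity
#' `baseline(user) + pollen_effect * grass_scaled(day) + urban_offset * is_urban(user)`,
#' and each of the three symptoms adds independent `N(0, noise_sd)` noise
#' before discretisation through `score_thresholds` into scores 0-3.
#'
#' @param n_regions Number of postcode-style regions.
#' @param urban_fraction Fraction of regions given an urban ONS-style
#'   category (rounded to the nearest whole region).
#' @param n_users Cohort size.
#' @param date_range Character or Date vector of length 2, inclusive.
#' @param urban_offset Latent-scale severity shift applied to users whose
#'   home region is urban.
#' @param pollen_effect Latent-scale slope per unit of min-max-scaled daily
#'   grass pollen.
#' @param reporting_probability Per-user per-day probability of submitting
#'   a report.
#' @param score_thresholds Three strictly increasing latent cut points
#'   mapping latent severity to scores 0-3.
#' @param spatial_corr Target pairwise correlation between sensor sites
#'   measuring the same variable, in `[0, 1)`.
#' @param seed Integer seed; every generator draw derives from it.
#' @param baseline_mean,baseline_sd Mean and spread of per-user latent
#'   baselines.
#' @param noise_sd Per-symptom latent noise standard deviation.
#' @param meds_intercept,meds_slope Logistic-scale coefficients giving the
#'   probability of the medication flag as a function of that day's
#'   `max_score` (slope positive so medication use rises with severity).
#' @param sites_per_variable Sensor sites generated per environmental
#'   variable.
#' @param variables Environmental variables to simulate; defaults to the
#'   full catalogue (six pollutants, three meteorological variables and
#'   twelve pollen taxa).
#'
#' @return An object of class `simulation_config` (a named list).
#' @export
#' @examples
#' cfg <- simulation_config(n_users = 20, seed = 1)
#' cfg$score_thresholds
simulation_config <- function(n_regions = 20,
                              urban_fraction = 0.5,
                              n_users = 250,
                              date_range = c("2016-03-01", "2016-09-30"),
                              urban_offset = 0.6,
                              pollen_effect = 1.2,
                              reporting_probability = 0.25,
                              score_thresholds = c(0.75, 1.75, 2.75),
                              spatial_corr = 0.7,
                              seed = 1L,
                              baseline_mean = -0.25,
                              baseline_sd = 0.75,
                              noise_sd = 1,
                              meds_intercept = -1.5,
                              meds_slope = 0.8,
                              sites_per_variable = 2,
                              variables = env_variables()) {
  date_range <- as.Date(date_range)
  if (length(date_range) != 2 || any(is.na(date_range)) ||
      date_range[2] < date_range[1]) {
    abort("date_range must be two parseable dates with start <= end")
  }
  if (length(score_thresholds) != 3 || any(diff(score_thresholds) <= 0)) {
    abort("score_thresholds must be 3 strictly increasing cut points")
  }
  if (reporting_probability < 0 || reporting_probability > 1) {
    abort("reporting_probability must lie in [0, 1]")
  }
  if (urban_fraction < 0 || urban_fraction > 1) {
    abort("urban_fraction must lie in [0, 1]")
  }
  if (spatial_corr < 0 || spatial_corr >= 1) {
    abort("spatial_corr must lie in [0, 1)")
  }
  unknown <- setdiff(variables, env_variables())
  if (length(unknown) > 0) {
    abort(paste0("unknown variable name(s): ", paste(unknown, collapse = ", ")))
  }
  structure(
    list(
      n_regions = as.integer(n_regions),
      urban_fraction = urban_fraction,
      n_users = as.integer(n_users),
      date_range = date_range,
      urban_offset = urban_offset,
      pollen_effect = pollen_effect,
      reporting_probability = reporting_probability,
      score_thresholds = score_thresholds,
      spatial_corr = spatial_corr,
      seed = as.integer(seed),
      baseline_mean = baseline_mean,
      baseline_sd = baseline_sd,
      noise_sd = noise_sd,
      meds_intercept = meds_intercept,
      meds_slope = meds_slope,
      sites_per_variable = as.integer(sites_per_variable),
      variables = variables
    ),
    class = "simulation_config"
  )
}

# ONS-style category codes: A1/B1/C1/C2 (England & Wales) and 1/2/3
# (Scotland) are urban; everything else is rural.
.urban_categories <- c("A1", "B1", "C1", "C2", "1", "2", "3")
.rural_categories <- c("D1", "D2", "E1", "E2", "F1", "F2", "4", "5", "6", "7", "8")

#' Generate a connected region map with ONS-style categories
#'
#' Builds a random connected graph over `n_regions` symbolic postcode-style
#' regions (a random spanning tree plus extra edges, giving a sparse,
#' planar-ish topology) and assigns each region an ONS-style rural-urban
#' category code. `round(urban_fraction * n_regions)` regions receive an
#' urban-class code (A1/B1/C1/C2), the rest a rural-class code.
#'
#' @param n_regions Number of regions (>= 1).
#' @param urban_fraction Fraction of regions classified urban.
#' @param seed Integer seed.
#' @param connected If `FALSE`, skip the spanning tree and only add random
#'   edges, possibly leaving isolated regions (useful for testing ring
#'   search on disconnected maps).
#' @return A list of class `region_map` with elements `regions` (tibble:
#'   `region_id`, `category`, `urban`) and `adjacency` (tibble: `region_a`,
#'   `region_b`, one row per undirected edge).
#' @export
#' @examples
#' rm <- generate_region_map(5, 0.4, seed = 1)
#' rm$regions
generate_region_map <- function(n_regions, urban_fraction, seed,
                                connected = TRUE) {
  if (n_regions < 1) abort("n_regions must be >= 1")
  if (urban_fraction < 0 || urban_fraction > 1) {
    abort("urban_fraction must lie in [0, 1]")
  }
  with_seed(seed, {
    ids <- sprintf("R%03d", seq_len(n_regions))
    n_urban <- round(urban_fraction * n_regions)
    urban <- rep(FALSE, n_regions)
    if (n_urban > 0) urban[sample.int(n_regions, n_urban)] <- TRUE
    category <- ifelse(
      urban,
      sample(c("A1", "B1", "C1", "C2"), n_regions, replace = TRUE),
      sample(c("D1", "E1", "E2", "F1"), n_regions, replace = TRUE)
    )

    edges <- NULL
    if (n_regions > 1) {
      if (connected) {
        # spanning tree: each region joins a uniformly chosen earlier one
        parent <- vapply(2:n_regions, function(i) {
          sample.int(i - 1L, 1L)
        }, integer(1))
        edges <- cbind(parent, 2:n_regions)
      }
      n_extra <- round(0.3 * n_regions)
      if (n_extra > 0) {
        a <- sample.int(n_regions, n_extra, replace = TRUE)
        b <- sample.int(n_regions, n_extra, replace = TRUE)
        keep <- a != b
        edges <- rbind(edges, cbind(a[keep], b[keep]))
      }
      if (!is.null(edges) && nrow(edges) > 0) {
        edges <- t(apply(edges, 1, sort))
        edges <- edges[!duplicated(edges), , drop = FALSE]
      }
    }
    adjacency <- if (is.null(edges) || nrow(edges) == 0) {
      tibble(region_a = character(), region_b = character())
    } else {
      tibble(region_a = ids[edges[, 1]], region_b = ids[edges[, 2]])
    }
    structure(
      list(
        regions = tibble(region_id = ids, category = category, urban = urban),
        adjacency = adjacency
      ),
      class = "region_map"
    )
  })
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf(
    "<region_map> %d regions (%d urban), %d adjacency edges\n",
    nrow(x$regions), sum(x$regions$urban), nrow(x$adjacency)
  ))
  invisible(x)
}

# Per-variable seasonal profile and noise scales. Pollutant and meteorology
# seasonality is a smooth annual cosine; each pollen taxon has a Gaussian
# bell around its flowering peak (day of year), so hazel peaks in early
# spring and grass in midsummer.
.variable_profiles <- local({
  p <- list(
    pm25 = list(kind = "cos", base = 10, amp = 4, peak = 15, sd = 2.5, diurnal = 1.5),
    pm10 = list(kind = "cos", base = 16, amp = 5, peak = 15, sd = 4, diurnal = 2),
    no2 = list(kind = "cos", base = 22, amp = 8, peak = 15, sd = 5, diurnal = 5),
    nox = list(kind = "cos", base = 38, amp = 14, peak = 15, sd = 9, diurnal = 8),
    so2 = list(kind = "cos", base = 3, amp = 1.2, peak = 15, sd = 0.8, diurnal = 0.5),
    o3 = list(kind = "cos", base = 52, amp = 14, peak = 130, sd = 8, diurnal = 8),
    rel_humidity = list(kind = "cos", base = 78, amp = 8, peak = 15, sd = 5, diurnal = 6),
    temperature = list(kind = "cos", base = 10, amp = 7, peak = 200, sd = 2.5, diurnal = 3),
    pressure = list(kind = "cos", base = 1013, amp = 4, peak = 15, sd = 5, diurnal = 0.5),
    hazel = list(kind = "bell", amp = 40, peak = 60, width = 18, sd = 12),
    alder = list(kind = "bell", amp = 30, peak = 65, width = 18, sd = 10),
    willow = list(kind = "bell", amp = 25, peak = 85, width = 18, sd = 9),
    birch = list(kind = "bell", amp = 80, peak = 105, width = 14, sd = 25),
    ash = list(kind = "bell", amp = 40, peak = 100, width = 14, sd = 13),
    elm = list(kind = "bell", amp = 20, peak = 80, width = 18, sd = 7),
    oak = list(kind = "bell", amp = 50, peak = 120, width = 14, sd = 16),
    plane = list(kind = "bell", amp = 30, peak = 115, width = 14, sd = 10),
    grass = list(kind = "bell", amp = 100, peak = 170, width = 25, sd = 30),
    nettle = list(kind = "bell", amp = 40, peak = 180, width = 28, sd = 13),
    mugwort = list(kind = "bell", amp = 15, peak = 215, width = 18, sd = 5),
    ragweed = list(kind = "bell", amp = 6, peak = 230, width = 18, sd = 2)
  )
  p
})

seasonal_mean <- function(variable, dates) {
  prof <- .variable_profiles[[variable]]
  doy <- as.integer(format(dates, "%j"))
  if (prof$kind == "cos") {
    prof$base + prof$amp * cos(2 * pi * (doy - prof$peak) / 365.25)
  } else {
    prof$amp * exp(-0.5 * ((doy - prof$peak) / prof$width)^2)
  }
}

#' Generate a sensor network and its measurement series
#'
#' Places `sites_per_variable` monitoring sites per variable in distinct
#' regions where possible and simulates their series. Each site's daily
#' signal is the variable's shared seasonal mean plus a mixture of a shared
#' daily deviation and site-specific noise, weighted so that the pairwise
#' inter-site correlation of daily values is approximately `spatial_corr`.
#' Pollutant and meteorological sites get hourly values (daily signal plus
#' a shared diurnal cycle and hourly noise); pollen sites get non-negative
#' integer daily counts.
#'
#' Pollutant sites are typed `urban_background` / `urban_traffic` /
#' `industrial` in urban regions and mostly `rural_background` in rural
#' ones; pollen and meteorology sites are `unclassified`, mirroring the
#' fact that those monitoring networks carry no location-type label.
#'
#' @param region_map A `region_map`.
#' @param variables Character vector of variable names.
#' @param sites_per_variable Sites per variable (>= 0).
#' @param spatial_corr Target pairwise inter-site correlation in `[0, 1)`.
#' @param date_range Two inclusive dates.
#' @param seed Integer seed.
#' @return A list of class `sensor_network`: `sites` (tibble: `site_id`,
#'   `variable`, `region_id`, `site_type`) and `measurements` (tibble:
#'   `site_id`, `timestamp`, `value`; hourly POSIXct timestamps for
#'   pollutants/meteorology, midnight timestamps for daily pollen counts).
#' @export
generate_sensor_network <- function(region_map, variables, sites_per_variable,
                                    spatial_corr, date_range, seed) {
  unknown <- setdiff(variables, env_variables())
  if (length(unknown) > 0) {
    abort(paste0("unknown variable name(s): ", paste(unknown, collapse = ", ")))
  }
  if (sites_per_variable < 0) abort("sites_per_variable must be >= 0")
  if (spatial_corr < 0 || spatial_corr >= 1) {
    abort("spatial_corr must lie in [0, 1)")
  }
  date_range <- as.Date(date_range)
  dates <- seq(date_range[1], date_range[2], by = "day")
  regions <- region_map$regions

  with_seed(seed, {
    sites_list <- list()
    meas_list <- list()
    for (v in variables) {
      k <- sites_per_variable
      if (k == 0) next
      # distinct regions while they last, then reuse
      pool <- sample(regions$region_id)
      site_regions <- pool[((seq_len(k) - 1L) %% length(pool)) + 1L]
      site_ids <- sprintf("%s_s%02d", v, seq_len(k))
      if (v %in% .pollutant_vars) {
        urban_here <- regions$urban[match(site_regions, regions$region_id)]
        site_type <- ifelse(
          urban_here,
          sample(c("urban_background", "urban_traffic", "industrial"),
                 k, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
          sample(c("rural_background", "industrial"),
                 k, replace = TRUE, prob = c(0.9, 0.1))
        )
      } else {
        site_type <- rep("unclassified", k)
      }
      sites_list[[v]] <- tibble(
        site_id = site_ids, variable = v,
        region_id = site_regions, site_type = site_type
      )

      prof <- .variable_profiles[[v]]
      mu <- seasonal_mean(v, dates)
      n_days <- length(dates)
      shared <- rnorm(n_days)
      w_shared <- sqrt(spatial_corr)
      w_site <- sqrt(1 - spatial_corr)
      for (i in seq_len(k)) {
        daily_dev <- prof$sd * (w_shared * shared + w_site * rnorm(n_days))
        daily_val <- mu + daily_dev
        if (is_pollen_var(v)) {
          value <- round(pmax(0, daily_val))
          meas_list[[site_ids[i]]] <- tibble(
            site_id = site_ids[i],
            timestamp = as.POSIXct(dates, tz = "UTC"),
            value = value
          )
        } else {
          hours <- 0:23
          diurnal <- prof$diurnal * sin(2 * pi * (hours - 9) / 24)
          ts <- rep(as.POSIXct(dates, tz = "UTC"), each = 24) +
            rep(hours, times = n_days) * 3600
          value <- rep(daily_val, each = 24) + rep(diurnal, times = n_days) +
            rnorm(n_days * 24, sd = 0.1 * prof$sd)
          meas_list[[site_ids[i]]] <- tibble(
            site_id = site_ids[i], timestamp = ts, value = value
          )
        }
      }
    }
    structure(
      list(
        sites = if (length(sites_list)) bind_rows(sites_list) else
          tibble(site_id = character(), variable = character(),
                 region_id = character(), site_type = character()),
        measurements = if (length(meas_list)) bind_rows(meas_list) else
          tibble(site_id = character(),
                 timestamp = as.POSIXct(character(), tz = "UTC"),
                 value = numeric())
      ),
      class = "sensor_network"
    )
  })
}

#' Generate a user cohort anchored to home regions
#'
#' Each user receives a year of birth, a gender and a home region drawn
#' uniformly from the map; all of a user's reports come from that region,
#' reflecting the observation that participants report from either urban or
#' rural areas rather than both.
#'
#' @param region_map A `region_map`.
#' @param n_users Cohort size (>= 0).
#' @param seed Integer seed.
#' @return Tibble: `user_id`, `year_of_birth`, `gender`, `home_region`.
#' @export
generate_cohort <- function(region_map, n_users, seed) {
  if (n_users < 0) abort("n_users must be >= 0")
  if (n_users > 0 && nrow(region_map$regions) == 0) {
    abort("cannot place users on an empty region map")
  }
  with_seed(seed, {
    tibble(
      user_id = sprintf("U%04d", seq_len(n_users)),
      year_of_birth = if (n_users) sample(1945:2005, n_users, replace = TRUE) else integer(),
      gender = if (n_users) sample(c("F", "M"), n_users, replace = TRUE) else character(),
      home_region = if (n_users) {
        sample(region_map$regions$region_id, n_users, replace = TRUE)
      } else character()
    )
  })
}

#' Generate symptom reports from a cohort and a grass pollen series
#'
#' For every user-day in the configured date range a report is emitted with
#' probability `reporting_probability`. Latent severity for that user-day is
#' `baseline(user) + pollen_effect * grass_scaled(day) +
#' urban_offset * is_urban(home region)`; each of nose/eyes/breathing adds
#' independent Gaussian noise and is discretised through
#' `score_thresholds` into 0-3. The medication flag is Bernoulli with
#' log-odds increasing in the day's `max_score` (the flag itself is stored;
#' `max_score` is recomputed downstream during preprocessing).
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param grass_series Tibble with columns `date`, `value`: the daily grass
#'   pollen signal used as the symptom driver. Must cover the configured
#'   date range.
#' @param config A [simulation_config()].
#' @param region_map The `region_map` the cohort was drawn from (used to
#'   look up which home regions are urban).
#' @return Tibble of reports: `user_id`, `timestamp`, `region_id`, `nose`,
#'   `eyes`, `breathing`, `taken_meds`.
#' @export
generate_reports <- function(cohort, grass_series, config, region_map) {
  dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  grass_series <- as_tibble(grass_series)
  assert_columns(grass_series, c("date", "value"), "grass_series")
  missing_dates <- setdiff(as.character(dates), as.character(grass_series$date))
  if (length(missing_dates) > 0) {
    abort(sprintf(
      "grass_series does not cover %d requested date(s), e.g. %s",
      length(missing_dates), missing_dates[1]
    ))
  }
  if (nrow(cohort) == 0) {
    return(tibble(
      user_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
      region_id = character(), nose = integer(), eyes = integer(),
      breathing = integer(), taken_meds = integer()
    ))
  }
  g <- grass_series$value[match(as.character(dates), as.character(grass_series$date))]
  rng <- range(g)
  g_scaled <- if (diff(rng) > 0) (g - rng[1]) / diff(rng) else rep(0, length(g))

  urban_regions <- region_map$regions$region_id[region_map$regions$urban]

  with_seed(config$seed + 1L, {
    n_users <- nrow(cohort)
    n_days <- length(dates)
    baseline <- rnorm(n_users, config$baseline_mean, config$baseline_sd)
    is_urban <- cohort$home_region %in% urban_regions

    # user-major grid so per-user draws stay contiguous
    u_idx <- rep(seq_len(n_users), each = n_days)
    d_idx <- rep(seq_len(n_days), times = n_users)
    reported <- runif(n_users * n_days) < config$reporting_probability
    u_idx <- u_idx[reported]
    d_idx <- d_idx[reported]
    n <- length(u_idx)
    latent_mean <- baseline[u_idx] +
      config$pollen_effect * g_scaled[d_idx] +
      config$urban_offset * is_urban[u_idx]
    score <- function() {
      latent <- latent_mean + rnorm(n, sd = config$noise_sd)
      findInterval(latent, config$score_thresholds)
    }
    nose <- score()
    eyes <- score()
    breathing <- score()
    mx <- pmax(nose, eyes, breathing)
    p_meds <- stats::plogis(config$meds_intercept + config$meds_slope * mx)
    taken_meds <- rbinom(n, 1, p_meds)
    hour <- sample(7:22, n, replace = TRUE)
    minute <- sample(0:59, n, replace = TRUE)
    tibble(
      user_id = cohort$user_id[u_idx],
      timestamp = as.POSIXct(dates[d_idx], tz = "UTC") +
        hour * 3600 + minute * 60,
      region_id = cohort$home_region[u_idx],
      nose = nose, eyes = eyes, breathing = breathing,
      taken_meds = taken_meds
    ) %>%
      arrange(.data$user_id, .data$timestamp)
  })
}

#' Run the full synthetic study
#'
#' Convenience wrapper: region map, sensor network, cohort and reports from
#' one configuration. The symptom driver is the UK-mean daily grass pollen
#' signal across the simulated grass sites (or, when no grass sites are
#' simulated, the noise-free seasonal grass curve).
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_study`: `config`, `region_map`,
#'   `network`, `cohort`, `reports`, `grass_series`.
#' @export
#' @examples
#' study <- simulate_study(simulation_config(n_users = 30, n_regions = 6,
#'                                           sites_per_variable = 1,
#'                                           variables = "grass", seed = 42))
#' nrow(study$reports)
simulate_study <- function(config = simulation_config()) {
  region_map <- generate_region_map(
    config$n_regions, config$urban_fraction, config$seed
  )
  network <- generate_sensor_network(
    region_map, config$variables, config$sites_per_variable,
    config$spatial_corr, config$date_range, config$seed + 2L
  )
  cohort <- generate_cohort(region_map, config$n_users, config$seed + 3L)
  dates <- seq(config$date_range[1], config$date_range[2], by = "day")
  grass_sites <- network$sites$site_id[network$sites$variable == "grass"]
  grass_series <- if (length(grass_sites) > 0) {
    network$measurements %>%
      filter(.data$site_id %in% grass_sites) %>%
      mutate(date = as.Date(.data$timestamp)) %>%
      group_by(.data$date) %>%
      summarise(value = mean(.data$value), .groups = "drop")
  } else {
    tibble(date = dates, value = seasonal_mean("grass", dates))
  }
  reports <- generate_reports(cohort, grass_series, config, region_map)
  structure(
    list(
      config = config, region_map = region_map, network = network,
      cohort = cohort, reports = reports, grass_series = grass_series
    ),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d regions, %d users, %d reports, %d sensor sites\n",
    nrow(x$region_map$regions), nrow(x$cohort), nrow(x$reports),
    nrow(x$network$sites)
  ))
  invisible(x)
}

#' Expected max-score under the latent threshold model
#'
#' Closed-form expectation of `max_score` for a user-day whose latent mean
#' is known: with three conditionally independent symptoms,
#' `P(max >= k) = 1 - pnorm((t_k - mu) / noise_sd)^3` and the expectation is
#' the sum over k of those tail probabilities.
#'
#' @param latent_mean Latent severity mean (vectorised).
#' @param thresholds The three score cut points.
#' @param noise_sd Per-symptom latent noise SD.
#' @return Expected `max_score` in `[0, 3]`.
#' @export
expected_max_score <- function(latent_mean, thresholds, noise_sd) {
  out <- numeric(length(latent_mean))
  for (t_k in thresholds) {
    out <- out + 1 - pnorm((t_k - latent_mean) / noise_sd)^3
  }
  out
}

#' Solve for the urban offset giving a target mean max-score gap
#'
#' Finds the latent-scale urban offset under which the population
#' urban-minus-rural gap in expected daily-mean `max_score` equals
#' `target_gap`, integrating the threshold model over the user baseline
#' distribution (Gauss-Legendre style grid) and averaging over the scaled
#' grass pollen values of the configured date range.
#'
#' @param target_gap Desired gap in mean `max_score` units.
#' @param config A [simulation_config()]; its `urban_offset` is ignored.
#' @param grass_scaled Optional vector of scaled daily pollen values in
#'   `[0, 1]`; defaults to the scaled noise-free seasonal grass curve over
#'   the configured dates.
#' @return The urban offset (latent units).
#' @export
calibrate_urban_offset <- function(target_gap, config, grass_scaled = NULL) {
  if (is.null(grass_scaled)) {
    dates <- seq(config$date_range[1], config$date_range[2], by = "day")
    g <- seasonal_mean("grass", dates)
    grass_scaled <- (g - min(g)) / (max(g) - min(g))
  }
  # integrate the baseline N(mean, sd) on a fine fixed grid
  z <- seq(-4.5, 4.5, length.out = 181)
  wz <- stats::dnorm(z)
  wz <- wz / sum(wz)
  b <- config$baseline_mean + config$baseline_sd * z
  pop_mean <- function(delta) {
    # mean over days of mean over baselines
    m <- outer(b + delta, config$pollen_effect * grass_scaled, "+")
    sum(wz * rowMeans(expected_max_score(
      as.vector(m), config$score_thresholds, config$noise_sd
    ) |> matrix(nrow = length(b))))
  }
  gap <- function(delta) pop_mean(delta) - pop_mean(0)
  uniroot(function(d) gap(d) - target_gap, c(0, 6), tol = 1e-8)$root
}

#' Write a synthetic study to CSV files
#'
#' Writes `reports.csv`, `sites.csv`, `measurements.csv`, `regions.csv`
#' and `adjacency.csv` in the long plain-text formats the rest of the
#' pipeline reads.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_study_csv <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c(
    "reports.csv", "sites.csv", "measurements.csv",
    "regions.csv", "adjacency.csv"
  ))
  reports <- study$reports %>%
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ"))
  write.csv(reports, paths[1], row.names = FALSE)
  write.csv(study$network$sites, paths[2], row.names = FALSE)
  meas <- study$network$measurements %>%
    mutate(timestamp = format(.data$timestamp, "%Y-%m-%dT%H:%M:%SZ"))
  write.csv(meas, paths[3], row.names = FALSE)
  write.csv(study$region_map$regions[, c("region_id", "category")],
            paths[4], row.names = FALSE)
  write.csv(study$region_map$adjacency, paths[5], row.names = FALSE)
  invisible(paths)
}
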