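#' Daily mean of a measure per land-use group
#'
#' One value per (group, calendar day): the mean of that day's reports in
#' the group. Days on which a group has no reports are simply absent from
#' its series.
#'
#' @param reports Preprocessed reports carrying `land_use`, `date` and the
#'   measure column.
#' @param measure One of [symptom_measures()].
#' @return Tibble: `land_use`, `date`, `value`, `n_reports`.
#' @export
daily_group_means <- function(reports, measure) {
  if (!measure %in% .symptom_measures) {
    abort(sprintf("unknown measure '%s'", measure))
  }
  assert_columns(reports, c("land_use", "date", measure), "reports")
  reports %>%
    group_by(.data$land_use, .data$date) %>%
    summarise(
      value = mean(.data[[measure]]),
      n_reports = n(),
      .groups = "drop"
    )
}

#' Cohen's d effect size
#'
#' Standardised mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled standard deviation
#' `sqrt(((n_x - 1) s_x^2 + (n_y - 1) s_y^2) / (n_x + n_y - 2))`.
#' Conventionally, magnitudes of about 0.2 are small, 0.5 medium and 0.8
#' large.
#'
#' @param x,y Numeric samples of size >= 2.
#' @return The effect size; positive when `mean(x) > mean(y)`.
#' @export
#' @examples
#' cohens_d(c(1, 2, 3), c(2, 3, 4))
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  nx <- length(x)
  ny <- length(y)
  if (nx < 2 || ny < 2) abort("cohens_d needs at least 2 values per sample")
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) abort("cohens_d undefined: pooled standard deviation is zero")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Two-sample Kolmogorov-Smirnov distance
#'
#' The supremum over thresholds of the absolute difference between the two
#' empirical distribution functions, in `[0, 1]`, with a two-tailed
#' p-value from the standard asymptotic two-sample distribution.
#'
#' @param x,y Non-empty numeric samples.
#' @return List with elements `U1` (the statistic) and `p_two_tailed`.
#' @export
#' @examples
#' ks_statistic(c(1, 2), c(2, 3))$U1
ks_statistic <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("ks_statistic needs non-empty samples")
  }
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(U1 = unname(kt$statistic), p_two_tailed = kt$p.value)
}

#' Urban vs rural severity comparison table
#'
#' For each year stratum (plus an all-years row set) and each measure:
#' computes the daily mean series per land-use group, then reports the
#' group means of those daily means, their difference (urban minus rural),
#' Cohen's d and the two-sample Kolmogorov-Smirnov distance with its
#' p-value, all on the daily-mean samples. When `use_daily_means = FALSE`
#' the statistics are computed on raw report scores instead.
#'
#' A stratum in which either group has no reports yields a row of missing
#' statistics (with a message) rather than an error.
#'
#' @param reports Preprocessed reports.
#' @param years `"all"`, a vector of years, or both (e.g.
#'   `c("all", 2016:2020)`); `"all"` pools every year.
#' @param measures Measures to tabulate.
#' @param use_daily_means Compare daily-mean distributions (default) or
#'   raw report scores.
#' @return Tibble: `year`, `measure`, `urban_mean`, `rural_mean`,
#'   `diff_mean`, `cohen_d`, `ks_U1`, `p_two_tailed`, `n_urban`,
#'   `n_rural`.
#' @export
compare_groups <- function(reports, years = "all",
                           measures = symptom_measures(),
                           use_daily_means = TRUE) {
  assert_columns(reports, c("land_use", "date"), "reports")
  reports$year <- lubridate::year(reports$date)
  rows <- list()
  for (yr in years) {
    sub <- if (identical(yr, "all")) reports else
      filter(reports, .data$year == as.integer(yr))
    for (m in measures) {
      if (use_daily_means) {
        dm <- daily_group_means(sub, m)
        xu <- dm$value[dm$land_use == "urban"]
        xr <- dm$value[dm$land_use == "rural"]
      } else {
        xu <- sub[[m]][sub$land_use == "urban"]
        xr <- sub[[m]][sub$land_use == "rural"]
      }
      row <- tibble(
        year = as.character(yr), measure = m,
        urban_mean = NA_real_, rural_mean = NA_real_, diff_mean = NA_real_,
        cohen_d = NA_real_, ks_U1 = NA_real_, p_two_tailed = NA_real_,
        n_urban = length(xu), n_rural = length(xr)
      )
      if (length(xu) == 0 || length(xr) == 0) {
        inform(sprintf(
          "stratum year=%s measure=%s: a group has no data; statistics missing",
          yr, m
        ))
      } else {
        row$urban_mean <- mean(xu)
        row$rural_mean <- mean(xr)
        row$diff_mean <- row$urban_mean - row$rural_mean
        if (length(xu) >= 2 && length(xr) >= 2) {
          row$cohen_d <- tryCatch(cohens_d(xu, xr), error = function(e) NA_real_)
        }
        ks <- ks_statistic(xu, xr)
        row$ks_U1 <- ks$U1
        row$p_two_tailed <- ks$p_two_tailed
      }
      rows[[length(rows) + 1]] <- row
    }
  }
  bind_rows(rows)
}

#' Subsample bootstrap of group means
#'
#' Draws `n_samples` random subsamples, each containing
#' `floor(sample_fraction * N)` of a group's reports without replacement,
#' and records the subsample mean of the measure — the re-sampling check
#' used to verify that an urban-rural difference is not driven by a few
#' prolific reporters. Histograms of the two groups' sample means can be
#' compared directly.
#'
#' @param reports Preprocessed reports.
#' @param measure Measure to average.
#' @param sample_fraction Fraction of each group's reports per subsample
#'   (default 0.2).
#' @param n_samples Number of subsamples (default 2000).
#' @param seed Integer seed.
#' @param replace Draw with replacement instead (classical bootstrap).
#' @return Tibble of class `bootstrap_result`: `measure`, `land_use`,
#'   `sample`, `mean_value`, with attributes `sample_fraction`,
#'   `n_samples`, `seed`.
#' @export
bootstrap_resample <- function(reports, measure, sample_fraction = 0.2,
                               n_samples = 2000, seed = 1L,
                               replace = FALSE) {
  if (sample_fraction <= 0 || sample_fraction > 1) {
    abort("sample_fraction must lie in (0, 1]")
  }
  assert_columns(reports, c("land_use", measure), "reports")
  with_seed(seed, {
    out <- list()
    for (g in sort(unique(reports$land_use))) {
      vals <- reports[[measure]][reports$land_use == g]
      size <- floor(sample_fraction * length(vals))
      if (size == 0) abort(sprintf("subsample size 0 for group '%s'", g))
      means <- vapply(seq_len(n_samples), function(i) {
        mean(vals[sample.int(length(vals), size, replace = replace)])
      }, numeric(1))
      out[[g]] <- tibble(
        measure = measure, land_use = g,
        sample = seq_len(n_samples), mean_value = means
      )
    }
    res <- bind_rows(out)
    attr(res, "sample_fraction") <- sample_fraction
    attr(res, "n_samples") <- n_samples
    attr(res, "seed") <- seed
    class(res) <- c("bootstrap_result", class(res))
    res
  })
}
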