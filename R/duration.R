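#' Chain policy for symptom-duration analysis
#'
#' A chain is a maximal run of calendar days whose reports score at or
#' above `min_score`, tolerating up to `allowed_gap` consecutive days with
#' no report at all. A reported day scoring below `min_score` always
#' breaks the chain, whatever the gap allowance.
#'
#' @param min_score Minimum score for a day to qualify (1-3).
#' @param allowed_gap Consecutive no-report days a chain may bridge (>= 0).
#' @param measure Which measure's scores define the chain.
#' @return An object of class `chain_policy`.
#' @export
chain_policy <- function(min_score = 1, allowed_gap = 0,
                         measure = "max_score") {
  if (!min_score %in% 1:3) abort("min_score must be 1, 2 or 3")
  if (allowed_gap < 0) abort("allowed_gap must be >= 0")
  if (!measure %in% .symptom_measures) {
    abort(sprintf("unknown measure '%s'", measure))
  }
  structure(
    list(min_score = as.integer(min_score),
         allowed_gap = as.integer(allowed_gap), measure = measure),
    class = "chain_policy"
  )
}

#' Extract symptom chains from one user's daily scores
#'
#' Scans the user's calendar in order. A day qualifies when a report
#' exists with score at or above the policy's `min_score`. Consecutive
#' qualifying days chain together; a chain also continues across up to
#' `allowed_gap` consecutive days with no report, but any reported
#' sub-threshold day breaks it. Chain duration is the calendar span from
#' first to last qualifying day inclusive, so a bridged no-report day
#' counts toward the duration (set `duration = "report_days"` to count
#' only the qualifying days themselves).
#'
#' @param daily_scores Tibble with columns `date` and `score`, at most one
#'   row per day (the post-filter guarantee).
#' @param policy A [chain_policy()] (its `measure` field is not consulted
#'   here; `score` is whatever the caller extracted).
#' @param duration `"span"` (calendar span, default) or `"report_days"`.
#' @return Integer vector of chain durations in days (possibly empty).
#' @export
#' @examples
#' d <- tibble::tibble(date = as.Date("2020-06-01") + c(0, 2), score = c(2, 1))
#' extract_chains(d, chain_policy(min_score = 1, allowed_gap = 1))
extract_chains <- function(daily_scores, policy = chain_policy(),
                           duration = c("span", "report_days")) {
  duration <- match.arg(duration)
  assert_columns(daily_scores, c("date", "score"), "daily_scores")
  if (anyDuplicated(daily_scores$date)) {
    abort("duplicate day in daily_scores: filter to one report per day first")
  }
  d <- arrange(as_tibble(daily_scores), .data$date)
  qual <- d$score >= policy$min_score
  q_dates <- as.integer(d$date[qual])
  r_dates <- as.integer(d$date)  # all reported days
  if (length(q_dates) == 0) return(integer())

  durations <- integer()
  start <- q_dates[1]
  prev <- q_dates[1]
  n_days <- 1L
  flush <- function() {
    if (duration == "span") prev - start + 1L else n_days
  }
  if (length(q_dates) > 1) {
    for (i in 2:length(q_dates)) {
      cur <- q_dates[i]
      has_report_between <- cur - prev > 1L && any(r_dates > prev & r_dates < cur)
      gap_len <- cur - prev - 1L
      if (has_report_between || gap_len > policy$allowed_gap) {
        durations <- c(durations, flush())
        start <- cur
        n_days <- 1L
      } else {
        n_days <- n_days + 1L
      }
      prev <- cur
    }
  }
  durations <- c(durations, flush())
  durations
}

#' Urban vs rural symptom-duration summary
#'
#' Per user: the mean duration over that user's chains (users with no
#' chain under the policy are excluded). Per land-use group: the median of
#' those user means. The difference is urban minus rural.
#'
#' @param reports Preprocessed reports (with `land_use`, `date` and the
#'   policy's measure column).
#' @param policy A [chain_policy()].
#' @param duration Passed to [extract_chains()].
#' @return One-row tibble: `min_score`, `allowed_gap`, `measure`,
#'   `rural_median`, `urban_median`, `diff`, `n_rural_users`,
#'   `n_urban_users`. A group with no chains yields a missing median (with
#'   a message).
#' @export
duration_summary <- function(reports, policy = chain_policy(),
                             duration = c("span", "report_days")) {
  duration <- match.arg(duration)
  assert_columns(reports, c("user_id", "land_use", "date", policy$measure),
                 "reports")
  user_means <- reports %>%
    select(user_id = "user_id", land_use = "land_use", date = "date",
           score = all_of(policy$measure)) %>%
    group_by(.data$user_id, .data$land_use) %>%
    summarise(
      mean_duration = {
        ch <- extract_chains(dplyr::pick("date", "score"), policy, duration)
        if (length(ch) == 0) NA_real_ else mean(ch)
      },
      .groups = "drop"
    ) %>%
    filter(!is.na(.data$mean_duration))

  med <- function(g) {
    v <- user_means$mean_duration[user_means$land_use == g]
    if (length(v) == 0) {
      inform(sprintf("no chains in group '%s' under this policy", g))
      NA_real_
    } else median(v)
  }
  rural_median <- med("rural")
  urban_median <- med("urban")
  tibble(
    min_score = policy$min_score, allowed_gap = policy$allowed_gap,
    measure = policy$measure,
    rural_median = rural_median, urban_median = urban_median,
    diff = urban_median - rural_median,
    n_rural_users = sum(user_means$land_use == "rural"),
    n_urban_users = sum(user_means$land_use == "urban")
  )
}

#' Duration summaries over a policy grid
#'
#' Evaluates [duration_summary()] over the cross product of minimum
#' scores, allowed gaps and measures, producing a duration comparison
#' table.
#'
#' @param reports Preprocessed reports.
#' @param min_scores,gaps,measures Grid dimensions.
#' @param duration Passed to [extract_chains()].
#' @return Tibble with one row per policy combination.
#' @export
duration_table <- function(reports, min_scores = 1:3, gaps = 0:1,
                           measures = c("nose", "eyes", "breathing",
                                        "taken_meds", "max_score"),
                           duration = c("span", "report_days")) {
  duration <- match.arg(duration)
  rows <- list()
  for (ms in min_scores) {
    for (g in gaps) {
      for (m in measures) {
        rows[[length(rows) + 1]] <- duration_summary(
          reports, chain_policy(ms, g, m), duration
        )
      }
    }
  }
  bind_rows(rows)
}
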