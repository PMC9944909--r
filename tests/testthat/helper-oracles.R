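# Independent oracles used to cross-check the package's statistics and
# algorithms on small cases.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force two-sample KS distance: evaluate both ECDFs on the pooled
# support and take the largest absolute difference.
ks_bruteforce <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  max(vapply(grid, function(t) {
    abs(mean(x <= t) - mean(y <= t))
  }, numeric(1)))
}

# Cohen's d via the pooled-variance t statistic: d = t * sqrt(1/nx + 1/ny).
cohens_d_via_t <- function(x, y) {
  tt <- t.test(x, y, var.equal = TRUE)
  unname(tt$statistic) * sqrt(1 / length(x) + 1 / length(y))
}

# All multisets of {0..3} of a given size, as a list of sorted vectors.
score_multisets <- function(size) {
  grid <- do.call(expand.grid, rep(list(0:3), size))
  keys <- apply(grid, 1, function(r) paste(sort(r), collapse = ","))
  lapply(unique(keys), function(k) as.numeric(strsplit(k, ",")[[1]]))
}

# Day-by-day state machine for symptom chains, used as the segmentation
# oracle. `scores` is a vector over consecutive calendar days with NA for
# days without any report.
chains_statemachine <- function(scores, min_score, allowed_gap,
                                duration = "span") {
  durations <- integer()
  open <- FALSE
  first <- last <- n_qual <- 0L
  missing_run <- 0L
  close_chain <- function() {
    if (open) {
      durations[[length(durations) + 1L]] <<-
        if (duration == "span") last - first + 1L else n_qual
    }
    open <<- FALSE
  }
  for (day in seq_along(scores)) {
    s <- scores[day]
    if (is.na(s)) {
      missing_run <- missing_run + 1L
      if (open && missing_run > allowed_gap) close_chain()
    } else if (s >= min_score) {
      if (!open) {
        open <- TRUE
        first <- day
        n_qual <- 0L
      }
      last <- day
      n_qual <- n_qual + 1L
      missing_run <- 0L
    } else {
      close_chain()
      missing_run <- 0L
    }
  }
  close_chain()
  durations
}

# Wrap a score-by-day vector (NA = no report) as the daily_scores tibble
# extract_chains() expects.
scores_to_daily <- function(scores, origin = as.Date("2019-06-01")) {
  keep <- !is.na(scores)
  tibble::tibble(date = origin + which(keep) - 1L, score = scores[keep])
}

# Shortest-path distances via igraph, the independent oracle for the
# concentric ring search.
igraph_distances <- function(adjacency, regions) {
  g <- igraph::graph_from_data_frame(
    adjacency, directed = FALSE,
    vertices = data.frame(name = regions)
  )
  igraph::distances(g)[regions, regions, drop = FALSE]
}

# A tiny deterministic report table used across preprocessing tests.
toy_reports <- function() {
  tibble::tibble(
    user_id = c(rep("u1", 13), rep("u2", 3), "u1"),
    timestamp = c(
      sprintf("2018-07-%02dT09:00:00Z", 1:12),   # u1: 12 July days
      "2018-07-01T17:00:00Z",                    # u1: later same-day report
      sprintf("2018-07-%02dT10:00:00Z", 20:22),  # u2: only 3 days
      "2018-02-15T10:00:00Z"                     # u1: outside month window
    ),
    region_id = "R1",
    nose = 1L, eyes = 0L, breathing = 0L, taken_meds = 0L
  )
}
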