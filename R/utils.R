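# Catalogue of environmental variables handled by the pipeline.
# Pollutants and meteorology are measured hourly and aggregated to daily
# mean/max; pollen taxa arrive as daily grain counts.

.pollutant_vars <- c("pm25", "pm10", "no2", "nox", "so2", "o3")
.met_vars <- c("rel_humidity", "temperature", "pressure")
.pollen_vars <- c(
  "hazel", "alder", "willow", "birch", "ash", "elm",
  "oak", "plane", "grass", "nettle", "mugwort", "ragweed"
)

#' Environmental variable names known to the pipeline
#'
#' @param type One of `"all"`, `"pollutant"`, `"met"`, `"pollen"`.
#' @return Character vector of variable names.
#' @export
#' @examples
#' env_variables("pollen")
env_variables <- function(type = c("all", "pollutant", "met", "pollen")) {
  type <- match.arg(type)
  switch(type,
    all = c(.pollutant_vars, .met_vars, .pollen_vars),
    pollutant = .pollutant_vars,
    met = .met_vars,
    pollen = .pollen_vars
  )
}

is_pollen_var <- function(x) x %in% .pollen_vars

is_hourly_var <- function(x) x %in% c(.pollutant_vars, .met_vars)

# Symptom measures reported per submission plus derived ones.
.symptom_measures <- c("nose", "eyes", "breathing", "taken_meds", "max_score")

#' Symptom measures used throughout the analysis
#'
#' The three reported ordinal scores, the daily medication flag, and the
#' derived `max_score` (maximum of the three scores).
#' @return Character vector.
#' @export
symptom_measures <- function() .symptom_measures

# Run code with a temporary RNG seed, leaving the caller's RNG state alone.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing_cols, collapse = ", ")
    ))
  }
  invisible(df)
}
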