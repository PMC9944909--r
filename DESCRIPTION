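Package: pollendiary
Title: Urban-Rural Analysis of Experience-Sampled Hay Fever Symptom Diaries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking experience-sampled hay fever symptom reports
    to land use and environmental sensor data. Provides a synthetic-data
    generator emulating sporadic mobile-app symptom diaries with
    pollen-driven seasonality and an urban severity offset; report-level
    filters (month window, latest report per user-day, minimum reporting
    days); concentric-regions gap-filling that estimates per-region daily
    environmental values from successive adjacency rings of a region graph;
    urban-versus-rural severity comparison with Cohen's d, two-sample
    Kolmogorov-Smirnov distance and subsample bootstrap; a gap-tolerant
    symptom-chain duration statistic; and Pearson correlation of symptom
    series with pollutant, meteorological and pollen series at daily,
    weekly, monthly and yearly aggregation, UK-wide or per region.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    rlang,
    lubridate,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    ggplot2,
    jsonlite,
    knitr
Config/testthat/edition: 3
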