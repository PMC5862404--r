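Package: avichange
Title: Projected Climate-Driven Change in Bird Communities of Protected Areas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Post-processes species-distribution-model climate suitability
    projections for bird species across a protected-area system. Fits a
    pooled ordinary-least-squares trend to ensemble suitability values per
    species and park, classifies each species-park combination as improving,
    stable, worsening, potential colonization, or potential extirpation
    against species-specific suitability thresholds, aggregates the
    classifications into park-level community-change metrics (binary
    Bray-Curtis turnover, colonization and extirpation proportions, richness
    ratios), assigns parks to five relative trend groups from cohort
    quantiles, and runs the comparative statistics layer (seasonal contrasts
    with a normality gate, latitudinal regressions, regional analysis of
    variance). Includes a synthetic-scenario generator with planted trend
    classes so the full pipeline is testable without model outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    car,
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
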