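# End-to-end orchestration: read and validate inputs, classify, summarize,
# group, test, and write a reproducible artifact set with a run manifest.

#' Configure a pipeline run
#'
#' @param suitability,thresholds,parks Paths to the three input CSVs.
#' @param out_dir Output directory (created if absent).
#' @param season `"summer"`, `"winter"`, or `"both"` (default).
#' @param rcp `"RCP2.6"`, `"RCP8.5"`, or `"both"` (default).
#' @param alpha Slope-test significance level.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed feeds any resampling extensions).
#' @param typology_season,typology_rcp Stratum the park typology is computed
#'   on (defaults summer, RCP8.5).
#' @param incomplete Incomplete-ensemble policy passed to
#'   [read_suitability_table()].
#' @return A `run_config` list.
#' @export
run_config <- function(suitability, thresholds, parks, out_dir,
                       season = "both", rcp = "both", alpha = 0.05,
                       seed = 1L, typology_season = "summer",
                       typology_rcp = "RCP8.5", incomplete = "error") {
  for (p in c(suitability, thresholds, parks)) {
    if (!file.exists(p)) abort("input file not found: %s", p)
  }
  season <- if (identical(season, "both")) season_levels else normalize_season(season)
  rcp <- if (identical(rcp, "both")) rcp_levels else normalize_rcp(rcp)
  structure(list(suitability = suitability, thresholds = thresholds,
                 parks = parks, out_dir = out_dir, season = season,
                 rcp = rcp, alpha = alpha, seed = as.integer(seed),
                 typology_season = normalize_season(typology_season),
                 typology_rcp = normalize_rcp(typology_rcp),
                 incomplete = incomplete),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort("stage %s: %s", name, conditionMessage(e))
  })
}

# Comparative tests the pipeline attempts; any whose preconditions fail on
# the given cohort are recorded as skipped rather than aborting the run.
pipeline_stats <- function(park_summary, parks, seasons, rcps, alpha) {
  metrics <- c("bray_curtis", "prop_colonization", "prop_extirpation")
  results <- list()
  add <- function(res, ...) {
    ctx <- list(...)
    results[[length(results) + 1]] <<- c(ctx, as.list(res))
  }
  try_test <- function(label, ctx, expr) {
    tryCatch(add(expr, test = label, context = ctx),
             error = function(e) {
               results[[length(results) + 1]] <<-
                 list(test = label, context = ctx, skipped = TRUE,
                      reason = conditionMessage(e))
             })
  }
  for (r in rcps) {
    if (all(season_levels %in% seasons)) {
      for (m in metrics) {
        su <- park_summary[park_summary$season == "summer" &
                             park_summary$rcp == r, ][[m]]
        wi <- park_summary[park_summary$season == "winter" &
                             park_summary$rcp == r, ][[m]]
        try_test("seasonal_comparison", paste(m, r),
                 compare_seasons(su, wi, alpha = alpha))
      }
    }
    for (s in seasons) {
      for (m in metrics) {
        try_test("latitude_regression", paste(m, s, r),
                 latitude_regression(park_summary, parks, m, s, r))
        try_test("regional_anova", paste(m, s, r),
                 regional_anova(park_summary, parks, m, s, r))
      }
      for (reg in intersect(unique(parks$region), region_levels)) {
        try_test("region_vs_overall", paste("bray_curtis", s, r, reg),
                 region_vs_overall(park_summary, parks, "bray_curtis",
                                   reg, s, r, alpha = alpha))
      }
    }
  }
  results
}

#' Run the full pipeline
#'
#' Executes classify -> summarize -> groups -> stats on the configured
#' inputs and writes `classifications.csv`, `park_summary.csv`,
#' `systemwide_summary.csv`, `trend_groups.csv`, `stats_report.json`, and
#' `manifest.json` (input hashes, settings, software version, output
#' hashes). Identical inputs and config give byte-identical outputs. Any
#' stage error aborts with a stage-named message.
#'
#' @param config A [run_config()].
#' @return Invisible list with the computed tables and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) abort("config must come from run_config()")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  suit <- stage("read_suitability",
                read_suitability_table(config$suitability,
                                       incomplete = config$incomplete))
  thr <- stage("read_thresholds", read_thresholds(config$thresholds))
  parks <- stage("read_parks", read_parks(config$parks))

  suit <- suit[suit$season %in% config$season & suit$rcp %in% config$rcp, ]
  if (nrow(suit) == 0) abort("stage filter: no records left for the requested season/rcp")

  settings <- classifier_settings(alpha = config$alpha)
  cls <- stage("classify", classify_all(suit, thr, settings))
  park_summary <- stage("summarize", summarize_parks(cls))
  system_summary <- stage("summarize", systemwide_summary(park_summary))

  groups <- NULL
  if (config$typology_season %in% config$season &&
      config$typology_rcp %in% config$rcp) {
    groups <- stage("groups",
                    classify_parks(park_summary, config$typology_season,
                                   config$typology_rcp))
  }
  stats_report <- stage("stats",
                        pipeline_stats(park_summary, parks, config$season,
                                       config$rcp, config$alpha))

  paths <- c(classifications = file.path(config$out_dir, "classifications.csv"),
             park_summary = file.path(config$out_dir, "park_summary.csv"),
             systemwide_summary = file.path(config$out_dir, "systemwide_summary.csv"),
             trend_groups = file.path(config$out_dir, "trend_groups.csv"),
             stats_report = file.path(config$out_dir, "stats_report.json"),
             manifest = file.path(config$out_dir, "manifest.json"))
  stage("write", {
    readr::write_csv(cls, paths["classifications"], progress = FALSE)
    readr::write_csv(park_summary, paths["park_summary"], progress = FALSE)
    readr::write_csv(system_summary, paths["systemwide_summary"], progress = FALSE)
    if (!is.null(groups)) {
      out_groups <- groups
      attr(out_groups, "thresholds") <- NULL
      readr::write_csv(out_groups, paths["trend_groups"], progress = FALSE)
      jsonlite::write_json(
        unclass(attr(groups, "thresholds")),
        file.path(config$out_dir, "typology_thresholds.json"),
        auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(stats_report, paths["stats_report"],
                         auto_unbox = TRUE, digits = NA, na = "null",
                         pretty = TRUE)
    input_md5 <- tools::md5sum(c(config$suitability, config$thresholds,
                                 config$parks))
    names(input_md5) <- c("suitability", "thresholds", "parks")
    out_files <- unname(paths[setdiff(names(paths), "manifest")])
    out_files <- out_files[file.exists(out_files)]
    out_md5 <- tools::md5sum(out_files)
    names(out_md5) <- basename(out_files)
    manifest <- list(
      inputs = as.list(input_md5),
      settings = list(season = config$season, rcp = config$rcp,
                      alpha = config$alpha, seed = config$seed,
                      typology_season = config$typology_season,
                      typology_rcp = config$typology_rcp),
      software = list(package = "avichange",
                      version = as.character(utils::packageVersion("avichange")),
                      r_version = paste(R.version$major, R.version$minor, sep = ".")),
      n = list(records = nrow(suit), keys = nrow(cls),
               parks = nrow(parks), park_strata = nrow(park_summary)),
      outputs = as.list(out_md5))
    jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  })
  invisible(list(classifications = cls, park_summary = park_summary,
                 systemwide_summary = system_summary, trend_groups = groups,
                 stats_report = stats_report, paths = paths))
}

#' Cross-validate the three input tables
#'
#' Report-only consistency check: species in the suitability table without
#' thresholds, parks without metadata (and vice versa), and ensemble
#' completeness percentages. Never fails.
#'
#' @param suitability,thresholds,parks The three tables (tibbles) or paths
#'   to their CSVs.
#' @return List with `orphan_species` (species x season lacking thresholds),
#'   `orphan_parks`, `unused_thresholds`, `unused_parks`, `completeness`
#'   (the [audit_completeness()] table), and `pct_complete_keys`.
#' @export
validate_inputs <- function(suitability, thresholds, parks) {
  if (is.character(suitability)) suitability <- read_suitability_table(suitability, incomplete = "drop")
  if (is.character(thresholds)) thresholds <- read_thresholds(thresholds)
  if (is.character(parks)) parks <- read_parks(parks)
  completeness <- audit_completeness(suitability)
  suit_parks <- unique(suitability$park_id)
  list(
    orphan_species = missing_thresholds(suitability, thresholds),
    orphan_parks = setdiff(suit_parks, parks$park_id),
    unused_thresholds = dplyr::anti_join(
      thresholds, dplyr::distinct(suitability, .data$species_id, .data$season),
      by = c("species_id", "season")),
    unused_parks = setdiff(parks$park_id, suit_parks),
    completeness = completeness,
    pct_complete_keys = 100 * mean(completeness$complete))
}
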