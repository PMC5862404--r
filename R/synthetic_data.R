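# Synthetic suitability ensembles with planted trend classes.
#
# The generator emulates the statistical structure of the study inputs: park
# averaged suitabilities in [0, 1] for 3 time periods (present 2000-2010,
# 2011-2040, 2041-2070, coded at their calendar midpoints) x 4 GCM ensemble
# members, two seasons and two emissions pathways, with independent Gaussian
# noise per GCM x period cell. Each species x park x season x RCP key is
# assigned one of the five trend classes and a noiseless mean trajectory is
# built relative to the species' threshold so the planted class is the
# correct downstream answer.

# Region weights proportional to the park counts of the seven NPS regions.
default_region_weights <- c(
  "Alaska" = 16, "Pacific West" = 39, "Intermountain" = 82, "Midwest" = 36,
  "Southeast" = 44, "National Capital" = 18, "Northeast" = 39)

# Region-typical latitude bands (degrees N). Alaska strictly above 54 N so
# the Alaska-exclusion rule in the latitudinal analysis is exercised.
default_latitude_bands <- list(
  "Alaska" = c(55, 68), "Pacific West" = c(33, 49),
  "Intermountain" = c(31, 49), "Midwest" = c(36, 49),
  "Southeast" = c(25, 37), "National Capital" = c(38, 40),
  "Northeast" = c(39, 47))

# Region-typical longitude bands (degrees, negative = west).
default_longitude_bands <- list(
  "Alaska" = c(-164, -131), "Pacific West" = c(-124, -116),
  "Intermountain" = c(-117, -103), "Midwest" = c(-100, -85),
  "Southeast" = c(-92, -76), "National Capital" = c(-78, -76),
  "Northeast" = c(-80, -68))

#' Configure a synthetic scenario
#'
#' Bundles and validates the parameters of the synthetic-data generator.
#' The default class mix is calibrated so that, of the species currently
#' suitable in a park, 20% are planted as potential extirpations and the
#' planted colonizations amount to 28% of present richness, which implies a
#' mean binary turnover of 0.48/2.08 (about 0.23) per park. The stable share
#' is kept small because recovery of a zero-slope class is bounded by the
#' slope test's nominal type-I error.
#'
#' @param n_parks Number of parks (default 274).
#' @param n_species Number of species (default 100, the scale of a park's
#'   summer species list).
#' @param seasons Subset of `c("summer", "winter")`.
#' @param rcps Subset of `c("RCP2.6", "RCP8.5")`.
#' @param class_mix Probability vector over the five planted classes in the
#'   order of [trend_classes()]; must sum to 1.
#' @param noise_sd Standard deviation of the additive Gaussian noise per
#'   GCM x period cell, in suitability units.
#' @param threshold_range Interval inside (0, 1) from which species
#'   thresholds are drawn uniformly.
#' @param slope_scale Absolute trend, in suitability units per year, of the
#'   non-stable planted classes.
#' @param clearance Margin, in suitability units, kept between a non-crossing
#'   trajectory and the threshold.
#' @param seed Integer seed; identical seeds give identical scenarios.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_parks = 274, n_species = 100,
                            seasons = c("summer", "winter"),
                            rcps = c("RCP2.6", "RCP8.5"),
                            class_mix = c(improving = 0.2625, stable = 0.10,
                                          worsening = 0.2625,
                                          potential_colonization = 0.21875,
                                          potential_extirpation = 0.15625),
                            noise_sd = 0.01,
                            threshold_range = c(0.2, 0.6),
                            slope_scale = 0.002,
                            clearance = 0.05,
                            seed = 1L) {
  seasons <- normalize_season(seasons)
  rcps <- normalize_rcp(rcps)
  if (length(seasons) < 1 || length(rcps) < 1) abort("need >= 1 season and >= 1 rcp")
  if (n_parks < 1 || n_species < 1) abort("n_parks and n_species must be >= 1")
  if (length(class_mix) != 5) abort("class_mix must have 5 entries")
  if (is.null(names(class_mix))) names(class_mix) <- trend_classes()
  if (!setequal(names(class_mix), trend_classes())) {
    abort("class_mix names must be %s", paste(trend_classes(), collapse = ", "))
  }
  class_mix <- class_mix[trend_classes()]
  if (any(class_mix < 0)) abort("class_mix entries must be nonnegative")
  if (abs(sum(class_mix) - 1) > 1e-9) {
    abort("class_mix must sum to 1 (got %s)", format(sum(class_mix)))
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (slope_scale <= 0) abort("slope_scale must be > 0")
  if (clearance <= 0) abort("clearance must be > 0")
  if (length(threshold_range) != 2 || threshold_range[1] >= threshold_range[2] ||
      threshold_range[1] <= 0 || threshold_range[2] >= 1) {
    abort("threshold_range must be an increasing interval inside (0, 1)")
  }
  span <- 2055.5 - 2005           # present-to-mid span in calendar years
  half_rise <- slope_scale * span / 2
  if (threshold_range[1] - half_rise < 0 ||
      threshold_range[2] + clearance + slope_scale * span > 1) {
    abort("infeasible geometry: threshold_range [%s, %s] too tight for slope_scale %s over the %s-year span",
          format(threshold_range[1]), format(threshold_range[2]),
          format(slope_scale), format(span))
  }
  structure(list(
    n_parks = as.integer(n_parks), n_species = as.integer(n_species),
    seasons = seasons, rcps = rcps, n_gcm = 4L, class_mix = class_mix,
    noise_sd = noise_sd, threshold_range = threshold_range,
    slope_scale = slope_scale, clearance = clearance, span = span,
    seed = as.integer(seed)), class = "scenario_config")
}

#' Generate synthetic park metadata
#'
#' Apportions `n_parks` across the seven NPS regions by deterministic
#' largest-remainder apportionment of `region_weights` (defaults proportional
#' to the regions' actual park counts 16, 39, 82, 36, 44, 18, 39) and draws
#' park latitudes/longitudes uniformly within region-typical bands.
#'
#' @param n_parks Number of parks to generate.
#' @param region_weights Named nonnegative weights over [nps_regions()].
#' @param latitude_bands Named list of `c(min, max)` latitude bands per region.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param require_all_regions If `TRUE`, error when the apportionment leaves
#'   any positively-weighted region without a park.
#' @return Tibble of park metadata (`park_id,park_name,region,latitude,longitude`).
#' @export
generate_park_metadata <- function(n_parks,
                                   region_weights = default_region_weights,
                                   latitude_bands = default_latitude_bands,
                                   seed = NULL,
                                   require_all_regions = FALSE) {
  if (n_parks < 1) abort("n_parks must be >= 1")
  if (is.null(names(region_weights)) ||
      !setequal(names(region_weights), region_levels)) {
    abort("region_weights must be named after the 7 regions: %s",
          paste(region_levels, collapse = ", "))
  }
  region_weights <- region_weights[region_levels]
  if (any(region_weights < 0) || sum(region_weights) <= 0) {
    abort("region_weights must be nonnegative and not all zero")
  }
  counts <- largest_remainder(n_parks, region_weights)
  positive <- region_weights > 0
  if (require_all_regions && any(counts[positive] == 0)) {
    abort("n_parks = %d too small to cover all %d positively-weighted regions",
          n_parks, sum(positive))
  }
  build <- function() {
    region <- rep(region_levels, counts)
    lat_lo <- vapply(region, function(r) latitude_bands[[r]][1], numeric(1))
    lat_hi <- vapply(region, function(r) latitude_bands[[r]][2], numeric(1))
    lon_lo <- vapply(region, function(r) default_longitude_bands[[r]][1], numeric(1))
    lon_hi <- vapply(region, function(r) default_longitude_bands[[r]][2], numeric(1))
    tibble::tibble(
      park_id = sprintf("PRK%03d", seq_len(n_parks)),
      park_name = sprintf("Synthetic Park %d", seq_len(n_parks)),
      region = region,
      latitude = stats::runif(n_parks, lat_lo, lat_hi),
      longitude = stats::runif(n_parks, lon_lo, lon_hi))
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

# Deterministic largest-remainder apportionment of n among weights; ties on
# the fractional part resolve in region order.
largest_remainder <- function(n, weights) {
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(quota - base), seq_along(quota))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(weights))
}

#' Generate a synthetic scenario
#'
#' Draws species thresholds, assigns each species x park x season x RCP key a
#' planted trend class, builds the matching noiseless mean trajectory over
#' the three period midpoints (2005, 2025.5, 2055.5), and adds independent
#' Gaussian noise per GCM x period cell, clipping to \[0, 1\].
#'
#' Trajectory geometry relative to the species threshold `t` (with slope `s`
#' = `slope_scale`, clearance `c`, and present-to-mid span `L` = 50.5 yr):
#' * improving: starts at `t + c`, rises with slope `+s` (stays suitable);
#' * worsening: starts at `t + c + sL`, falls with slope `-s` (stays suitable);
#' * stable: constant at `t + c`;
#' * potential colonization: starts at `t - sL/2`, rises with slope `+s`,
#'   crossing `t` upward mid-span;
#' * potential extirpation: mirror image, crossing `t` downward.
#'
#' @param config A [scenario_config()].
#' @return A list of class `scenario` with elements `suitability`,
#'   `thresholds`, `parks`, and `truth` (the planted classes with
#'   `true_slope` and `true_present_mean`).
#' @export
#' @examples
#' sc <- generate_scenario(scenario_config(n_parks = 3, n_species = 4, seed = 7))
#' dplyr::count(sc$truth, planted_class)
generate_scenario <- function(config) {
  if (!inherits(config, "scenario_config")) {
    abort("config must come from scenario_config()")
  }
  with_seed(config$seed, generate_scenario_impl(config))
}

generate_scenario_impl <- function(config) {
  species <- sprintf("SP%03d", seq_len(config$n_species))
  thresholds <- tidyr::expand_grid(species_id = species,
                                   season = config$seasons) |>
    dplyr::mutate(threshold = stats::runif(
      dplyr::n(), config$threshold_range[1], config$threshold_range[2]))

  keys <- tidyr::expand_grid(species_id = species,
                             park_id = sprintf("PRK%03d", seq_len(config$n_parks)),
                             season = config$seasons,
                             rcp = config$rcps)
  keys$planted_class <- sample(trend_classes(), nrow(keys), replace = TRUE,
                               prob = config$class_mix)
  keys <- dplyr::left_join(keys, thresholds, by = c("species_id", "season"))

  s <- config$slope_scale
  L <- config$span
  cl <- config$clearance
  t <- keys$threshold
  geom <- switch_geometry(keys$planted_class, t, s, L, cl)
  keys$true_slope <- geom$slope
  keys$true_present_mean <- geom$m0

  cells <- tidyr::expand_grid(
    keys,
    gcm = gcm_levels,
    period = period_levels)
  x <- unname(period_midpoints()[cells$period])
  mu <- cells$true_present_mean + cells$true_slope * (x - 2005)
  y <- if (config$noise_sd > 0) {
    mu + stats::rnorm(length(mu), 0, config$noise_sd)
  } else mu
  cells$suitability <- pmin(pmax(y, 0), 1)

  suit <- cells[suitability_cols]
  truth <- keys[c("species_id", "park_id", "season", "rcp",
                  "planted_class", "true_slope", "true_present_mean")]
  parks <- generate_park_metadata(config$n_parks,
                                  seed = config$seed + 1L)
  structure(list(suitability = tibble::as_tibble(suit),
                 thresholds = tibble::as_tibble(thresholds),
                 parks = parks,
                 truth = tibble::as_tibble(truth)),
            class = "scenario")
}

# Noiseless mean-at-present (m0) and slope per planted class.
switch_geometry <- function(class, t, s, L, cl) {
  m0 <- ifelse(class == "improving", t + cl,
        ifelse(class == "worsening", t + cl + s * L,
        ifelse(class == "stable", t + cl,
        ifelse(class == "potential_colonization", t - s * L / 2,
               t + s * L / 2))))               # potential_extirpation
  slope <- ifelse(class == "improving", s,
           ifelse(class == "worsening", -s,
           ifelse(class == "stable", 0,
           ifelse(class == "potential_colonization", s, -s))))
  list(m0 = m0, slope = slope)
}

#' Write a scenario's tables to a directory
#'
#' Serializes `suitability.csv`, `thresholds.csv`, `parks.csv`, and
#' `truth.csv` with canonical headers.
#'
#' @param scenario A `scenario` list from [generate_scenario()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  if (!inherits(scenario, "scenario")) abort("not a scenario object")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    suitability = file.path(dir, "suitability.csv"),
    thresholds = file.path(dir, "thresholds.csv"),
    parks = file.path(dir, "parks.csv"),
    truth = file.path(dir, "truth.csv"))
  write_suitability_table(scenario$suitability, paths["suitability"])
  write_thresholds(scenario$thresholds, paths["thresholds"])
  write_parks(scenario$parks, paths["parks"])
  readr::write_csv(scenario$truth, paths["truth"], progress = FALSE)
  invisible(paths)
}
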