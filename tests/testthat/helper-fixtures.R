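# Shared fixture builders. All fixtures are generated in code; no files.

# 12-record ensemble (4 GCMs x 3 periods) for one key, from a linear mean
# trajectory plus optional Gaussian noise.
make_key_records <- function(present_mean = 0.5, slope = 0, noise_sd = 0,
                             species_id = "SP001", park_id = "PRK001",
                             season = "summer", rcp = "RCP8.5") {
  recs <- tidyr::expand_grid(
    species_id = species_id, park_id = park_id, season = season, rcp = rcp,
    gcm = c("CanESM2", "CESM1-CAM5", "HadGEM2-ES", "MIROC-ESM"),
    period = c("present", "near", "mid"))
  x <- unname(avichange::period_midpoints()[recs$period])
  mu <- present_mean + slope * (x - 2005)
  y <- if (noise_sd > 0) mu + stats::rnorm(nrow(recs), 0, noise_sd) else mu
  recs$suitability <- pmin(pmax(y, 0), 1)
  recs
}

# Small complete scenario reused across tests.
small_scenario <- function(seed = 11, n_parks = 6, n_species = 12, ...) {
  generate_scenario(scenario_config(n_parks = n_parks, n_species = n_species,
                                    seed = seed, ...))
}

# Random disjoint-ish species set pair for Bray-Curtis oracles.
random_set_pair <- function(pool = sprintf("S%03d", 1:40)) {
  a <- sample(pool, sample(1:25, 1))
  b <- sample(pool, sample(1:25, 1))
  list(present = a, future = b)
}

# Independent vector-form Bray-Curtis on 0/1 abundances via vegan.
vegan_bray <- function(present, future) {
  pool <- union(present, future)
  m <- rbind(as.integer(pool %in% present), as.integer(pool %in% future))
  as.numeric(vegan::vegdist(m, method = "bray"))
}

# Synthetic park-summary cohort for typology tests (proportions only).
random_cohort <- function(n) {
  tibble::tibble(
    park_id = sprintf("PRK%03d", seq_len(n)),
    season = "summer", rcp = "RCP8.5",
    richness_present = 100L, richness_future = 100L,
    n_colonization = 0L, n_extirpation = 0L,
    prop_colonization = stats::runif(n, 0, 0.6),
    prop_extirpation = stats::runif(n, 0, 0.6),
    bray_curtis = stats::runif(n, 0, 0.5),
    richness_ratio = 1, realization_fraction = 1,
    n_year_round = 0L)
}

# Brute-force sector evaluation used as the typology oracle.
brute_force_group <- function(pc, pe, thr) {
  in_rect <- pc >= thr$q1_col && pc <= thr$q3_col &&
    pe >= thr$q1_ext && pe <= thr$q3_ext
  if (in_rect) return("intermediate_change")
  above_c <- pc > thr$median_col
  above_e <- pe > thr$median_ext
  if (above_c && above_e) "high_turnover"
  else if (above_c) "high_colonization"
  else if (above_e) "high_extirpation"
  else "low_change"
}
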