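mk_cls <- function(species, pm, thr, category,
                   park = "PRK001", season = "summer", rcp = "RCP8.5") {
  tibble::tibble(species_id = species, park_id = park, season = season,
                 rcp = rcp, threshold = thr, slope = 0, intercept = 0,
                 p_value = 0.5, n_points = 12L, present_mean = pm,
                 mid_mean = pm, category = category, included = TRUE)
}

test_that("species lists follow the set algebra of realized change", {
  cls <- mk_cls(c("A", "B", "C", "D"),
                pm = c(0.6, 0.6, 0.6, 0.2), thr = 0.4,
                category = c("stable", "improving", "potential_extirpation",
                             "potential_colonization"))
  lists <- species_lists(cls)
  expect_equal(lists$present, c("A", "B", "C"))
  expect_equal(lists$future, c("A", "B", "D"))

  none <- mk_cls(c("A", "B"), pm = 0.6, thr = 0.4,
                 category = c("stable", "worsening"))
  expect_equal(species_lists(none)$future, species_lists(none)$present)
  expect_error(species_lists(dplyr::bind_rows(
    cls, mk_cls("E", 0.6, 0.4, "stable", park = "PRK002"))), "one \\(park")
})

test_that("species lists match a brute-force reconstruction on random cohorts", {
  set.seed(71)
  for (i in 1:50) {
    n <- sample(3:30, 1)
    ids <- sprintf("S%02d", seq_len(n))
    pm <- runif(n)
    cat <- ifelse(pm < 0.4,
                  sample(c("potential_colonization", "stable"), n, TRUE),
                  sample(c("stable", "improving", "worsening",
                           "potential_extirpation"), n, TRUE))
    cls <- mk_cls(ids, pm, 0.4, cat)
    lists <- species_lists(cls)
    present <- ids[pm >= 0.4]
    future <- sort(union(setdiff(present, ids[cat == "potential_extirpation"]),
                         ids[cat == "potential_colonization"]))
    expect_equal(lists$present, sort(present))
    expect_equal(lists$future, future)
  }
})

test_that("binary Bray-Curtis hits its anchors and the vector-form oracle", {
  expect_equal(bray_curtis_binary(c("A", "B"), c("A", "B")), 0)
  expect_equal(bray_curtis_binary(c("A", "B"), c("C", "D", "E")), 1)
  expect_equal(bray_curtis_binary(c("A", "B", "C"), c("B", "C", "D")), 2 / 6)
  expect_true(is.na(bray_curtis_binary(character(), character())))

  set.seed(72)
  for (i in 1:200) {
    pair <- random_set_pair()
    expect_equal(bray_curtis_binary(pair$present, pair$future),
                 vegan_bray(pair$present, pair$future), tolerance = 1e-12)
  }
})

test_that("Bray-Curtis is 0 iff no change and 1 iff disjoint lists", {
  set.seed(73)
  for (i in 1:100) {
    pair <- random_set_pair()
    bc <- bray_curtis_binary(pair$present, pair$future)
    expect_true(bc >= 0 && bc <= 1)
    expect_equal(bc == 0, setequal(pair$present, pair$future))
    expect_equal(bc == 1, length(intersect(pair$present, pair$future)) == 0)
  }
})

test_that("park summary reproduces hand-computed change metrics", {
  n_pres <- 100; n_col <- 28; n_ext <- 20
  pres_ids <- sprintf("P%03d", seq_len(n_pres))
  col_ids <- sprintf("C%03d", seq_len(n_col))
  cat <- c(rep("stable", n_pres - n_ext), rep("potential_extirpation", n_ext),
           rep("potential_colonization", n_col))
  cls <- mk_cls(c(pres_ids, col_ids), pm = c(rep(0.6, n_pres), rep(0.2, n_col)),
                thr = 0.4, category = cat)
  got <- summarize_park(cls, n_year_round = 3L)
  expect_equal(got$richness_present, 100)
  expect_equal(got$richness_future, 108)
  expect_equal(got$prop_colonization, 0.28)
  expect_equal(got$prop_extirpation, 0.20)
  expect_equal(got$richness_ratio, 1.08)
  expect_equal(got$bray_curtis, 48 / 208)
  expect_equal(got$realization_fraction, 20 / 28)
  expect_equal(got$n_year_round, 3L)
})

test_that("zero change and zero colonizations are handled", {
  cls <- mk_cls(c("A", "B"), pm = 0.6, thr = 0.4,
                category = c("stable", "improving"))
  got <- summarize_park(cls)
  expect_equal(got$bray_curtis, 0)
  expect_equal(got$richness_ratio, 1)
  expect_equal(got$n_colonization, 0)
  expect_true(is.na(got$realization_fraction))

  ext <- mk_cls(c("A", "B", "C", "D"), pm = 0.6, thr = 0.4,
                category = c("stable", rep("potential_extirpation", 3)))
  expect_true(is.na(summarize_park(ext)$realization_fraction))
})

test_that("batch summaries equal per-park summaries and keep the richness identity", {
  sc <- small_scenario(seed = 74, n_parks = 6, n_species = 25)
  cls <- classify_all(sc$suitability, sc$thresholds)
  batch <- summarize_parks(cls)
  yr <- year_round_counts(cls)
  one_by_one <- cls |>
    dplyr::group_by(park_id, season, rcp) |>
    dplyr::group_map(function(g, k) {
      nyr <- yr$n_year_round[yr$park_id == k$park_id & yr$rcp == k$rcp]
      summarize_park(dplyr::mutate(g, park_id = k$park_id, season = k$season,
                                   rcp = k$rcp), nyr)
    }) |>
    dplyr::bind_rows() |>
    dplyr::arrange(park_id, season, rcp)
  expect_equal(batch, one_by_one)
  expect_true(all(batch$richness_future ==
                    batch$richness_present - batch$n_extirpation +
                    batch$n_colonization))
})

test_that("systemwide summary matches hand-checked arithmetic", {
  ps <- random_cohort(2)
  ps$bray_curtis <- c(0.2, 0.3)
  ps$prop_colonization <- c(0.3, 0.1)
  ps$prop_extirpation <- c(0.25, 0.05)
  ps$n_colonization <- c(5L, 0L)
  ps$n_extirpation <- c(1L, 2L)
  ps$realization_fraction <- c(1 / 5, NA)
  got <- systemwide_summary(ps)
  expect_equal(got$mean_bray_curtis, 0.25)
  expect_equal(got$se_bray_curtis, stats::sd(c(0.2, 0.3)) / sqrt(2))
  expect_equal(got$se_bray_curtis, 0.05)
  # strict > 0.25: a park at exactly 0.25 is not counted
  expect_equal(got$n_parks_ext_gt25, 0L)
  expect_equal(got$n_parks_col_gt25, 1L)
  expect_equal(got$n_parks_col_exceeds_ext, 1L)
  expect_equal(got$mean_realization_fraction, 0.2)
  expect_equal(got$n_parks_no_colonization, 1L)

  same <- random_cohort(3)
  same$bray_curtis <- 0.2
  expect_equal(systemwide_summary(same)$se_bray_curtis, 0)
})

test_that("systemwide aggregates are invariant to park order", {
  sc <- small_scenario(seed = 75, n_parks = 8, n_species = 15)
  ps <- summarize_parks(classify_all(sc$suitability, sc$thresholds))
  base <- systemwide_summary(ps)
  perm <- systemwide_summary(ps[sample(nrow(ps)), ])
  expect_equal(perm, base)
  expect_error(systemwide_summary(ps[0, ]), "empty")
})
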