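test_that("constant suitability gives slope 0, p 1, category stable", {
  recs <- make_key_records(present_mean = 0.5, slope = 0)
  fit <- fit_trend(recs)
  expect_identical(fit$slope, 0)
  expect_identical(fit$p_value, 1)
  expect_equal(fit$present_mean, 0.5)
  expect_equal(classify(fit, 0.4), "stable")
})

test_that("a noiseless line is recovered exactly with p driven to 0", {
  recs <- make_key_records(present_mean = 0.1, slope = 0.002)
  fit <- fit_trend(recs)
  expect_equal(fit$slope, 0.002, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.1 - 0.002 * 2005, tolerance = 1e-9)
  expect_identical(fit$p_value, 0)
  expect_equal(fit$n_points, 12L)
})

test_that("pooled OLS matches lm() to 1e-12 on random ensembles", {
  set.seed(404)
  x_map <- period_midpoints()
  worst <- c(slope = 0, intercept = 0, p = 0)
  for (i in 1:200) {
    recs <- make_key_records(present_mean = runif(1, 0.2, 0.6),
                             slope = runif(1, -0.003, 0.003),
                             noise_sd = runif(1, 0.005, 0.05))
    fit <- fit_trend(recs)
    ref <- stats::lm(suitability ~ x, data = data.frame(
      suitability = recs$suitability, x = unname(x_map[recs$period])))
    sm <- summary(ref)$coefficients
    worst <- pmax(worst, c(
      abs(fit$slope - sm["x", "Estimate"]),
      abs(fit$intercept - sm["(Intercept)", "Estimate"]),
      abs(fit$p_value - sm["x", "Pr(>|t|)"])))
  }
  expect_lt(worst["slope"], 1e-12)
  expect_lt(worst["intercept"], 1e-9)
  expect_lt(worst["p"], 1e-12)
})

test_that("fit_trend rejects degenerate inputs", {
  recs <- make_key_records()
  expect_error(fit_trend(recs[recs$period == "present", ]), "2 distinct")
  expect_error(fit_trend(recs[recs$period != "mid", ]), "present.*mid")
  bad <- recs; bad$suitability[1] <- 1.5
  expect_error(fit_trend(bad), "outside \\[0, 1\\]")
})

test_that("the five-way decision order follows the crossing-then-trend rules", {
  mk <- function(slope, p, pm, mm) {
    tibble::tibble(slope = slope, intercept = 0, p_value = p, n_points = 12L,
                   present_mean = pm, mid_mean = mm)
  }
  # downward crossing with significant negative slope -> extirpation
  expect_equal(classify(mk(-0.004, 0.001, 0.6, 0.2), 0.4), "potential_extirpation")
  # upward crossing regardless of significance -> colonization
  expect_equal(classify(mk(0.004, 0.8, 0.3, 0.5), 0.4), "potential_colonization")
  # downward crossing without significance falls through to the trend test
  expect_equal(classify(mk(-0.004, 0.3, 0.6, 0.2), 0.4), "stable")
  expect_equal(classify(mk(0.004, 0.001, 0.5, 0.7), 0.4), "improving")
  expect_equal(classify(mk(-0.004, 0.001, 0.9, 0.6), 0.4), "worsening")
  # extirpation is a subset of worsening: remove the crossing, keep the trend
  expect_equal(classify(mk(-0.004, 0.001, 0.9, 0.45), 0.4), "worsening")
  # optional stricter colonization rule gates on the slope test
  strict <- classifier_settings(colonization_requires_trend = TRUE)
  expect_equal(classify(mk(0.004, 0.8, 0.3, 0.5), 0.4, strict), "stable")
  expect_equal(classify(mk(0.004, 0.001, 0.3, 0.5), 0.4, strict),
               "potential_colonization")
})

test_that("species-inclusion rule matches brute-force evaluation on a grid", {
  grid <- expand.grid(pm = seq(0.05, 0.95, by = 0.15),
                      mm = seq(0.05, 0.95, by = 0.15),
                      thr = c(0.2, 0.4, 0.6))
  got <- species_included(list(present_mean = grid$pm, mid_mean = grid$mm),
                          grid$thr)
  want <- mapply(function(p, m, t) p >= t || m >= t, grid$pm, grid$mm, grid$thr)
  expect_equal(got, unname(want))
  expect_true(species_included(list(present_mean = 0.5, mid_mean = 0.1), 0.4))
  expect_false(species_included(list(present_mean = 0.1, mid_mean = 0.1), 0.4))
})

test_that("year-round detection requires summer-now plus winter colonization", {
  fitv <- function(pm, mm) list(present_mean = pm, mid_mean = mm)
  expect_true(detect_year_round(fitv(0.6, 0.6), fitv(0.2, 0.5), 0.4, 0.4))
  # winter already suitable at present
  expect_false(detect_year_round(fitv(0.6, 0.6), fitv(0.5, 0.6), 0.4, 0.4))
  # summer unsuitable at present
  expect_false(detect_year_round(fitv(0.2, 0.6), fitv(0.2, 0.5), 0.4, 0.4))
})

test_that("classify_all recovers all planted classes on noiseless data", {
  sc <- small_scenario(seed = 41, n_parks = 5, n_species = 20, noise_sd = 0)
  cls <- classify_all(sc$suitability, sc$thresholds, keep_excluded = TRUE)
  tr <- dplyr::inner_join(cls, sc$truth,
                          by = c("species_id", "park_id", "season", "rcp"))
  expect_equal(nrow(tr), nrow(sc$truth))
  expect_true(all(tr$category == tr$planted_class))
  # every planted key passes the inclusion rule by construction
  expect_true(all(tr$included))
})

test_that("classify_all is invariant to row order and empty on empty input", {
  sc <- small_scenario(seed = 42, n_parks = 2, n_species = 6)
  base <- classify_all(sc$suitability, sc$thresholds)
  shuffled <- sc$suitability[sample(nrow(sc$suitability)), ]
  expect_equal(classify_all(shuffled, sc$thresholds), base)
  empty <- sc$suitability[0, ]
  expect_equal(nrow(classify_all(empty, sc$thresholds)), 0)
})

test_that("classify_all errors when a species lacks a threshold", {
  sc <- small_scenario(seed = 43, n_parks = 1, n_species = 3)
  thr <- sc$thresholds[sc$thresholds$species_id != "SP003", ]
  expect_error(classify_all(sc$suitability, thr), "SP003")
})

test_that("alpha extremes collapse the category set as expected", {
  sc <- small_scenario(seed = 44, n_parks = 3, n_species = 10,
                       seasons = "summer", rcps = "RCP8.5")
  # alpha -> 1: only exact-zero slopes can stay stable
  loose <- classify_all(sc$suitability, sc$thresholds,
                        classifier_settings(alpha = 1 - 1e-12))
  stable_slopes <- loose$slope[loose$category == "stable"]
  expect_true(all(stable_slopes == 0))
  # alpha -> 0: nothing is significant, so only stable and colonization remain
  strict <- classify_all(sc$suitability, sc$thresholds,
                         classifier_settings(alpha = 1e-300))
  expect_true(all(strict$category %in% c("stable", "potential_colonization")))
})

test_that("ordinal time coding preserves noiseless classifications", {
  sc <- small_scenario(seed = 45, n_parks = 3, n_species = 10, noise_sd = 0)
  mid <- classify_all(sc$suitability, sc$thresholds)
  ord <- classify_all(sc$suitability, sc$thresholds,
                      classifier_settings(time_coding = "ordinal"))
  expect_equal(ord$category, mid$category)
  expect_equal(sign(ord$slope), sign(mid$slope))
})

test_that("year_round_counts matches per-key detect_year_round", {
  sc <- small_scenario(seed = 46, n_parks = 4, n_species = 15)
  cls <- classify_all(sc$suitability, sc$thresholds)
  counts <- year_round_counts(cls)
  # brute-force reconstruction
  su <- cls[cls$season == "summer", ]
  wi <- cls[cls$season == "winter", ]
  brute <- merge(su, wi, by = c("species_id", "park_id", "rcp"))
  flag <- mapply(function(pm_s, t_s, pm_w, mm_w, t_w) {
    detect_year_round(list(present_mean = pm_s, mid_mean = NA),
                      list(present_mean = pm_w, mid_mean = mm_w), t_s, t_w)
  }, brute$present_mean.x, brute$threshold.x, brute$present_mean.y,
     brute$mid_mean.y, brute$threshold.y)
  want <- stats::aggregate(flag, by = list(park_id = brute$park_id,
                                           rcp = brute$rcp), FUN = sum)
  got <- merge(counts, want, by = c("park_id", "rcp"))
  expect_equal(got$n_year_round, got$x)
})
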