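# Inferential layer: seasonal contrasts with a normality gate, latitudinal
# regressions excluding Alaska, regional one-way ANOVA with a
# heteroscedasticity screen, and region-versus-rest rank tests.
#
# Test choices: Shapiro-Wilk at alpha 0.05 gates t-test vs the two-sample
# Wilcoxon rank-sum; Wilcoxon p-values are exact when both samples have
# n <= 25 and no ties, otherwise normal approximation with continuity
# correction; Levene's test is median-centered (Brown-Forsythe) and is
# reported alongside the ANOVA, not blocking. No multiple-testing correction
# is applied by default.

test_result <- function(test_name, statistic = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, p_value = NA_real_,
                        r_squared = NA_real_, slope = NA_real_,
                        direction = NA_character_, n = NA_integer_, ...) {
  tibble::tibble(test_name = test_name, statistic = statistic, df1 = df1,
                 df2 = df2, p_value = p_value, r_squared = r_squared,
                 slope = slope, direction = direction, n = n, ...)
}

wilcox_exact <- function(x, y) {
  length(x) <= 25 && length(y) <= 25 && !anyDuplicated(c(x, y))
}

#' Compare a park metric between seasons
#'
#' Two-sided comparison of a per-park metric between summer and winter,
#' choosing the test with a normality gate: Shapiro-Wilk on each sample (on
#' the paired differences when `paired = TRUE`); if either is rejected at
#' `normality_alpha`, the Wilcoxon test is used, otherwise the t-test.
#'
#' @param summer,winter Numeric vectors of the metric per park.
#' @param alpha Significance level used to call a direction.
#' @param paired Treat the samples as paired (same parks in both seasons)
#'   and use the paired t / signed-rank forms. Default `FALSE` (rank-sum).
#' @param normality_alpha Level of the Shapiro-Wilk gate.
#' @return One-row tibble: `test_name` (`"t_test"` or
#'   `"wilcoxon_rank_sum"`/`"wilcoxon_signed_rank"`), `statistic`, `df1`,
#'   `p_value`, `direction` (`"higher"`/`"lower"` for winter relative to
#'   summer when significant, else `"ns"`), and the gate's Shapiro p-values.
#' @export
compare_seasons <- function(summer, winter, alpha = 0.05, paired = FALSE,
                            normality_alpha = 0.05) {
  summer <- summer[!is.na(summer)]
  winter <- winter[!is.na(winter)]
  if (length(summer) < 3 || length(winter) < 3) {
    abort("compare_seasons needs >= 3 values per sample")
  }
  if (paired && length(summer) != length(winter)) {
    abort("paired comparison needs equal-length samples")
  }
  shapiro_p <- function(v) {
    if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
  }
  if (paired) {
    d <- winter - summer
    sw1 <- sw2 <- shapiro_p(d)
  } else {
    sw1 <- shapiro_p(summer)
    sw2 <- shapiro_p(winter)
  }
  normal <- sw1 >= normality_alpha && sw2 >= normality_alpha
  if (normal) {
    ht <- stats::t.test(winter, summer, paired = paired)
    name <- "t_test"
    df1 <- unname(ht$parameter)
  } else {
    ht <- stats::wilcox.test(winter, summer, paired = paired,
                             exact = if (paired) NULL else wilcox_exact(summer, winter),
                             correct = TRUE)
    name <- if (paired) "wilcoxon_signed_rank" else "wilcoxon_rank_sum"
    df1 <- NA_real_
  }
  direction <- if (ht$p.value < alpha) {
    if (stats::median(winter) > stats::median(summer)) "higher" else "lower"
  } else "ns"
  test_result(name, statistic = unname(ht$statistic), df1 = df1,
              p_value = ht$p.value, direction = direction,
              n = length(summer) + length(winter),
              shapiro_p_summer = sw1, shapiro_p_winter = sw2)
}

join_metric <- function(park_summaries, park_metas, metric, season, rcp) {
  if (!metric %in% names(park_summaries)) {
    abort("metric '%s' not found in park summaries", metric)
  }
  ps <- park_summaries
  if (!is.null(season)) {
    season <- normalize_season(season)
    ps <- dplyr::filter(ps, .data$season == !!season)
  }
  if (!is.null(rcp)) {
    rcp <- normalize_rcp(rcp)
    ps <- dplyr::filter(ps, .data$rcp == !!rcp)
  }
  out <- dplyr::inner_join(ps, park_metas, by = "park_id")
  out$metric_value <- out[[metric]]
  dplyr::filter(out, !is.na(.data$metric_value))
}

#' Latitudinal regression of a park metric
#'
#' Simple linear regression of a per-park metric on latitude. Parks in the
#' excluded regions (Alaska by default, where the sampled latitudinal
#' gradient is interrupted) are removed before fitting.
#'
#' @param park_summaries Output of [summarize_parks()].
#' @param park_metas Park metadata ([read_parks()]).
#' @param metric Column of `park_summaries` to model (e.g. `"bray_curtis"`,
#'   `"prop_colonization"`, `"prop_extirpation"`).
#' @param season,rcp Stratum to analyze (`NULL` = no filtering).
#' @param exclude_regions Regions dropped before fitting.
#' @return One-row tibble: `test_name = "ols"`, `slope` (per degree
#'   latitude), `statistic` (slope t), `df1` (n - 2), `p_value`,
#'   `r_squared`, `n`.
#' @export
latitude_regression <- function(park_summaries, park_metas, metric,
                                season = "summer", rcp = "RCP8.5",
                                exclude_regions = "Alaska") {
  df <- join_metric(park_summaries, park_metas, metric, season, rcp)
  df <- dplyr::filter(df, !(.data$region %in% exclude_regions))
  if (nrow(df) < 3) abort("latitude regression needs >= 3 parks after exclusions")
  if (stats::sd(df$latitude) == 0) abort("zero latitude variance")
  fit <- stats::lm(metric_value ~ latitude, data = df)
  sm <- summary(fit)
  test_result("ols",
              statistic = sm$coefficients["latitude", "t value"],
              df1 = fit$df.residual,
              p_value = sm$coefficients["latitude", "Pr(>|t|)"],
              r_squared = sm$r.squared,
              slope = sm$coefficients["latitude", "Estimate"],
              n = nrow(df))
}

#' Regional one-way ANOVA of a park metric
#'
#' Fixed-effects one-way ANOVA of a per-park metric across NPS regions
#' (df = k - 1, n - k), with a median-centered Levene heteroscedasticity
#' screen reported alongside (not blocking). Regions with fewer than 2 parks
#' are excluded with a warning.
#'
#' @inheritParams latitude_regression
#' @return One-row tibble: `test_name = "anova"`, `statistic` (F), `df1`,
#'   `df2`, `p_value`, `n`, plus `levene_statistic` and `levene_p`.
#' @export
regional_anova <- function(park_summaries, park_metas, metric,
                           season = "summer", rcp = "RCP8.5") {
  df <- join_metric(park_summaries, park_metas, metric, season, rcp)
  sizes <- table(df$region)
  small <- names(sizes)[sizes < 2]
  if (length(small) > 0) {
    warn("excluding region(s) with < 2 parks: %s", paste(small, collapse = ", "))
    df <- dplyr::filter(df, !(.data$region %in% small))
  }
  if (length(unique(df$region)) < 2) abort("ANOVA needs >= 2 regions")
  df$region <- factor(df$region)
  fit <- stats::aov(metric_value ~ region, data = df)
  tab <- summary(fit)[[1]]
  lev <- car::leveneTest(metric_value ~ region, data = df, center = stats::median)
  test_result("anova",
              statistic = tab[["F value"]][1],
              df1 = tab[["Df"]][1], df2 = tab[["Df"]][2],
              p_value = tab[["Pr(>F)"]][1],
              n = nrow(df),
              levene_statistic = lev[["F value"]][1],
              levene_p = lev[["Pr(>F)"]][1])
}

#' Compare one region's parks against the rest of the system
#'
#' Two-sided Wilcoxon rank-sum of the metric for the region's parks versus
#' all parks outside it (a rank test against the systemwide level; comparing
#' to a constant mean is not well-defined for a rank test). Direction is
#' called from the medians when significant.
#'
#' @inheritParams latitude_regression
#' @param region One of [nps_regions()].
#' @param alpha Significance level used to call a direction.
#' @return One-row tibble: `test_name = "wilcoxon_rank_sum"`, `statistic`
#'   (W for region vs rest), `p_value`, `direction`, `n`.
#' @export
region_vs_overall <- function(park_summaries, park_metas, metric, region,
                              season = "summer", rcp = "RCP8.5", alpha = 0.05) {
  if (!region %in% park_metas$region) {
    abort("region '%s' absent from park metadata", region)
  }
  df <- join_metric(park_summaries, park_metas, metric, season, rcp)
  x <- df$metric_value[df$region == region]
  y <- df$metric_value[df$region != region]
  if (length(x) < 3) abort("region '%s' has < 3 parks with the metric", region)
  if (length(y) < 3) abort("fewer than 3 parks outside region '%s'", region)
  ht <- stats::wilcox.test(x, y, exact = wilcox_exact(x, y), correct = TRUE)
  direction <- if (ht$p.value < alpha) {
    if (stats::median(x) > stats::median(y)) "higher" else "lower"
  } else "ns"
  test_result("wilcoxon_rank_sum", statistic = unname(ht$statistic),
              p_value = ht$p.value, direction = direction,
              n = length(x) + length(y))
}
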