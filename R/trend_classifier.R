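# Per-key trend regression and the five-way classification.
#
# For each species x park x season x RCP, suitability (dependent variable)
# is regressed on time, pooling the 4 GCM values at each of the 3 periods so
# the fit is the average trend across the ensemble. The slope's two-sided t
# test (n - 2 df) decides improving/stable/worsening; crossings of the
# species' TSS-derived threshold between the present and mid-century
# across-GCM means decide potential colonization/extirpation.

#' Period midpoints used as the time axis
#'
#' Calendar-year midpoints of the three projection periods: present
#' (2000-2010) -> 2005, 2011-2040 -> 2025.5, 2041-2070 -> 2055.5.
#'
#' @return Named numeric vector over `c("present", "near", "mid")`.
#' @export
period_midpoints <- function() c(present = 2005, near = 2025.5, mid = 2055.5)

#' Classifier settings
#'
#' @param alpha Two-sided significance level for the slope test (default
#'   0.05, the conventional level; the trend is "significant" when the
#'   slope's p-value falls below it).
#' @param time_coding `"midpoint"` (default) regresses on the calendar-year
#'   period midpoints so the slope is in suitability units per year;
#'   `"ordinal"` uses 0/1/2 for sensitivity checks.
#' @param colonization_requires_trend If `TRUE`, an upward threshold crossing
#'   is only labelled potential colonization when the slope is also
#'   significantly positive. Default `FALSE`: the crossing alone suffices,
#'   unlike extirpation which is a subset of the worsening trend.
#' @return A `classifier_settings` list with the resolved `period_years`.
#' @export
classifier_settings <- function(alpha = 0.05,
                                time_coding = c("midpoint", "ordinal"),
                                colonization_requires_trend = FALSE) {
  time_coding <- match.arg(time_coding)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1) {
    abort("alpha must be a single number in (0, 1)")
  }
  period_years <- if (time_coding == "midpoint") period_midpoints() else
    c(present = 0, near = 1, mid = 2)
  structure(list(alpha = alpha, time_coding = time_coding,
                 period_years = period_years,
                 colonization_requires_trend = isTRUE(colonization_requires_trend)),
            class = "classifier_settings")
}

# Closed-form pooled OLS of y on x with the degenerate-input policy:
# constant y -> slope 0, p 1 (stable by construction); an exact nonconstant
# fit -> p 0. Relative tolerance keeps the policy scale-free.
pooled_ols <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  dx <- x - xb
  sxx <- sum(dx^2)
  sxy <- sum(dx * (y - yb))
  syy <- sum((y - yb)^2)
  if (syy <= 1e-20) {
    return(list(slope = 0, intercept = yb, p_value = 1, n_points = n))
  }
  slope <- sxy / sxx
  intercept <- yb - slope * xb
  rss <- syy - slope * sxy
  if (rss <= max(1e-20, 1e-12 * syy)) {
    p <- 0
  } else {
    se <- sqrt(rss / (n - 2) / sxx)
    p <- 2 * stats::pt(-abs(slope / se), df = n - 2)
  }
  list(slope = slope, intercept = intercept, p_value = p, n_points = n)
}

#' Fit the suitability trend for one key
#'
#' Ordinary least squares of suitability on time, pooled over GCMs, for the
#' (typically 12) records of one species x park x season x RCP key.
#'
#' @param records Tibble with columns `period` and `suitability` (a `gcm`
#'   column may be present but is not used: the regression pools the
#'   ensemble).
#' @param settings A [classifier_settings()].
#' @return One-row tibble with `slope`, `intercept`, `p_value`, `n_points`,
#'   `present_mean`, and `mid_mean` (across-GCM means of the present and
#'   mid-century periods).
#' @export
#' @examples
#' recs <- tidyr::expand_grid(gcm = 1:4,
#'                            period = c("present", "near", "mid"))
#' recs$suitability <- 0.1 + 0.002 * (period_midpoints()[recs$period] - 2005)
#' fit_trend(recs)  # slope exactly 0.002, p -> 0
fit_trend <- function(records, settings = classifier_settings()) {
  period <- normalize_period(records$period)
  y <- records$suitability
  if (any(!is.finite(y) | y < 0 | y > 1)) abort("suitability values outside [0, 1]")
  if (length(unique(period)) < 2) {
    abort("fit_trend needs >= 2 distinct time periods (got %d)",
          length(unique(period)))
  }
  if (!all(c("present", "mid") %in% period)) {
    abort("fit_trend needs both 'present' and 'mid' period records")
  }
  x <- unname(settings$period_years[period])
  fit <- pooled_ols(x, y)
  tibble::tibble(slope = fit$slope, intercept = fit$intercept,
                 p_value = fit$p_value, n_points = fit$n_points,
                 present_mean = mean(y[period == "present"]),
                 mid_mean = mean(y[period == "mid"]))
}

classify_vec <- function(slope, p_value, present_mean, mid_mean, threshold,
                         alpha, colonization_requires_trend) {
  upward <- present_mean < threshold & mid_mean >= threshold
  if (colonization_requires_trend) upward <- upward & slope > 0 & p_value < alpha
  dplyr::case_when(
    upward ~ "potential_colonization",
    present_mean >= threshold & mid_mean < threshold &
      slope < 0 & p_value < alpha ~ "potential_extirpation",
    p_value < alpha & slope > 0 ~ "improving",
    p_value < alpha & slope < 0 ~ "worsening",
    .default = "stable")
}

#' Classify one fitted trend
#'
#' Applies the five-way decision rule to a fitted trend and a species
#' threshold, in this precedence order: (1) upward threshold crossing
#' (present mean below, mid-century mean at or above) -> potential
#' colonization; (2) downward crossing with a significantly negative slope
#' -> potential extirpation; (3) significantly positive slope -> improving;
#' (4) significantly negative slope -> worsening; (5) otherwise stable.
#' A downward crossing without slope significance falls through to the trend
#' test: extirpation is a subset of the worsening trend.
#'
#' @param fit One-row tibble from [fit_trend()].
#' @param threshold Species suitability threshold in (0, 1).
#' @param settings A [classifier_settings()].
#' @return One of the [trend_classes()] labels.
#' @export
classify <- function(fit, threshold, settings = classifier_settings()) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold >= 1) {
    abort("threshold must be a single number in (0, 1)")
  }
  classify_vec(fit$slope, fit$p_value, fit$present_mean, fit$mid_mean,
               threshold, settings$alpha, settings$colonization_requires_trend)
}

#' Species-inclusion rule
#'
#' A species is analyzed in a park only if the park's climate is suitable
#' for it either at present or by mid-century: the across-GCM present or
#' mid-century mean reaches the species threshold.
#'
#' @param fit One-row tibble from [fit_trend()] (or any list with
#'   `present_mean` and `mid_mean`).
#' @param threshold Species suitability threshold.
#' @return Logical.
#' @export
species_included <- function(fit, threshold) {
  fit$present_mean >= threshold | fit$mid_mean >= threshold
}

#' Detect prospective year-round suitability
#'
#' Flags a species x park x RCP for which conditions are suitable in summer
#' at present while winter is currently unsuitable but projected to become
#' suitable by mid-century (a winter potential colonization of a summer
#' resident).
#'
#' @param summer_fit,winter_fit Fits from [fit_trend()] for the same
#'   species/park/rcp in each season.
#' @param summer_threshold,winter_threshold Seasonal species thresholds.
#' @return Logical.
#' @export
detect_year_round <- function(summer_fit, winter_fit,
                              summer_threshold, winter_threshold) {
  summer_fit$present_mean >= summer_threshold &
    winter_fit$present_mean < winter_threshold &
    winter_fit$mid_mean >= winter_threshold
}

#' Fit and classify every key of a suitability table
#'
#' Vectorized batch form of [fit_trend()] + [classify()] +
#' [species_included()] over all species x park x season x RCP keys.
#'
#' @param records Suitability records tibble (canonical columns, e.g. from
#'   [read_suitability_table()] or [generate_scenario()]).
#' @param thresholds Thresholds tibble; every species x season in `records`
#'   must be covered, otherwise an error lists the orphans.
#' @param settings A [classifier_settings()].
#' @param keep_excluded If `FALSE` (default), keys failing the
#'   species-inclusion rule are dropped so the output row count equals the
#'   number of included keys; if `TRUE`, they are retained with
#'   `included = FALSE`.
#' @return Tibble with the key columns, `threshold`, the fit columns
#'   (`slope`, `intercept`, `p_value`, `n_points`, `present_mean`,
#'   `mid_mean`), `category`, and `included`.
#' @export
classify_all <- function(records, thresholds,
                         settings = classifier_settings(),
                         keep_excluded = FALSE) {
  if (nrow(records) == 0) {
    return(tibble::tibble(species_id = character(), park_id = character(),
                          season = character(), rcp = character(),
                          threshold = numeric(), slope = numeric(),
                          intercept = numeric(), p_value = numeric(),
                          n_points = integer(), present_mean = numeric(),
                          mid_mean = numeric(), category = character(),
                          included = logical()))
  }
  orphans <- missing_thresholds(records, thresholds)
  if (nrow(orphans) > 0) {
    abort("no threshold for %d species x season key(s): %s%s",
          nrow(orphans),
          paste(utils::head(paste(orphans$species_id, orphans$season, sep = "/"), 5),
                collapse = ", "),
          if (nrow(orphans) > 5) ", ..." else "")
  }
  df <- records
  df$period <- normalize_period(df$period)
  df$x <- unname(settings$period_years[df$period])
  fits <- df |>
    dplyr::group_by(.data$species_id, .data$park_id, .data$season, .data$rcp) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      n_periods = dplyr::n_distinct(.data$period),
      has_ends = all(c("present", "mid") %in% .data$period),
      present_mean = mean(.data$suitability[.data$period == "present"]),
      mid_mean = mean(.data$suitability[.data$period == "mid"]),
      sxx = sum((.data$x - mean(.data$x))^2),
      sxy = sum((.data$x - mean(.data$x)) *
                  (.data$suitability - mean(.data$suitability))),
      syy = sum((.data$suitability - mean(.data$suitability))^2),
      xbar = mean(.data$x),
      ybar = mean(.data$suitability),
      .groups = "drop")
  if (any(fits$n_periods < 2) || any(!fits$has_ends)) {
    abort("%d key(s) lack the present/mid periods needed for trend fitting",
          sum(fits$n_periods < 2 | !fits$has_ends))
  }
  out <- fits |>
    dplyr::mutate(
      slope = ifelse(.data$syy <= 1e-20, 0, .data$sxy / .data$sxx),
      intercept = .data$ybar - .data$slope * .data$xbar,
      rss = pmax(.data$syy - .data$slope * .data$sxy, 0),
      p_value = dplyr::case_when(
        syy <= 1e-20 ~ 1,
        rss <= pmax(1e-20, 1e-12 * syy) ~ 0,
        .default = 2 * stats::pt(-abs(slope / sqrt(rss / (n_points - 2) / sxx)),
                                 df = n_points - 2))) |>
    dplyr::left_join(thresholds, by = c("species_id", "season")) |>
    dplyr::mutate(
      category = classify_vec(.data$slope, .data$p_value, .data$present_mean,
                              .data$mid_mean, .data$threshold, settings$alpha,
                              settings$colonization_requires_trend),
      included = .data$present_mean >= .data$threshold |
        .data$mid_mean >= .data$threshold)
  if (!keep_excluded) out <- dplyr::filter(out, .data$included)
  out |>
    dplyr::select("species_id", "park_id", "season", "rcp", "threshold",
                  "slope", "intercept", "p_value", "n_points",
                  "present_mean", "mid_mean", "category", "included") |>
    dplyr::arrange(.data$species_id, .data$park_id, .data$season, .data$rcp)
}

#' Count prospective year-round species per park
#'
#' Batch form of [detect_year_round()]: joins each park's summer and winter
#' classifications per RCP and counts species currently suitable only in
#' summer whose winter suitability is projected to cross the threshold
#' upward. Defined per park x RCP (not per season). Keys missing one of the
#' two seasons are skipped.
#'
#' @param classifications Output of [classify_all()] covering both seasons.
#' @return Tibble `park_id, rcp, n_year_round`; parks present in the input
#'   for an RCP but with no qualifying species get 0.
#' @export
year_round_counts <- function(classifications) {
  parks <- dplyr::distinct(classifications, .data$park_id, .data$rcp)
  su <- dplyr::filter(classifications, .data$season == "summer")
  wi <- dplyr::filter(classifications, .data$season == "winter")
  if (nrow(su) == 0 || nrow(wi) == 0) {
    parks$n_year_round <- NA_integer_
    return(parks)
  }
  joined <- dplyr::inner_join(
    su[c("species_id", "park_id", "rcp", "present_mean", "threshold")],
    wi[c("species_id", "park_id", "rcp", "present_mean", "mid_mean", "threshold")],
    by = c("species_id", "park_id", "rcp"), suffix = c("_summer", "_winter"))
  flags <- joined |>
    dplyr::mutate(year_round = .data$present_mean_summer >= .data$threshold_summer &
                    .data$present_mean_winter < .data$threshold_winter &
                    .data$mid_mean >= .data$threshold_winter) |>
    dplyr::group_by(.data$park_id, .data$rcp) |>
    dplyr::summarise(n_year_round = sum(.data$year_round), .groups = "drop")
  parks |>
    dplyr::left_join(flags, by = c("park_id", "rcp")) |>
    dplyr::mutate(n_year_round = dplyr::coalesce(.data$n_year_round, 0L))
}
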