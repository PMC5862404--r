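# Relative park trend groups from cohort quantiles of the colonization and
# extirpation proportions (one season x RCP stratum, canonically summer
# under the high-emissions pathway).
#
# Plotting prop_colonization against prop_extirpation across the cohort,
# the plane is cut into five sectors: the axis-aligned interquartile
# rectangle around the joint median is "intermediate change"; outside it,
# the two median lines split the remainder into high turnover (both above),
# high colonization, high extirpation, and low change (both at or below).

#' Cohort quantile thresholds for the park typology
#'
#' Medians and quartiles of the colonization and extirpation proportions
#' across parks, computed with the linear-interpolation quantile estimator
#' (type 7, the common default).
#'
#' @param park_summaries [summarize_parks()] rows for one (season, rcp)
#'   cohort; parks with undefined proportions are dropped with a warning.
#' @return List of class `typology_thresholds` with `median_col`,
#'   `median_ext`, `q1_col`, `q3_col`, `q1_ext`, `q3_ext`, and `n_parks`.
#' @export
compute_typology_thresholds <- function(park_summaries) {
  ok <- !is.na(park_summaries$prop_colonization) &
    !is.na(park_summaries$prop_extirpation)
  if (any(!ok)) {
    warn("excluding %d park(s) with undefined proportions from the typology",
         sum(!ok))
  }
  ps <- park_summaries[ok, ]
  if (nrow(ps) < 4) {
    abort("typology needs >= 4 parks with defined proportions (got %d)", nrow(ps))
  }
  qc <- stats::quantile(ps$prop_colonization, c(0.25, 0.5, 0.75),
                        type = 7, names = FALSE)
  qe <- stats::quantile(ps$prop_extirpation, c(0.25, 0.5, 0.75),
                        type = 7, names = FALSE)
  structure(list(median_col = qc[2], median_ext = qe[2],
                 q1_col = qc[1], q3_col = qc[3],
                 q1_ext = qe[1], q3_ext = qe[3],
                 n_parks = nrow(ps)),
            class = "typology_thresholds")
}

#' Assign parks to trend groups
#'
#' Decision order: (1) a park inside the interquartile rectangle on both
#' axes is `intermediate_change`; otherwise (2) above the median on both
#' axes -> `high_turnover`; (3) above the colonization median only ->
#' `high_colonization`; (4) above the extirpation median only ->
#' `high_extirpation`; (5) at or below both medians -> `low_change`. Ties at
#' a median resolve to the low-change side.
#'
#' @param prop_col,prop_ext Numeric vectors of park proportions.
#' @param thresholds A `typology_thresholds` from
#'   [compute_typology_thresholds()], computed from the same cohort.
#' @return Character vector of [park_trend_groups()] labels.
#' @export
assign_group <- function(prop_col, prop_ext, thresholds) {
  if (!inherits(thresholds, "typology_thresholds")) {
    abort("thresholds must come from compute_typology_thresholds()")
  }
  dplyr::case_when(
    prop_col >= thresholds$q1_col & prop_col <= thresholds$q3_col &
      prop_ext >= thresholds$q1_ext & prop_ext <= thresholds$q3_ext ~
      "intermediate_change",
    prop_col > thresholds$median_col & prop_ext > thresholds$median_ext ~
      "high_turnover",
    prop_col > thresholds$median_col ~ "high_colonization",
    prop_ext > thresholds$median_ext ~ "high_extirpation",
    .default = "low_change")
}

#' Classify a park cohort into trend groups
#'
#' Restricts the park summaries to one (season, rcp) stratum — canonically
#' summer under RCP8.5, the stratum the typology is defined on — computes
#' the cohort quantile thresholds, and labels every park exactly once.
#'
#' @param park_summaries Output of [summarize_parks()].
#' @param season,rcp Stratum to classify (defaults `"summer"`, `"RCP8.5"`).
#' @return Tibble `park_id, group, prop_col, prop_ext` with the
#'   `typology_thresholds` attached as attribute `"thresholds"`.
#' @export
classify_parks <- function(park_summaries, season = "summer", rcp = "RCP8.5") {
  season <- normalize_season(season)
  rcp <- normalize_rcp(rcp)
  if (length(season) != 1 || length(rcp) != 1) {
    abort("classify_parks works on a single (season, rcp) stratum")
  }
  ps <- dplyr::filter(park_summaries, .data$season == !!season,
                      .data$rcp == !!rcp)
  if (nrow(ps) == 0) {
    abort("no park summaries for season = %s, rcp = %s", season, rcp)
  }
  ok <- !is.na(ps$prop_colonization) & !is.na(ps$prop_extirpation)
  if (any(!ok)) {
    warn("excluding %d park(s) with undefined proportions", sum(!ok))
    ps <- ps[ok, ]
  }
  thr <- compute_typology_thresholds(ps)
  out <- tibble::tibble(
    park_id = ps$park_id,
    group = assign_group(ps$prop_colonization, ps$prop_extirpation, thr),
    prop_col = ps$prop_colonization,
    prop_ext = ps$prop_extirpation)
  attr(out, "thresholds") <- thr
  out
}
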