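# Park-level community change: projected species lists, binary Bray-Curtis
# turnover, colonization/extirpation proportions, richness ratios.
#
# Species lists assume every potential colonization and extirpation is
# realized: future list = present list minus extirpations plus colonizations.

#' Present and projected species lists for one park stratum
#'
#' @param classifications [classify_all()] rows for a single
#'   (park, season, rcp) group; an error is raised for mixed groups.
#' @return List with sorted character vectors `present` (species whose
#'   across-GCM present mean reaches their threshold) and `future`
#'   (present minus potential extirpations, plus potential colonizations).
#' @export
#' @examples
#' # a park where C is extirpated and D colonizes: future list {A, B, D}
species_lists <- function(classifications) {
  grp <- dplyr::distinct(classifications, .data$park_id, .data$season, .data$rcp)
  if (nrow(grp) > 1) {
    abort("species_lists expects one (park, season, rcp) group; got %d", nrow(grp))
  }
  present <- classifications$species_id[
    classifications$present_mean >= classifications$threshold]
  ext <- classifications$species_id[
    classifications$category == "potential_extirpation"]
  col <- classifications$species_id[
    classifications$category == "potential_colonization"]
  list(present = sort(present),
       future = sort(union(setdiff(present, ext), col)))
}

#' Binary Bray-Curtis dissimilarity of two species lists
#'
#' For presence/absence lists this equals the Sorensen dissimilarity:
#' (species unique to either list) / (sum of list sizes); 0 means no change
#' and 1 complete turnover.
#'
#' @param present,future Character vectors of species identifiers.
#' @return Dissimilarity in \[0, 1\]; `NA` when both lists are empty
#'   (undefined, flagged not computed).
#' @export
#' @examples
#' bray_curtis_binary(c("A", "B", "C"), c("B", "C", "D"))  # 2/6
bray_curtis_binary <- function(present, future) {
  present <- unique(present)
  future <- unique(future)
  a <- length(present)
  b <- length(future)
  if (a + b == 0) return(NA_real_)
  shared <- length(intersect(present, future))
  (a + b - 2 * shared) / (a + b)
}

summary_cols <- c("park_id", "season", "rcp", "richness_present",
                  "richness_future", "n_colonization", "n_extirpation",
                  "prop_colonization", "prop_extirpation", "bray_curtis",
                  "richness_ratio", "realization_fraction", "n_year_round")

#' Summarize community change for one park stratum
#'
#' @param classifications [classify_all()] rows for one (park, season, rcp).
#' @param n_year_round Count of prospective year-round species for this
#'   park x RCP (see [year_round_counts()]); `NA` when winter data are absent.
#' @return One-row tibble with richness, colonization/extirpation counts and
#'   proportions, binary Bray-Curtis turnover, richness ratio
#'   (future/present), and realization fraction (extirpations per
#'   colonization; `NA` when there are no colonizations). Proportions are
#'   `NA` when present richness is 0.
#' @export
summarize_park <- function(classifications, n_year_round = NA_integer_) {
  lists <- species_lists(classifications)
  rp <- length(lists$present)
  nc <- sum(classifications$category == "potential_colonization")
  ne <- sum(classifications$category == "potential_extirpation")
  if (rp == 0) warn("park %s: zero present richness; proportions undefined",
                    classifications$park_id[1])
  tibble::tibble(
    park_id = classifications$park_id[1],
    season = classifications$season[1],
    rcp = classifications$rcp[1],
    richness_present = rp,
    richness_future = length(lists$future),
    n_colonization = nc,
    n_extirpation = ne,
    prop_colonization = if (rp > 0) nc / rp else NA_real_,
    prop_extirpation = if (rp > 0) ne / rp else NA_real_,
    bray_curtis = bray_curtis_binary(lists$present, lists$future),
    richness_ratio = if (rp > 0) length(lists$future) / rp else NA_real_,
    realization_fraction = if (nc > 0) ne / nc else NA_real_,
    n_year_round = as.integer(n_year_round))
}

#' Summarize community change for every park stratum
#'
#' Vectorized batch form of [summarize_park()] over all
#' (park, season, rcp) groups, with the year-round count attached per
#' park x RCP. Because a potential extirpation is by definition currently
#' suitable and a potential colonization currently unsuitable, the turnover
#' reduces to (n_col + n_ext) / (2 richness_present + n_col - n_ext).
#'
#' @param classifications Output of [classify_all()].
#' @param year_round Optional tibble from [year_round_counts()]; computed
#'   from `classifications` when both seasons are present, otherwise `NA`.
#' @return Tibble with one row per (park, season, rcp) and the columns of
#'   [summarize_park()].
#' @export
summarize_parks <- function(classifications, year_round = NULL) {
  if (is.null(year_round)) {
    year_round <- if (all(season_levels %in% classifications$season)) {
      year_round_counts(classifications)
    } else {
      tibble::tibble(park_id = character(), rcp = character(),
                     n_year_round = integer())
    }
  }
  out <- classifications |>
    dplyr::group_by(.data$park_id, .data$season, .data$rcp) |>
    dplyr::summarise(
      richness_present = sum(.data$present_mean >= .data$threshold),
      n_colonization = sum(.data$category == "potential_colonization"),
      n_extirpation = sum(.data$category == "potential_extirpation"),
      .groups = "drop") |>
    dplyr::mutate(
      richness_future = .data$richness_present - .data$n_extirpation +
        .data$n_colonization,
      prop_colonization = ifelse(.data$richness_present > 0,
                                 .data$n_colonization / .data$richness_present,
                                 NA_real_),
      prop_extirpation = ifelse(.data$richness_present > 0,
                                .data$n_extirpation / .data$richness_present,
                                NA_real_),
      bray_curtis = ifelse(
        .data$richness_present + .data$richness_future > 0,
        (.data$n_colonization + .data$n_extirpation) /
          (.data$richness_present + .data$richness_future),
        NA_real_),
      richness_ratio = ifelse(.data$richness_present > 0,
                              .data$richness_future / .data$richness_present,
                              NA_real_),
      realization_fraction = ifelse(.data$n_colonization > 0,
                                    .data$n_extirpation / .data$n_colonization,
                                    NA_real_))
  n_zero <- sum(out$richness_present == 0)
  if (n_zero > 0) warn("%d park stratum(s) with zero present richness", n_zero)
  out |>
    dplyr::left_join(year_round, by = c("park_id", "rcp")) |>
    dplyr::select(dplyr::all_of(summary_cols)) |>
    dplyr::arrange(.data$park_id, .data$season, .data$rcp)
}

se_mean <- function(x) stats::sd(x) / sqrt(length(x))

#' System-wide summary across parks
#'
#' Per (season, rcp): mean and standard error (sample sd / sqrt(n)) of the
#' Bray-Curtis turnover and of the extirpation and colonization proportions
#' across parks; counts and percentages of parks with strictly more than 25%
#' extirpations, strictly more than 25% colonizations, and where the number
#' of potential colonizations exceeds potential extirpations; the mean
#' per-park realization fraction (parks with zero colonizations excluded,
#' with a logged count); and the mean year-round count.
#'
#' @param park_summaries Output of [summarize_parks()]. Parks with undefined
#'   proportions (zero present richness) are excluded with a warning.
#' @return Tibble with one row per (season, rcp).
#' @export
systemwide_summary <- function(park_summaries) {
  if (nrow(park_summaries) == 0) abort("systemwide_summary: empty input")
  n_undef <- sum(is.na(park_summaries$prop_colonization))
  if (n_undef > 0) {
    warn("excluding %d park stratum(s) with undefined proportions", n_undef)
    park_summaries <- dplyr::filter(park_summaries,
                                    !is.na(.data$prop_colonization))
  }
  park_summaries |>
    dplyr::group_by(.data$season, .data$rcp) |>
    dplyr::summarise(
      n_parks = dplyr::n(),
      mean_bray_curtis = mean(.data$bray_curtis),
      se_bray_curtis = se_mean(.data$bray_curtis),
      mean_prop_extirpation = mean(.data$prop_extirpation),
      se_prop_extirpation = se_mean(.data$prop_extirpation),
      mean_prop_colonization = mean(.data$prop_colonization),
      se_prop_colonization = se_mean(.data$prop_colonization),
      n_parks_ext_gt25 = sum(.data$prop_extirpation > 0.25),
      pct_parks_ext_gt25 = 100 * mean(.data$prop_extirpation > 0.25),
      n_parks_col_gt25 = sum(.data$prop_colonization > 0.25),
      pct_parks_col_gt25 = 100 * mean(.data$prop_colonization > 0.25),
      n_parks_col_exceeds_ext = sum(.data$n_colonization > .data$n_extirpation),
      pct_parks_col_exceeds_ext =
        100 * mean(.data$n_colonization > .data$n_extirpation),
      mean_richness_ratio = mean(.data$richness_ratio),
      n_parks_no_colonization = sum(is.na(.data$realization_fraction)),
      mean_realization_fraction =
        mean(.data$realization_fraction, na.rm = TRUE),
      mean_n_year_round = mean(.data$n_year_round),
      .groups = "drop")
}
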