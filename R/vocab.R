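# Canonical vocabularies shared across the package. Periods are stored
# internally as short codes ("present", "near", "mid"); CSV files carry the
# calendar labels ("present", "2011-2040", "2041-2070").

season_levels <- c("summer", "winter")

rcp_levels <- c("RCP2.6", "RCP8.5")

period_levels <- c("present", "near", "mid")

period_file_labels <- c(present = "present", near = "2011-2040", mid = "2041-2070")

# CMIP5 ensemble members used for the projections; readers accept any labels
# as long as each key carries exactly four distinct ones.
gcm_levels <- c("CanESM2", "CESM1-CAM5", "HadGEM2-ES", "MIROC-ESM")

region_levels <- c("Alaska", "Pacific West", "Intermountain", "Midwest",
                   "Southeast", "National Capital", "Northeast")

#' Five-way suitability trend classes
#'
#' Category labels used throughout the package, in canonical order:
#' `improving`, `stable`, `worsening`, `potential_colonization`,
#' `potential_extirpation`.
#'
#' @return Character vector of the five class labels.
#' @export
#' @examples
#' trend_classes()
trend_classes <- function() {
  c("improving", "stable", "worsening",
    "potential_colonization", "potential_extirpation")
}

#' Park trend group labels
#'
#' The five relative trend groups a park can be assigned to, in canonical
#' order: `high_turnover`, `high_colonization`, `high_extirpation`,
#' `intermediate_change`, `low_change`.
#'
#' @return Character vector of the five group labels.
#' @export
#' @examples
#' park_trend_groups()
park_trend_groups <- function() {
  c("high_turnover", "high_colonization", "high_extirpation",
    "intermediate_change", "low_change")
}

#' NPS geographic regions
#'
#' The seven National Park Service regions used as the grouping factor in
#' regional comparisons.
#'
#' @return Character vector of the seven region names.
#' @export
nps_regions <- function() region_levels

abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

normalize_season <- function(x, context = "season") {
  out <- tolower(trimws(as.character(x)))
  bad <- !(out %in% season_levels) & !is.na(out)
  if (any(bad)) {
    abort("%s: invalid value(s) %s; allowed: %s", context,
          paste(unique(out[bad]), collapse = ", "),
          paste(season_levels, collapse = ", "))
  }
  out
}

normalize_rcp <- function(x, context = "rcp") {
  raw <- toupper(gsub("[ _]", "", as.character(x)))
  out <- ifelse(raw %in% c("RCP2.6", "2.6", "RCP26"), "RCP2.6",
         ifelse(raw %in% c("RCP8.5", "8.5", "RCP85"), "RCP8.5", NA_character_))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    abort("%s: invalid value(s) %s; allowed: %s", context,
          paste(unique(as.character(x)[bad]), collapse = ", "),
          paste(rcp_levels, collapse = ", "))
  }
  out
}

normalize_period <- function(x, context = "period") {
  raw <- tolower(trimws(as.character(x)))
  file_to_enum <- stats::setNames(names(period_file_labels),
                                  tolower(period_file_labels))
  out <- ifelse(raw %in% period_levels, raw,
                unname(file_to_enum[raw]))
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) {
    abort("%s: invalid value(s) %s; allowed: %s or %s", context,
          paste(unique(as.character(x)[bad]), collapse = ", "),
          paste(period_levels, collapse = ", "),
          paste(period_file_labels, collapse = ", "))
  }
  out
}
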