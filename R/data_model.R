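#' @importFrom rlang .data
NULL

suitability_cols <- c("species_id", "park_id", "season", "rcp", "gcm",
                      "period", "suitability")
threshold_cols <- c("species_id", "season", "threshold")
park_cols <- c("park_id", "park_name", "region", "latitude", "longitude")

apply_col_map <- function(df, col_map, path) {
  if (is.null(col_map)) return(df)
  if (is.null(names(col_map)) || any(names(col_map) == "")) {
    abort("col_map must be a named character vector (canonical = file column)")
  }
  missing <- setdiff(unname(col_map), names(df))
  if (length(missing) > 0) {
    abort("%s: col_map refers to absent column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  names(df)[match(unname(col_map), names(df))] <- names(col_map)
  df
}

require_cols <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort("%s: missing required column(s): %s", path,
          paste(missing, collapse = ", "))
  }
  df
}

# Validate a canonical suitability table; `where` labels error messages.
# Row numbers in messages are 1-based data rows (header excluded).
validate_suitability <- function(df, where = "suitability table") {
  df <- tibble::as_tibble(df)[suitability_cols]
  if (!is.numeric(df$suitability)) {
    abort("%s: column 'suitability' must be numeric", where)
  }
  bad <- which(!is.finite(df$suitability) | df$suitability < 0 | df$suitability > 1)
  if (length(bad) > 0) {
    abort("%s: row %d: suitability = %s outside [0, 1]", where, bad[1],
          format(df$suitability[bad[1]]))
  }
  df$season <- normalize_season(df$season, paste0(where, ": season"))
  df$rcp <- normalize_rcp(df$rcp, paste0(where, ": rcp"))
  df$period <- normalize_period(df$period, paste0(where, ": period"))
  df$species_id <- as.character(df$species_id)
  df$park_id <- as.character(df$park_id)
  df$gcm <- as.character(df$gcm)
  key <- do.call(paste, c(df[c("species_id", "park_id", "season", "rcp",
                               "gcm", "period")], sep = "\r"))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort("%s: row %d: duplicate (species, park, season, rcp, gcm, period) key: %s",
          where, dup[1], gsub("\r", "/", key[dup[1]]))
  }
  df
}

#' Read a climate-suitability table
#'
#' Reads the long-format CSV of park-averaged climate suitability values
#' (one row per species x park x season x RCP x GCM x period) and validates
#' it: suitabilities must lie in \[0, 1\], enum columns must be resolvable,
#' keys must be unique, and every (species, park, season, rcp) key must
#' carry the full 4 GCM x 3 period ensemble.
#'
#' @param path Path to a CSV file with columns
#'   `species_id,park_id,season,rcp,gcm,period,suitability`. The `period`
#'   column may use either the short codes (`present`, `near`, `mid`) or the
#'   calendar labels (`present`, `2011-2040`, `2041-2070`).
#' @param col_map Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(species_id = "species")`,
#'   absorbing dialect differences in supplementary tables.
#' @param incomplete Policy for keys missing some of their 12 GCM x period
#'   cells: `"error"` (default) aborts; `"drop"` excludes the affected keys
#'   with a warning.
#' @return A tibble of validated suitability records with canonical columns
#'   and internal period codes.
#' @seealso [write_suitability_table()], [audit_completeness()]
#' @export
read_suitability_table <- function(path, col_map = NULL,
                                   incomplete = c("error", "drop")) {
  incomplete <- match.arg(incomplete)
  if (!file.exists(path)) abort("suitability file not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- apply_col_map(df, col_map, path)
  df <- require_cols(df, suitability_cols, path)
  df <- validate_suitability(df, path)
  audit <- audit_completeness(df)
  bad <- audit[audit$n_cells != 12L, ]
  if (nrow(bad) > 0) {
    keys <- paste(bad$species_id, bad$park_id, bad$season, bad$rcp, sep = "/")
    if (incomplete == "error") {
      abort("%s: %d key(s) with incomplete GCM x period ensembles (e.g. %s with %d of 12 cells); use incomplete = \"drop\" to exclude them",
            path, nrow(bad), keys[1], bad$n_cells[1])
    }
    warn("%s: dropping %d key(s) with incomplete ensembles (%s%s)", path,
         nrow(bad), paste(utils::head(keys, 3), collapse = ", "),
         if (nrow(bad) > 3) ", ..." else "")
    df <- dplyr::anti_join(df, bad[c("species_id", "park_id", "season", "rcp")],
                           by = c("species_id", "park_id", "season", "rcp"))
  }
  df
}

#' Write a climate-suitability table
#'
#' Serializes validated suitability records to CSV with the canonical column
#' order and calendar period labels. Reals are written at full precision so
#' that a write/read round trip reproduces the exact record set.
#'
#' @param records Tibble of suitability records (canonical columns).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_suitability_table <- function(records, path) {
  df <- validate_suitability(records, "records")
  df$period <- unname(period_file_labels[df$period])
  readr::write_csv(df[suitability_cols], path, progress = FALSE)
  invisible(path)
}

#' Audit ensemble completeness
#'
#' Counts, for every (species, park, season, rcp) key in a suitability
#' table, how many of the 12 expected GCM x period cells are present.
#'
#' @param records Tibble of suitability records.
#' @return Tibble with the key columns, `n_cells` (distinct GCM x period
#'   combinations found), and `complete` (`n_cells == 12`).
#' @export
audit_completeness <- function(records) {
  records |>
    dplyr::group_by(.data$species_id, .data$park_id, .data$season, .data$rcp) |>
    dplyr::summarise(
      n_cells = dplyr::n_distinct(paste(.data$gcm, .data$period)),
      .groups = "drop") |>
    dplyr::mutate(complete = .data$n_cells == 12L)
}

validate_thresholds <- function(df, where = "thresholds table") {
  df <- tibble::as_tibble(df)[threshold_cols]
  if (!is.numeric(df$threshold)) abort("%s: column 'threshold' must be numeric", where)
  bad <- which(!is.finite(df$threshold) | df$threshold <= 0 | df$threshold >= 1)
  if (length(bad) > 0) {
    abort("%s: row %d: threshold = %s outside open interval (0, 1)", where,
          bad[1], format(df$threshold[bad[1]]))
  }
  df$season <- normalize_season(df$season, paste0(where, ": season"))
  df$species_id <- as.character(df$species_id)
  key <- paste(df$species_id, df$season, sep = "/")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    abort("%s: duplicate (species, season) key: %s", where, key[dup[1]])
  }
  df
}

#' Read species suitability thresholds
#'
#' Reads the per-species, per-season suitability cut-points (TSS-derived,
#' taken as given) that binarize suitability into suitable/unsuitable.
#'
#' @param path CSV with columns `species_id,season,threshold`.
#' @return Tibble of validated thresholds, one row per (species, season).
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) abort("thresholds file not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- require_cols(df, threshold_cols, path)
  validate_thresholds(df, path)
}

#' Write species suitability thresholds
#' @param thresholds Tibble with columns `species_id,season,threshold`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_thresholds <- function(thresholds, path) {
  df <- validate_thresholds(thresholds, "thresholds")
  readr::write_csv(df[threshold_cols], path, progress = FALSE)
  invisible(path)
}

validate_parks <- function(df, where = "parks table") {
  df <- tibble::as_tibble(df)[park_cols]
  df$park_id <- as.character(df$park_id)
  df$park_name <- as.character(df$park_name)
  df$region <- as.character(df$region)
  bad_region <- which(!(df$region %in% region_levels))
  if (length(bad_region) > 0) {
    abort("%s: row %d: unknown region \"%s\"; allowed: %s", where,
          bad_region[1], df$region[bad_region[1]],
          paste(region_levels, collapse = ", "))
  }
  if (!is.numeric(df$latitude)) abort("%s: column 'latitude' must be numeric", where)
  bad_lat <- which(!is.finite(df$latitude) | df$latitude < 24 | df$latitude > 72)
  if (length(bad_lat) > 0) {
    abort("%s: row %d: latitude = %s outside [24, 72] degrees N", where,
          bad_lat[1], format(df$latitude[bad_lat[1]]))
  }
  if (!is.numeric(df$longitude)) abort("%s: column 'longitude' must be numeric", where)
  dup <- which(duplicated(df$park_id))
  if (length(dup) > 0) abort("%s: duplicate park_id: %s", where, df$park_id[dup[1]])
  df
}

#' Read park metadata
#'
#' Reads park identifiers, names, NPS regions, and coordinates. Longitude is
#' stored signed with negative values west of Greenwich. Park grouping of
#' jointly-managed units is assumed already applied upstream.
#'
#' @param path CSV with columns `park_id,park_name,region,latitude,longitude`.
#' @return Tibble of validated park metadata.
#' @export
read_parks <- function(path) {
  if (!file.exists(path)) abort("parks file not found: %s", path)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- require_cols(df, park_cols, path)
  validate_parks(df, path)
}

#' Write park metadata
#' @param parks Tibble with columns `park_id,park_name,region,latitude,longitude`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parks <- function(parks, path) {
  df <- validate_parks(parks, "parks")
  readr::write_csv(df[park_cols], path, progress = FALSE)
  invisible(path)
}

#' Report species lacking thresholds
#'
#' Compares the species x season keys of a suitability table against the
#' thresholds table and reports (never silently drops) species with no
#' cut-point.
#'
#' @param records Suitability records tibble.
#' @param thresholds Thresholds tibble.
#' @return Tibble of (species_id, season) keys present in `records` but
#'   absent from `thresholds`; zero rows when coverage is complete.
#' @export
missing_thresholds <- function(records, thresholds) {
  dplyr::distinct(records, .data$species_id, .data$season) |>
    dplyr::anti_join(thresholds, by = c("species_id", "season"))
}
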