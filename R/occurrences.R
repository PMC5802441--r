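#' Read occurrence records
#'
#' Reads point records of species observations from a delimited table (or
#' a point-vector CSV, which differs only in its default column names).
#' Rows with unparseable or out-of-range coordinates (longitude outside
#' [-180, 180], latitude outside [-90, 90]) or an empty species id are
#' dropped and counted; the count is reported via a message and stored in
#' the `dropped` attribute. Duplicate (species, lon, lat) rows are kept —
#' de-duplication to occupied pixels happens downstream.
#'
#' @param path file path of a delimited text table.
#' @param species_col,lon_col,lat_col column names holding the species
#'   identifier and WGS84 coordinates.
#' @param source_col optional column with a per-record source tag.
#' @return tibble with `species_id`, `lon`, `lat` (and `source` if
#'   requested); attribute `dropped` holds the number of discarded rows.
#' @export
read_occurrences <- function(path, species_col = "species_id",
                             lon_col = "lon", lat_col = "lat",
                             source_col = NULL) {
  if (!file.exists(path)) stop("occurrence file not found: ", path)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(raw) == 0) stop("occurrence file is empty: ", path)
  need <- c(species_col, lon_col, lat_col)
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("occurrence table lacks required column(s): ",
         paste(missing, collapse = ", "))
  }
  occ <- tibble::tibble(
    species_id = as.character(raw[[species_col]]),
    lon = suppressWarnings(as.numeric(raw[[lon_col]])),
    lat = suppressWarnings(as.numeric(raw[[lat_col]]))
  )
  if (!is.null(source_col)) occ$source <- as.character(raw[[source_col]])
  validate_occurrences(occ)
}

#' Validate an in-memory occurrence table
#'
#' @param occ data frame with `species_id`, `lon`, `lat`.
#' @return validated tibble with invalid rows dropped (count in the
#'   `dropped` attribute).
#' @export
validate_occurrences <- function(occ) {
  occ <- tibble::as_tibble(occ)
  ok <- !is.na(occ$lon) & !is.na(occ$lat) &
    occ$lon >= -180 & occ$lon <= 180 &
    occ$lat >= -90 & occ$lat <= 90 &
    !is.na(occ$species_id) & nzchar(occ$species_id)
  dropped <- sum(!ok)
  if (dropped > 0) {
    message(dropped, " occurrence record(s) dropped (bad coordinates or species id)")
  }
  out <- occ[ok, ]
  attr(out, "dropped") <- dropped
  out
}

#' Write an occurrence table to CSV
#' @param occ occurrence tibble.
#' @param path output path.
#' @export
write_occurrences <- function(occ, path) {
  readr::write_csv(occ, path)
  invisible(path)
}
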