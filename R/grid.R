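#' Build the graticule analysis grid
#'
#' Creates the rectangular analysis grid of `cell_size_arcmin` arc-minute
#' cells covering the study polygon. The grid is anchored to the (0, 0)
#' graticule: the bounding box of the polygon is snapped outward to
#' multiples of the cell size, so the same study area always yields the
#' same cells. The study mask is the subset of cells whose rectangle
#' intersects the study polygon. Cells are half-open
#' `[west, east) x [south, north)`; `row = 1` is the southernmost row.
#'
#' @param study_polygon a [polygon_set()] with the study-area boundary.
#' @param cell_size_arcmin cell size in arc-minutes (default 10).
#' @return an object of class `grid_system`: list with `extent`,
#'   `cell_size_arcmin`, `ncol`, `nrow` and a `cells` tibble
#'   (`cell_id`, `col`, `row`, `west`, `south`, `east`, `north`,
#'   `in_study`).
#' @export
build_grid <- function(study_polygon, cell_size_arcmin = 10) {
  stopifnot(cell_size_arcmin > 0)
  areas <- polygon_area_deg(study_polygon)
  if (sum(areas$area_deg2) <= 0) stop("study polygon has zero area")
  cs <- cell_size_arcmin / 60
  v <- study_polygon$vertices
  west <- floor(min(v$lon) / cs) * cs
  east <- ceiling(max(v$lon) / cs) * cs
  south <- floor(min(v$lat) / cs) * cs
  north <- ceiling(max(v$lat) / cs) * cs
  nc <- round((east - west) / cs)
  nr <- round((north - south) / cs)
  cells <- tidyr::expand_grid(row = seq_len(nr), col = seq_len(nc)) |>
    dplyr::mutate(
      west = !!west + (.data$col - 1) * cs,
      south = !!south + (.data$row - 1) * cs,
      east = .data$west + cs,
      north = .data$south + cs,
      cell_id = sprintf("c%03d_r%03d", .data$col, .data$row)
    ) |>
    dplyr::relocate("cell_id")
  cells$in_study <- purrr::pmap_lgl(
    cells[, c("west", "south", "east", "north")],
    function(west, south, east, north) {
      rect_intersects(study_polygon, west, south, east, north)
    }
  )
  structure(
    list(extent = c(west = west, south = south, east = east, north = north),
         cell_size_arcmin = cell_size_arcmin, ncol = nc, nrow = nr,
         cells = cells),
    class = "grid_system"
  )
}

#' @export
print.grid_system <- function(x, ...) {
  cat(sprintf("<grid_system> %d x %d cells of %g', %d in study mask\n",
              x$ncol, x$nrow, x$cell_size_arcmin, sum(x$cells$in_study)))
  invisible(x)
}

#' Locate points in grid cells
#'
#' Vectorised coordinate-to-cell lookup using the grid's half-open edge
#' rule (a point on a shared east/north edge belongs to the next cell).
#'
#' @param grid a `grid_system`.
#' @param lon,lat coordinate vectors.
#' @return tibble with `col`, `row`, `cell_id` (`NA` outside the extent).
#' @export
grid_locate <- function(grid, lon, lat) {
  cs <- grid$cell_size_arcmin / 60
  e <- grid$extent
  col <- floor((lon - e["west"]) / cs) + 1
  row <- floor((lat - e["south"]) / cs) + 1
  ok <- col >= 1 & col <= grid$ncol & row >= 1 & row <= grid$nrow &
    !is.na(lon) & !is.na(lat)
  col[!ok] <- NA; row[!ok] <- NA
  tibble::tibble(
    col = as.integer(col), row = as.integer(row),
    cell_id = ifelse(ok, sprintf("c%03d_r%03d", as.integer(col), as.integer(row)),
                     NA_character_)
  )
}

#' Spatial join of occurrences onto the analysis grid
#'
#' Assigns every record to the grid cell containing it and reduces to the
#' per-species sets of occupied cells. Records outside the grid extent are
#' logged and excluded (count in the `excluded` attribute).
#'
#' @param occ occurrence tibble (`species_id`, `lon`, `lat`).
#' @param grid a `grid_system` from [build_grid()].
#' @return tibble with one row per (species, occupied cell):
#'   `species_id`, `cell_id`, `col`, `row`, `n_records`. The distinct
#'   `cell_id` values form the sampled-cell set.
#' @export
spatial_join <- function(occ, grid) {
  loc <- grid_locate(grid, occ$lon, occ$lat)
  out_of_extent <- sum(is.na(loc$cell_id))
  if (out_of_extent > 0) {
    message(out_of_extent, " record(s) outside the grid extent excluded from the join")
  }
  joined <- dplyr::bind_cols(occ[, "species_id"], loc) |>
    dplyr::filter(!is.na(.data$cell_id)) |>
    dplyr::count(.data$species_id, .data$cell_id, .data$col, .data$row,
                 name = "n_records") |>
    dplyr::arrange(.data$species_id, .data$cell_id)
  attr(joined, "excluded") <- out_of_extent
  joined
}

#' Cells sampled by at least one record
#' @param joined output of [spatial_join()].
#' @return tibble of distinct occupied cells.
#' @export
sampled_cells <- function(joined) {
  dplyr::distinct(joined, .data$cell_id, .data$col, .data$row) |>
    dplyr::arrange(.data$cell_id)
}
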