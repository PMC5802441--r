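#' Area of occupancy (AOO)
#'
#' Reduces a species' records to the set of occupied pixels of the
#' analysis raster and sums their areas. At the native resolution every
#' occupied pixel counts once; at the coarse alternative the pixels are
#' aggregated into 2 x 2 blocks and a block counts whole if any of its
#' pixels is occupied (so the coarse area is always at least the native
#' one, matching the IUCN 4 km² convention relative to the 1 km²
#' analysis grid).
#'
#' @param occ_species occurrence tibble for one species.
#' @param template a [grid_raster()] defining the analysis pixels (the
#'   elevation or any climate layer).
#' @param block aggregation factor: 1 = native pixels, 2 = 2 x 2 blocks.
#' @return object of class `range_estimate` with `pixels` (tibble `row`,
#'   `col` at native resolution), `area_km2`, `method`, `block`.
#' @export
aoo <- function(occ_species, template, block = 1) {
  stopifnot(block %in% c(1, 2), nrow(occ_species) >= 1)
  rc <- raster_rowcol(template, occ_species$lon, occ_species$lat)
  px <- dplyr::distinct(tidyr::drop_na(rc))
  if (block == 1) {
    centres <- raster_centres(template, px$row, px$col)
    area <- sum(pixel_area_km2(centres$lat, template$res))
    native <- px
  } else {
    blocks <- dplyr::distinct(tibble::tibble(
      brow = (px$row - 1L) %/% 2L, bcol = (px$col - 1L) %/% 2L))
    native <- tidyr::expand_grid(blocks, dr = 1:2, dc = 1:2) |>
      dplyr::transmute(row = .data$brow * 2L + .data$dr,
                       col = .data$bcol * 2L + .data$dc) |>
      dplyr::filter(.data$row <= nrow(template$values),
                    .data$col <= ncol(template$values))
    centres <- raster_centres(template, native$row, native$col)
    area <- sum(pixel_area_km2(centres$lat, template$res))
  }
  new_range_estimate(occ_species$species_id[1], "AOO", native, area,
                     block = block)
}

new_range_estimate <- function(species_id, method, pixels, area_km2,
                               block = 1, fallback_used = FALSE) {
  structure(
    list(species_id = species_id, method = method,
         pixels = dplyr::arrange(pixels, .data$row, .data$col),
         area_km2 = area_km2, block = block, fallback_used = fallback_used,
         protected_km2 = NA_real_, percent_protected = NA_real_),
    class = "range_estimate"
  )
}

#' @export
print.range_estimate <- function(x, ...) {
  cat(sprintf("<range_estimate> %s %s%s: %d pixels, %.2f km2%s\n",
              x$species_id, x$method,
              if (x$block > 1) sprintf(" (block %d)", x$block) else "",
              nrow(x$pixels), x$area_km2,
              if (!is.na(x$percent_protected)) {
                sprintf(", %.2f%% protected", x$percent_protected)
              } else ""))
  invisible(x)
}

#' Minimum convex polygon of a species' records
#'
#' Convex hull of the record coordinates in degree space. With fewer than
#' three distinct, non-collinear points no polygon exists and a fallback
#' signal is returned — the extent of occurrence then falls back to the
#' occupied-pixel set.
#'
#' @param occ_species occurrence tibble for one species.
#' @return list with `ok` flag, hull `vertices` (tibble `lon`, `lat`,
#'   counter-clockwise), and planar `area_deg2`; `ok = FALSE` signals the
#'   fallback.
#' @export
mcp <- function(occ_species) {
  pts <- dplyr::distinct(occ_species[, c("lon", "lat")])
  if (nrow(pts) >= 3) {
    h <- rev(grDevices::chull(pts$lon, pts$lat))   # counter-clockwise
    v <- pts[h, ]
    n <- nrow(v)
    j <- c(n, seq_len(n - 1))
    area <- sum(v$lon[j] * v$lat - v$lon * v$lat[j]) / 2
    if (abs(area) > 0) {
      return(list(ok = TRUE, vertices = v, area_deg2 = abs(area)))
    }
  }
  list(ok = FALSE, vertices = NULL, area_deg2 = NA_real_)
}

#' Extent of occurrence (EOO)
#'
#' The pixel set of the analysis raster inside the species' minimum
#' convex polygon, filtered by elevation, plus the species' own occupied
#' pixels (a record's pixel is part of the range by definition, even when
#' its centre falls marginally outside the hull). Two filter modes:
#' `"observed-range"` keeps pixels whose elevation lies within the
#' min–max of the record elevations (default); `"mean-band"` keeps pixels
#' within mean ± `k` standard deviations. Species without a valid MCP use
#' the occupied-pixel set directly (`fallback_used = TRUE`).
#'
#' @param occ_species occurrence tibble for one species.
#' @param elevation [grid_raster()] of elevation; also the pixel template.
#' @param filter_mode `"observed-range"` or `"mean-band"`.
#' @param k band half-width in standard deviations for `"mean-band"`.
#' @return a `range_estimate` with `method = "EOO"`.
#' @export
eoo <- function(occ_species, elevation,
                filter_mode = c("observed-range", "mean-band"), k = 1) {
  filter_mode <- match.arg(filter_mode)
  hull <- mcp(occ_species)
  occ_px <- aoo(occ_species, elevation)$pixels
  if (!hull$ok) {
    centres <- raster_centres(elevation, occ_px$row, occ_px$col)
    area <- sum(pixel_area_km2(centres$lat, elevation$res))
    return(new_range_estimate(occ_species$species_id[1], "EOO", occ_px, area,
                              fallback_used = TRUE))
  }
  elv <- extract_at_points(elevation, occ_species)
  ev <- elv$value[!elv$excluded]
  band <- if (filter_mode == "observed-range") {
    c(min(ev), max(ev))
  } else {
    m <- mean(ev); s <- stats::sd(ev)
    if (is.na(s)) s <- 0
    c(m - k * s, m + k * s)
  }
  hp <- polygon_set(tibble::tibble(name = "mcp", part = 1L,
                                   lon = hull$vertices$lon,
                                   lat = hull$vertices$lat))
  # candidate pixels restricted to the hull's bounding box
  bb_rc <- raster_rowcol(
    elevation,
    lon = pmin(pmax(range(hull$vertices$lon), raster_extent(elevation)["west"]),
               raster_extent(elevation)["east"] - 1e-9),
    lat = pmin(pmax(range(hull$vertices$lat), raster_extent(elevation)["south"]),
               raster_extent(elevation)["north"] - 1e-9)
  )
  rows <- seq(min(bb_rc$row, na.rm = TRUE), max(bb_rc$row, na.rm = TRUE))
  cols <- seq(min(bb_rc$col, na.rm = TRUE), max(bb_rc$col, na.rm = TRUE))
  cand <- tidyr::expand_grid(row = rows, col = cols)
  cc <- raster_centres(elevation, cand$row, cand$col)
  inside <- points_in_feature(hp, "mcp", cc$lon, cc$lat)
  elev_val <- elevation$values[cbind(cand$row, cand$col)]
  pass <- inside & !is.na(elev_val) & elev_val >= band[1] & elev_val <= band[2]
  px <- dplyr::distinct(dplyr::bind_rows(cand[pass, ], occ_px))
  centres <- raster_centres(elevation, px$row, px$col)
  area <- sum(pixel_area_km2(centres$lat, elevation$res))
  est <- new_range_estimate(occ_species$species_id[1], "EOO", px, area)
  est$filter_mode <- filter_mode
  est$elevation_band <- band
  est
}

#' Overlay a range estimate with the protected-area network
#'
#' A pixel counts as protected iff its centre lies inside any protected
#' area polygon; the protected percentage is reported half-up to 2
#' decimal places. An empty range yields an undefined percentage and a
#' flag.
#'
#' @param range a `range_estimate` (from [aoo()] or [eoo()]).
#' @param pas protected areas as a [polygon_set()].
#' @param template the analysis [grid_raster()] used to build the range.
#' @return the range estimate with `protected_km2` and
#'   `percent_protected` filled in.
#' @export
protected_fraction <- function(range, pas, template) {
  if (nrow(range$pixels) == 0) {
    range$protected_km2 <- 0
    range$percent_protected <- NA_real_
    range$empty <- TRUE
    return(range)
  }
  centres <- raster_centres(template, range$pixels$row, range$pixels$col)
  inside <- points_in_any(pas, centres$lon, centres$lat)
  areas <- pixel_area_km2(centres$lat, template$res)
  range$protected_km2 <- sum(areas[inside])
  range$percent_protected <- round_half_up(
    100 * range$protected_km2 / range$area_km2, 2)
  range
}

#' @method tidy range_estimate
#' @export
tidy.range_estimate <- function(x, ...) {
  tibble::tibble(
    species_id = x$species_id, method = x$method, block = x$block,
    n_pixels = nrow(x$pixels), area_km2 = x$area_km2,
    protected_km2 = x$protected_km2,
    percent_protected = x$percent_protected,
    fallback_used = x$fallback_used
  )
}

#' Gap analysis across all species
#'
#' Runs both range estimators (AOO at the native pixel resolution and the
#' elevation-filtered MCP-based EOO) for every species, overlays them with
#' the protected-area network and scores each species against the
#' conservation targets (defaults: the Aichi 17% and the older 12%).
#'
#' @param occ occurrence tibble for all species.
#' @param attributes species attribute tibble (needs `species_id` and
#'   logical `endemic`).
#' @param pas protected areas as a [polygon_set()].
#' @param template the analysis [grid_raster()].
#' @param targets protection targets in percent.
#' @param filter_mode,k forwarded to [eoo()].
#' @return object of class `gap_report`: `species` (per-species tibble in
#'   both approaches), `counts` (per approach and target, plus combined
#'   either-approach counts and zero-protection counts, overall and for
#'   endemics), `targets`.
#' @export
gap_report <- function(occ, attributes, pas, template, targets = c(17, 12),
                       filter_mode = "observed-range", k = 1) {
  stopifnot(all(targets > 0 & targets <= 100))
  species <- sort(unique(occ$species_id))
  per_species <- purrr::map_dfr(species, function(sp) {
    o <- occ[occ$species_id == sp, ]
    dplyr::bind_rows(
      tidy(protected_fraction(aoo(o, template), pas, template)),
      tidy(protected_fraction(eoo(o, template, filter_mode, k), pas, template))
    )
  })
  per_species <- dplyr::left_join(
    per_species,
    attributes[, intersect(c("species_id", "endemic"), names(attributes))],
    by = "species_id"
  )
  if (!"endemic" %in% names(per_species)) per_species$endemic <- FALSE

  wide <- per_species |>
    dplyr::select("species_id", "endemic", "method", "percent_protected") |>
    tidyr::pivot_wider(names_from = "method", values_from = "percent_protected")
  count_block <- function(tbl, label) {
    dplyr::bind_rows(lapply(targets, function(tg) {
      tibble::tibble(
        scope = label, target = tg,
        aoo_pass = sum(tbl$AOO >= tg, na.rm = TRUE),
        eoo_pass = sum(tbl$EOO >= tg, na.rm = TRUE),
        either_pass = sum(tbl$AOO >= tg | tbl$EOO >= tg, na.rm = TRUE)
      )
    })) |>
      dplyr::mutate(
        aoo_zero = sum(tbl$AOO == 0, na.rm = TRUE),
        eoo_zero = sum(tbl$EOO == 0, na.rm = TRUE),
        n_species = nrow(tbl)
      )
  }
  counts <- dplyr::bind_rows(
    count_block(wide, "all"),
    count_block(wide[wide$endemic %in% TRUE, ], "endemic")
  )
  structure(list(species = per_species, counts = counts, targets = targets),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  n <- length(unique(x$species$species_id))
  cat(sprintf("<gap_report> %d species vs targets %s%%\n", n,
              paste(x$targets, collapse = "/")))
  print(x$counts)
  invisible(x)
}

#' @method tidy gap_report
#' @export
tidy.gap_report <- function(x, ...) x$species

#' @method glance gap_report
#' @export
glance.gap_report <- function(x, ...) {
  dplyr::filter(x$counts, .data$scope == "all")
}

#' Sorted per-species protection bars
#'
#' The bar-plot shape of the gap analysis: per approach, species sorted
#' by their protected percentage.
#'
#' @param report a [gap_report()].
#' @return tibble: `method`, `rank`, `species_id`, `percent_protected`,
#'   `endemic`.
#' @export
gap_bars <- function(report) {
  report$species |>
    dplyr::select("method", "species_id", "percent_protected", "endemic") |>
    dplyr::group_by(.data$method) |>
    dplyr::arrange(dplyr::desc(.data$percent_protected), .data$species_id,
                   .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}
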