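#' The nine land-cover classes
#'
#' Class codes 1–9 used by all categorical land-cover rasters.
#' @export
landcover_classes <- tibble::tibble(
  code = 1:9,
  class = c("Tree Open", "Cropland", "Cropland / Other vegetation mosaic",
            "Shrub", "Herbaceous", "Sparse Vegetation",
            "Bare Areas Gravel Rock", "Bare Areas Sand", "Urban")
)

# one root seed, per-component derived streams
substream <- function(seed, i) (abs(seed) + 104729L * i) %% 2147483647L

# smooth random surface: sum of Gaussian bumps over the pixel lattice
smooth_field <- function(lon, lat, n_bumps, amp, width_frac = c(0.1, 0.3)) {
  W <- diff(range(lon)); H <- diff(range(lat))
  f <- matrix(0, length(lat), length(lon))
  LON <- matrix(lon, length(lat), length(lon), byrow = TRUE)
  LAT <- matrix(lat, length(lat), length(lon))
  for (b in seq_len(n_bumps)) {
    cx <- stats::runif(1, min(lon), max(lon))
    cy <- stats::runif(1, min(lat), max(lat))
    sx <- stats::runif(1, width_frac[1], width_frac[2]) * W
    sy <- stats::runif(1, width_frac[1], width_frac[2]) * H
    a <- stats::runif(1, -amp, amp)
    f <- f + a * exp(-((LON - cx)^2 / (2 * sx^2) + (LAT - cy)^2 / (2 * sy^2)))
  }
  f
}

#' Gaussian niche suitability in climate space
#'
#' The suitability kernel every virtual species is built from:
#' `exp(-((b1-c1)/w1)^2/2 - ((b12-c2)/w2)^2/2)`. As the widths grow the
#' surface flattens to 1 everywhere, so an infinitely wide niche samples
#' the background climate uniformly.
#'
#' @param b1,b12 climate values (annual mean temperature, annual
#'   precipitation).
#' @param centre length-2 niche centre `(c1, c2)`.
#' @param width length-2 niche widths `(w1, w2)`, same units.
#' @return suitability in (0, 1].
#' @export
niche_suitability <- function(b1, b12, centre, width) {
  exp(-0.5 * ((b1 - centre[1]) / width[1])^2 -
        0.5 * ((b12 - centre[2]) / width[2])^2)
}

gaussian_bump <- function(lon, lat, cx, cy, sx, sy, amp) {
  LON <- matrix(lon, length(lat), length(lon), byrow = TRUE)
  LAT <- matrix(lat, length(lat), length(lon))
  amp * exp(-((LON - cx)^2 / (2 * sx^2) + (LAT - cy)^2 / (2 * sy^2)))
}

#' Generate a synthetic study system
#'
#' Builds a complete, self-consistent virtual study region: a two-massif
#' elevation surface (a north-eastern mountain arc and a southern coastal
#' massif, echoing the geometry of arid-belt study areas), twelve
#' mutually consistent bioclim surfaces (temperature variables follow a
#' −6.5 °C/km lapse rate on elevation; precipitation combines a coastal
#' gradient with an orographic term; subsidiary variables are smooth
#' transforms that respect the bioclim order constraints), a nine-class
#' land-cover mosaic thresholded on elevation and precipitation with
#' categorical noise, an irregular study boundary, administrative
#' regions, and a protected-area network whose individual areas are
#' log-uniform over about five orders of magnitude and sum to a chosen
#' fraction of the study area. All layers outside the boundary are set to
#' missing. Identical seeds give bit-identical worlds.
#'
#' @param seed integer root seed; every component draws from a derived
#'   substream.
#' @param extent named vector `(west, south, east, north)` in degrees.
#' @param resolution pixel size in degrees.
#' @param n_regions number of administrative regions (longitudinal
#'   slabs).
#' @param n_protected number of protected areas.
#' @param protected_coverage_fraction total protected fraction of the
#'   study-area polygon, in `[0, 0.5]`.
#' @return object of class `synthetic_world`.
#' @export
generate_world <- function(seed = 1,
                           extent = c(west = 52, south = 16, east = 58,
                                      north = 24),
                           resolution = 0.05,
                           n_regions = 5, n_protected = 22,
                           protected_coverage_fraction = 0.04) {
  if (protected_coverage_fraction < 0 || protected_coverage_fraction > 0.5) {
    stop("protected_coverage_fraction must be in [0, 0.5]")
  }
  nlon <- round((extent["east"] - extent["west"]) / resolution)
  nlat <- round((extent["north"] - extent["south"]) / resolution)
  lon <- extent["west"] + (seq_len(nlon) - 0.5) * resolution
  lat <- extent["north"] - (seq_len(nlat) - 0.5) * resolution  # row 1 = north
  W <- diff(range(lon)); H <- diff(range(lat))
  mk <- function(v, kind = "continuous", classes = NULL) {
    grid_raster(v, west = unname(extent["west"]), north = unname(extent["north"]),
                dlon = resolution, dlat = resolution, kind = kind,
                classes = classes)
  }

  # --- elevation: two fixed massifs + seeded secondary relief -----------
  set.seed(substream(seed, 1))
  elev <- gaussian_bump(lon, lat, extent["west"] + 0.78 * W,
                        extent["south"] + 0.82 * H, 0.16 * W, 0.10 * H, 2600) +
    gaussian_bump(lon, lat, extent["west"] + 0.30 * W,
                  extent["south"] + 0.10 * H, 0.12 * W, 0.06 * H, 1500) +
    smooth_field(lon, lat, 12, 180, c(0.05, 0.2))
  elev <- pmax(elev, 0)

  # --- temperature / precipitation and derived bioclim surfaces ---------
  set.seed(substream(seed, 2))
  LAT <- matrix(lat, nlat, nlon)
  bio1 <- 29 - 0.35 * (LAT - extent["south"]) - 6.5 * elev / 1000 +
    smooth_field(lon, lat, 8, 0.6)
  coast_dist <- (LAT - extent["south"]) / H
  bio12 <- pmax(15 + 0.22 * elev + 220 * exp(-(coast_dist / 0.25)^2) +
                  smooth_field(lon, lat, 8, 12), 0)
  set.seed(substream(seed, 3))
  amp_warm <- pmax(7 + smooth_field(lon, lat, 6, 1.5), 0.5)
  amp_cold <- pmax(8 + smooth_field(lon, lat, 6, 1.5), 0.5)
  qtr_warm <- pmax(3.5 + smooth_field(lon, lat, 6, 0.8), 0.2)
  qtr_cold <- pmax(4.0 + smooth_field(lon, lat, 6, 0.8), 0.2)
  bio5 <- bio1 + amp_warm
  bio6 <- bio1 - amp_cold
  bio7 <- bio5 - bio6
  bio10 <- bio1 + qtr_warm
  bio11 <- bio1 - qtr_cold
  bio4 <- 100 * (bio10 - bio11) * (1 + 0.1 * smooth_field(lon, lat, 5, 1))
  set.seed(substream(seed, 4))
  f13 <- pmin(pmax(0.25 + 0.05 * smooth_field(lon, lat, 5, 1), 0.05), 0.45)
  bio13 <- f13 * bio12
  bio16 <- pmin(2.5 * bio13, bio12)
  f18 <- pmin(pmax(0.30 + 0.05 * smooth_field(lon, lat, 5, 1), 0.05), 0.9)
  f19 <- pmin(pmax(0.20 + 0.05 * smooth_field(lon, lat, 5, 1), 0.05), 0.9)
  bio18 <- f18 * bio12
  bio19 <- f19 * bio12

  # --- land cover: thresholds on elevation/precipitation + noise --------
  set.seed(substream(seed, 5))
  jp <- smooth_field(lon, lat, 10, 25)
  je <- smooth_field(lon, lat, 10, 120)
  p <- bio12 + jp
  e <- elev + je
  lc <- matrix(8L, nlat, nlon)                      # Bare Areas Sand
  lc[p >= 40 & e >= 300] <- 7L                      # Bare Areas Gravel Rock
  lc[p >= 90 & p < 140] <- 6L                       # Sparse Vegetation
  lc[p >= 140 & p < 180] <- 5L                      # Herbaceous
  lc[p >= 180 & p < 215] <- 4L                      # Shrub
  lc[p >= 215 & e < 350] <- 2L                      # Cropland
  lc[p >= 215 & e >= 350 & e < 700] <- 3L           # Cropland / mosaic
  lc[p >= 215 & e >= 700] <- 1L                     # Tree Open
  urb <- cbind(sample(nlat, 6), sample(nlon, 6))    # a few towns
  lc[urb] <- 9L

  # --- study boundary: irregular seeded blob ---------------------------
  set.seed(substream(seed, 6))
  cx <- extent["west"] + 0.5 * W; cy <- extent["south"] + 0.5 * H
  ang <- seq(0, 2 * pi, length.out = 13)[-13]
  rad <- stats::runif(12, 0.62, 0.92)
  boundary <- polygon_set(tibble::tibble(
    name = "study_area", part = 1L,
    lon = unname(cx + rad * cos(ang) * 0.5 * W),
    lat = unname(cy + rad * sin(ang) * 0.5 * H)
  ))

  # --- administrative regions: longitudinal slabs ----------------------
  edges <- seq(extent["west"], extent["east"], length.out = n_regions + 1)
  regions <- polygon_set(purrr::map_dfr(seq_len(n_regions), function(i) {
    tibble::tibble(name = sprintf("region_%02d", i), part = 1L,
                   lon = unname(c(edges[i], edges[i + 1], edges[i + 1], edges[i])),
                   lat = unname(c(extent["south"], extent["south"],
                                  extent["north"], extent["north"])))
  }))

  # --- protected areas: log-uniform sizes, placed inside the boundary ---
  set.seed(substream(seed, 7))
  b_area <- polygon_area_deg(boundary)$area_deg2
  pas <- NULL
  if (n_protected > 0 && protected_coverage_fraction > 0) {
    raw <- 10^stats::runif(n_protected, -5, 0)
    a_deg <- sort(raw / sum(raw) * protected_coverage_fraction * b_area,
                  decreasing = TRUE)
    placed <- list()
    bboxes <- matrix(numeric(0), 0, 4)
    for (i in seq_len(n_protected)) {
      aspect <- stats::runif(1, 0.5, 2)
      wi <- sqrt(a_deg[i] * aspect); hi <- a_deg[i] / wi
      ok <- FALSE
      for (try in 1:500) {
        x0 <- stats::runif(1, extent["west"], extent["east"] - wi)
        y0 <- stats::runif(1, extent["south"], extent["north"] - hi)
        corners_in <- all(points_in_feature(boundary, "study_area",
                                            c(x0, x0 + wi, x0 + wi, x0),
                                            c(y0, y0, y0 + hi, y0 + hi)))
        overlap <- nrow(bboxes) > 0 &&
          any(x0 < bboxes[, 3] & x0 + wi > bboxes[, 1] &
                y0 < bboxes[, 4] & y0 + hi > bboxes[, 2])
        if (corners_in && !overlap) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("could not place ", n_protected, " protected areas at coverage ",
             protected_coverage_fraction, "; fewer or smaller areas needed")
      }
      bboxes <- rbind(bboxes, c(x0, y0, x0 + wi, y0 + hi))
      placed[[i]] <- tibble::tibble(
        name = sprintf("pa_%02d", i), part = 1L,
        lon = c(x0, x0 + wi, x0 + wi, x0), lat = c(y0, y0, y0 + hi, y0 + hi))
    }
    pas <- polygon_set(dplyr::bind_rows(placed))
  }

  # --- mask all layers to the boundary ---------------------------------
  LON <- matrix(lon, nlat, nlon, byrow = TRUE)
  mask <- matrix(points_in_feature(boundary, "study_area",
                                   as.vector(LON), as.vector(LAT)),
                 nlat, nlon)
  apply_mask <- function(v) { v[!mask] <- NA; v }
  lc <- apply_mask(lc)
  bioclim <- list(BIO1 = bio1, BIO4 = bio4, BIO5 = bio5, BIO6 = bio6,
                  BIO7 = bio7, BIO10 = bio10, BIO11 = bio11, BIO12 = bio12,
                  BIO13 = bio13, BIO16 = bio16, BIO18 = bio18, BIO19 = bio19)
  bioclim <- lapply(bioclim, function(v) mk(apply_mask(v)))

  structure(
    list(seed = seed, extent = extent, resolution = resolution,
         elevation = mk(apply_mask(elev)),
         bioclim = bioclim,
         landcover = mk(apply_mask(lc), kind = "categorical", classes = 1:9),
         boundary = boundary, regions = regions, protected_areas = pas,
         study_mask = mask),
    class = "synthetic_world"
  )
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> seed %d: %d x %d pixels at %g deg, %d study pixels\n",
              x$seed, nrow(x$study_mask), ncol(x$study_mask), x$resolution,
              sum(x$study_mask)))
  cat(sprintf("  %d protected area(s), %d region(s)\n",
              if (is.null(x$protected_areas)) 0 else
                length(ps_names(x$protected_areas)),
              length(ps_names(x$regions))))
  invisible(x)
}

#' Generate niche-driven virtual species and occurrences
#'
#' Every species receives a Gaussian suitability surface in
#' (BIO1, BIO12) climate space — so climate-envelope profiling has a
#' recoverable truth — with its centre anchored at the climate of a
#' randomly chosen study pixel. Species types set the niche breadth and
#' the anchor habitat: montane specialists anchor on high-elevation
#' pixels, desert specialists on hot dry lowland pixels, generalists get
#' niche widths several times the background spread. Occurrences are
#' drawn pixel-wise with probability proportional to suitability times a
#' spatially uneven effort surface (`effort_bias = 0` means uniform
#' effort); record coordinates jitter uniformly inside the pixel, so the
#' occupied pixel set is exactly known. `sampling = "exhaustive"` instead
#' places one record in every pixel of the species' true occupied set
#' (suitability at least `suit_threshold`), the regime under which the
#' pipeline must recover ground truth exactly.
#'
#' Species attributes are Bernoulli draws with configurable prevalences;
#' the defaults (20/101 endemic, 9/101 venomous, 29/101 island) mirror a
#' typical arid-belt reptile fauna.
#'
#' @param world a [generate_world()] world.
#' @param seed integer seed (independent of the world seed).
#' @param n_species number of species.
#' @param records_per_species inclusive range of record counts per
#'   species (random sampling mode).
#' @param effort_bias log-scale amplitude of the spatial effort surface;
#'   0 = uniform effort.
#' @param sampling `"random"` or `"exhaustive"`.
#' @param suit_threshold suitability defining true occupancy.
#' @param prevalences named list of attribute prevalences.
#' @return list with `occurrences` (tibble), `attributes` (tibble), and
#'   `truth` (class `ground_truth`): per-species niche parameters, true
#'   occupied pixels, true AOO areas, true protected percentages, and
#'   true per-cell richness on the 10-arc-minute graticule.
#' @export
generate_species <- function(world, seed = 1, n_species = 30,
                             records_per_species = c(5, 120),
                             effort_bias = 0,
                             sampling = c("random", "exhaustive"),
                             suit_threshold = 0.5,
                             prevalences = list(endemic = 20 / 101,
                                                venomous = 9 / 101,
                                                island = 29 / 101)) {
  sampling <- match.arg(sampling)
  stopifnot(n_species >= 1)
  ref <- world$elevation
  keep <- which(world$study_mask & !is.na(ref$values))
  nr <- nrow(ref$values)
  px <- tibble::tibble(
    row = ((keep - 1) %% nr) + 1L,
    col = ((keep - 1) %/% nr) + 1L
  )
  px <- dplyr::bind_cols(px, raster_centres(ref, px$row, px$col))
  px$elev <- ref$values[keep]
  px$b1 <- world$bioclim$BIO1$values[keep]
  px$b12 <- world$bioclim$BIO12$values[keep]
  s1 <- stats::sd(px$b1); s12 <- stats::sd(px$b12)

  set.seed(substream(seed, 11))
  effort <- if (effort_bias == 0) {
    rep(1, nrow(px))
  } else {
    lonv <- sort(unique(px$lon)); latv <- sort(unique(px$lat), decreasing = TRUE)
    g <- smooth_field(lonv, latv, 10, 1)
    g <- (g - mean(g)) / stats::sd(g)
    gr <- grid_raster(g, west = unname(world$extent["west"]),
                      north = unname(world$extent["north"]),
                      dlon = world$resolution, dlat = world$resolution)
    exp(effort_bias * extract_at_points(gr, px)$value)
  }

  set.seed(substream(seed, 12))
  types <- sample(c("generalist", "montane", "desert", "mesic"), n_species,
                  replace = TRUE, prob = c(0.2, 0.25, 0.3, 0.25))
  hi_elev <- which(px$elev >= stats::quantile(px$elev, 0.8))
  lo_dry <- which(px$elev <= stats::quantile(px$elev, 0.4) &
                    px$b12 <= stats::quantile(px$b12, 0.4))
  wet <- which(px$b12 >= stats::quantile(px$b12, 0.75))

  species <- sprintf("species_%03d", seq_len(n_species))
  occ_list <- list(); truth_list <- list(); occ_px_list <- list()
  for (i in seq_len(n_species)) {
    anchor_pool <- switch(types[i], montane = hi_elev, desert = lo_dry,
                          mesic = wet, seq_len(nrow(px)))
    wfac <- if (types[i] == "generalist") stats::runif(2, 1.5, 3) else
      stats::runif(2, 0.15, 0.5)
    for (attempt in 1:20) {
      a <- sample(anchor_pool, 1)
      c1 <- px$b1[a]; c2 <- px$b12[a]
      suit <- niche_suitability(px$b1, px$b12, c(c1, c2),
                                c(wfac[1] * s1, wfac[2] * s12))
      if (sum(suit) > 1e-9) break
      warning("species ", species[i], ": zero-suitability niche centre resampled")
    }
    if (sampling == "exhaustive") {
      occ_idx <- which(suit >= suit_threshold)
      coords <- px[occ_idx, c("lon", "lat")]
    } else {
      n_rec <- sample(seq(records_per_species[1], records_per_species[2]), 1)
      occ_idx <- sample(nrow(px), n_rec, replace = TRUE,
                        prob = suit * effort)
      coords <- px[occ_idx, c("lon", "lat")]
      coords$lon <- coords$lon + stats::runif(nrow(coords), -0.3, 0.3) *
        world$resolution
      coords$lat <- coords$lat + stats::runif(nrow(coords), -0.3, 0.3) *
        world$resolution
    }
    occ_list[[i]] <- tibble::tibble(species_id = species[i],
                                    lon = coords$lon, lat = coords$lat)
    upx <- dplyr::distinct(px[occ_idx, c("row", "col", "lon", "lat")])
    occ_px_list[[i]] <- dplyr::mutate(upx, species_id = species[i])
    truth_list[[i]] <- tibble::tibble(
      species_id = species[i], type = types[i],
      centre_bio1 = c1, centre_bio12 = c2,
      width_bio1 = wfac[1] * s1, width_bio12 = wfac[2] * s12,
      n_records = nrow(coords)
    )
  }
  occurrences <- dplyr::bind_rows(occ_list)
  occupied <- dplyr::bind_rows(occ_px_list)

  # --- attributes -------------------------------------------------------
  set.seed(substream(seed, 13))
  attributes <- tibble::tibble(
    species_id = species,
    endemic = stats::runif(n_species) < prevalences$endemic,
    venomous = stats::runif(n_species) < prevalences$venomous,
    island = stats::runif(n_species) < prevalences$island,
    described = stats::runif(n_species) < 0.9,
    iucn = sample(iucn_categories, n_species, replace = TRUE,
                  prob = c(32, 5, 32, 26, 1, 5)),
    group = sample(c("gecko", "snake", "agamid", "skink", "lacertid",
                     "varanid", "amphisbaenid"), n_species, replace = TRUE,
                   prob = c(45, 21, 13, 7, 13, 1, 1))
  )

  # --- ground truth computed with the generator's own arithmetic --------
  areas <- pixel_area_km2(occupied$lat, c(world$resolution, world$resolution))
  prot <- if (!is.null(world$protected_areas)) {
    points_in_any(world$protected_areas, occupied$lon, occupied$lat)
  } else {
    rep(FALSE, nrow(occupied))
  }
  per_species <- occupied |>
    dplyr::mutate(area = areas, prot = prot) |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      n_pixels = dplyr::n(),
      aoo_km2 = sum(.data$area),
      protected_km2 = sum(.data$area[.data$prot]),
      .groups = "drop"
    ) |>
    dplyr::mutate(percent_protected = round_half_up(
      100 * .data$protected_km2 / .data$aoo_km2, 2))
  cs <- 10 / 60
  cell_richness <- occupied |>
    dplyr::mutate(cell_lon = floor(.data$lon / cs),
                  cell_lat = floor(.data$lat / cs)) |>
    dplyr::group_by(.data$cell_lon, .data$cell_lat) |>
    dplyr::summarise(richness = dplyr::n_distinct(.data$species_id),
                     .groups = "drop")
  truth <- structure(
    list(niche = dplyr::bind_rows(truth_list),
         occupied = occupied[, c("species_id", "row", "col", "lon", "lat")],
         per_species = per_species,
         cell_richness = cell_richness,
         cell_size_arcmin = 10),
    class = "ground_truth"
  )
  list(occurrences = occurrences, attributes = attributes, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d species, %d occupied pixels, %d occupied cells\n",
              nrow(x$niche), nrow(x$occupied), nrow(x$cell_richness)))
  invisible(x)
}
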