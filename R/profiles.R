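#' Elevation frequency histogram for one species
#'
#' Crosses a species' records with the elevation raster and bins the
#' elevations in fixed-width bins `[0, 100)`, `[100, 200)`, ... metres
#' (a value exactly on a bin edge belongs to the upper bin). Negative
#' elevations, if any, are folded into a single `[min, 0)` bin. Records
#' on nodata pixels are excluded; if all records lack elevation an empty
#' histogram is returned with a warning.
#'
#' @param occ_species occurrence tibble for one species.
#' @param elevation a [grid_raster()] of elevation in metres.
#' @param bin_width bin width in metres (default 100).
#' @return tibble with `bin_lower`, `bin_upper`, `count`; attribute
#'   `n_valid` holds the number of records with valid elevation.
#' @export
elevation_histogram <- function(occ_species, elevation, bin_width = 100) {
  ext <- extract_at_points(elevation, occ_species)
  elev <- ext$value[!ext$excluded]
  if (length(elev) == 0) {
    warning("no records with valid elevation; empty profile")
    out <- tibble::tibble(bin_lower = numeric(0), bin_upper = numeric(0),
                          count = integer(0))
    attr(out, "n_valid") <- 0L
    return(out)
  }
  idx <- floor(elev / bin_width)
  idx[elev < 0] <- -1              # all sub-sea-level records share one bin
  tab <- table(idx)
  lower <- as.numeric(names(tab)) * bin_width
  upper <- lower + bin_width
  if (any(elev < 0)) {
    lower[as.numeric(names(tab)) == -1] <- min(elev)
    upper[as.numeric(names(tab)) == -1] <- 0
  }
  out <- tibble::tibble(bin_lower = lower, bin_upper = upper,
                        count = as.integer(tab)) |>
    dplyr::arrange(.data$bin_lower)
  attr(out, "n_valid") <- length(elev)
  out
}

#' Bivariate climate envelope of a species
#'
#' Positions each record in the two-dimensional climate space spanned by
#' annual mean temperature (BIO1) and annual precipitation (BIO12),
#' together with the background cloud of all study pixels, and summarises
#' the occupied envelope with min/quartiles/max per axis.
#'
#' @param occ_species occurrence tibble for one species.
#' @param bio1,bio12 [grid_raster()] layers.
#' @param background optional tibble of background pixel values
#'   (`BIO1`, `BIO12`); computed from the rasters when `NULL`.
#' @return list with `points` (per-record pairs), `background`, and
#'   `summary` (five-number summary per axis).
#' @export
climate_envelope <- function(occ_species, bio1, bio12, background = NULL) {
  v1 <- extract_at_points(bio1, occ_species)
  v12 <- extract_at_points(bio12, occ_species)
  ok <- !v1$excluded & !v12$excluded
  points <- tibble::tibble(species_id = occ_species$species_id[ok],
                           BIO1 = v1$value[ok], BIO12 = v12$value[ok])
  if (is.null(background)) {
    background <- tibble::tibble(BIO1 = as.vector(bio1$values),
                                 BIO12 = as.vector(bio12$values)) |>
      tidyr::drop_na()
  }
  fivenum_tbl <- function(x, axis) {
    f <- stats::fivenum(x)
    tibble::tibble(axis = axis, min = f[1], q1 = f[2], median = f[3],
                   q3 = f[4], max = f[5])
  }
  list(points = points, background = background,
       summary = dplyr::bind_rows(fivenum_tbl(points$BIO1, "BIO1"),
                                  fivenum_tbl(points$BIO12, "BIO12")))
}

# Exact 1-D squared Euclidean distance transform (lower envelope of
# parabolas). f holds squared distances along the scan line (here 0 at
# class pixels, Inf elsewhere); step is the inter-sample spacing. Infinite
# entries contribute no parabola, so all-Inf lines stay Inf.
dt_1d <- function(f, step) {
  n <- length(f)
  d <- rep(Inf, n)
  fin <- which(is.finite(f))
  if (length(fin) == 0) return(d)
  x <- seq_len(n) * step
  v <- integer(length(fin)); z <- numeric(length(fin) + 1)
  k <- 1; v[1] <- fin[1]; z[1] <- -Inf; z[2] <- Inf
  for (q in fin[-1]) {
    repeat {
      p <- v[k]
      s <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * x[q] - 2 * x[p])
      if (s <= z[k] && k > 1) k <- k - 1 else break
    }
    k <- k + 1; v[k] <- q; z[k] <- s; z[k + 1] <- Inf
  }
  k <- 1
  for (q in seq_len(n)) {
    while (z[k + 1] < x[q]) k <- k + 1
    d[q] <- (x[q] - x[v[k]])^2 + f[v[k]]
  }
  d
}

#' Distance transform to a pixel class
#'
#' Exact Euclidean distance (km) from every pixel centre to the nearest
#' pixel centre of the target class, computed by a separable
#' two-pass parabolic-envelope transform. Distances are metric: pixel
#' spacings are converted to km with an equidistant cylindrical
#' projection (standard parallel at the equator), matching how land-cover
#' distances are conventionally measured in this pipeline.
#'
#' @param r categorical [grid_raster()].
#' @param class_code target class.
#' @return numeric matrix of distances in km (`Inf` if the class is
#'   absent).
#' @export
distance_to_class <- function(r, class_code) {
  kmdeg <- 111.32
  dx <- unname(r$res["dlon"]) * kmdeg
  dy <- unname(r$res["dlat"]) * kmdeg
  f <- matrix(Inf, nrow(r$values), ncol(r$values))
  f[which(r$values == class_code)] <- 0
  if (all(is.infinite(f))) return(f)
  for (j in seq_len(ncol(f))) f[, j] <- dt_1d(f[, j], dy)
  for (i in seq_len(nrow(f))) f[i, ] <- dt_1d(f[i, ], dx)
  sqrt(f)
}

#' Distance transforms for every declared land-cover class
#'
#' @param landcover categorical [grid_raster()].
#' @return named list of distance matrices (km), one per class.
#' @export
class_distance_stack <- function(landcover) {
  stats::setNames(
    lapply(landcover$classes, function(cl) distance_to_class(landcover, cl)),
    as.character(landcover$classes)
  )
}

#' Per-class land-cover distance statistics for one species
#'
#' For each record and each land-cover class, the distance (km, in an
#' equidistant cylindrical projection) from the record's pixel to the
#' nearest pixel of that class; summarised per class as a five-number
#' summary (the boxplot shape). A record sitting on a class has distance
#' zero to it; classes absent from the raster are reported with `n = 0`.
#'
#' @param occ_species occurrence tibble for one species.
#' @param landcover categorical [grid_raster()] with declared classes.
#' @param distances optional precomputed [class_distance_stack()], reused
#'   across species to avoid recomputing the transforms.
#' @return tibble: `class`, `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
landcover_distances <- function(occ_species, landcover, distances = NULL) {
  if (landcover$kind != "categorical") stop("landcover raster must be categorical")
  if (is.null(distances)) distances <- class_distance_stack(landcover)
  rc <- raster_rowcol(landcover, occ_species$lon, occ_species$lat)
  inside <- !is.na(rc$row)
  idx <- cbind(rc$row[inside], rc$col[inside])
  purrr::map_dfr(landcover$classes, function(cl) {
    d <- distances[[as.character(cl)]][idx]
    d <- d[is.finite(d)]
    if (length(d) == 0) {
      return(tibble::tibble(class = cl, n = 0L, min = NA_real_, q1 = NA_real_,
                            median = NA_real_, q3 = NA_real_, max = NA_real_))
    }
    f <- stats::fivenum(d)
    tibble::tibble(class = cl, n = length(d), min = f[1], q1 = f[2],
                   median = f[3], q3 = f[4], max = f[5])
  })
}

#' Full ecological profile of one species
#'
#' Bundles the elevation histogram, BIO1 x BIO12 climate envelope and
#' land-cover distance statistics.
#'
#' @param occ_species occurrence tibble for one species.
#' @param elevation,bio1,bio12,landcover [grid_raster()] layers.
#' @param distances optional precomputed [class_distance_stack()].
#' @return object of class `species_profile`.
#' @export
species_profile <- function(occ_species, elevation, bio1, bio12, landcover,
                            distances = NULL) {
  structure(
    list(species_id = occ_species$species_id[1],
         n_records = nrow(occ_species),
         elevation_hist = elevation_histogram(occ_species, elevation),
         climate = climate_envelope(occ_species, bio1, bio12),
         landcover = landcover_distances(occ_species, landcover, distances)),
    class = "species_profile"
  )
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %s: %d records, %d elevation bins\n",
              x$species_id, x$n_records, nrow(x$elevation_hist)))
  invisible(x)
}
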