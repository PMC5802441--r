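#' Polygon feature sets
#'
#' A `polygon_set` stores named polygon/multipolygon features as a tidy
#' vertex table (`name`, `part`, `lon`, `lat`; WGS84 degrees, one row per
#' ring vertex, rings implicitly closed) together with an optional
#' per-feature attribute table. Containment tests use even-odd ring
#' parity via [mgcv::in.out()], so multi-part features and holes behave
#' as in standard GIS tools.
#'
#' @param vertices data frame with columns `name`, `part`, `lon`, `lat`.
#' @param attributes optional data frame keyed by `name`.
#' @return an object of class `polygon_set`.
#' @export
polygon_set <- function(vertices, attributes = NULL) {
  stopifnot(all(c("name", "part", "lon", "lat") %in% names(vertices)))
  vertices <- tibble::as_tibble(vertices)
  counts <- dplyr::count(vertices, .data$name, .data$part)
  if (any(counts$n < 3)) stop("every polygon ring needs at least 3 vertices")
  if (!is.null(attributes)) {
    attributes <- tibble::as_tibble(attributes)
    stopifnot("name" %in% names(attributes))
    if (anyDuplicated(attributes$name)) stop("feature names must be unique")
  }
  structure(list(vertices = vertices, attributes = attributes),
            class = "polygon_set")
}

#' @export
print.polygon_set <- function(x, ...) {
  cat(sprintf("<polygon_set> %d feature(s): %s\n",
              length(ps_names(x)),
              paste(utils::head(ps_names(x), 5), collapse = ", ")))
  invisible(x)
}

#' Feature names of a polygon set
#' @param ps a `polygon_set`.
#' @export
ps_names <- function(ps) unique(ps$vertices$name)

# ring matrix for one feature, NA rows separating parts (mgcv::in.out layout)
ps_boundary <- function(ps, name) {
  v <- ps$vertices[ps$vertices$name == name, ]
  if (nrow(v) == 0) stop("no feature named '", name, "'")
  parts <- split(v[, c("lon", "lat")], v$part)
  m <- do.call(rbind, lapply(parts, function(p) rbind(as.matrix(p), c(NA, NA))))
  m[-nrow(m), , drop = FALSE]
}

#' Point-in-polygon tests
#'
#' `points_in_feature()` tests containment in one named feature;
#' `points_in_any()` in the union of all features;
#' `first_containing()` returns, per point, the first feature (in table
#' order) containing it, or `NA` — the deterministic tie-break used when
#' assigning records to administrative regions.
#'
#' @param ps a `polygon_set`.
#' @param lon,lat point coordinate vectors, degrees.
#' @param name feature name.
#' @return logical vector, or character vector for `first_containing()`.
#' @export
points_in_feature <- function(ps, name, lon, lat) {
  if (length(lon) == 0) return(logical(0))
  mgcv::in.out(ps_boundary(ps, name), cbind(lon, lat))
}

#' @rdname points_in_feature
#' @export
points_in_any <- function(ps, lon, lat) {
  inside <- rep(FALSE, length(lon))
  for (nm in ps_names(ps)) {
    todo <- !inside
    if (!any(todo)) break
    inside[todo] <- points_in_feature(ps, nm, lon[todo], lat[todo])
  }
  inside
}

#' @rdname points_in_feature
#' @export
first_containing <- function(ps, lon, lat) {
  out <- rep(NA_character_, length(lon))
  for (nm in ps_names(ps)) {
    todo <- is.na(out)
    if (!any(todo)) break
    hit <- points_in_feature(ps, nm, lon[todo], lat[todo])
    out[which(todo)[hit]] <- nm
  }
  out
}

#' Planar polygon areas in degree space
#'
#' Shoelace area summed over a feature's parts (holes are not signed;
#' generated features have no holes). Used for construction bookkeeping in
#' synthetic worlds; physical areas in km² always come from pixel sums via
#' [pixel_area_km2()].
#'
#' @param ps a `polygon_set`.
#' @return tibble with `name`, `area_deg2`.
#' @export
polygon_area_deg <- function(ps) {
  shoelace <- function(x, y) {
    n <- length(x)
    j <- c(n, seq_len(n - 1))
    abs(sum(x[j] * y - x * y[j])) / 2
  }
  ps$vertices |>
    dplyr::group_by(.data$name, .data$part) |>
    dplyr::summarise(a = shoelace(.data$lon, .data$lat), .groups = "drop") |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(area_deg2 = sum(.data$a), .groups = "drop")
}

# --- rectangle / polygon intersection (used to mask grid cells) ----------

# TRUE if segment p1-p2 intersects segment p3-p4 (proper or touching)
segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  (d1 == 0 && on_seg(p3, p4, p1)) || (d2 == 0 && on_seg(p3, p4, p2)) ||
    (d3 == 0 && on_seg(p1, p2, p3)) || (d4 == 0 && on_seg(p1, p2, p4))
}

# TRUE if the rectangle [w,e] x [s,n] intersects any feature of ps
rect_intersects <- function(ps, w, s, e, n) {
  corners <- cbind(c(w, e, e, w), c(s, s, n, n))
  if (any(points_in_any(ps, corners[, 1], corners[, 2]))) return(TRUE)
  v <- ps$vertices
  vin <- v$lon >= w & v$lon <= e & v$lat >= s & v$lat <= n
  if (any(vin)) return(TRUE)
  # remaining case: an edge crossing with no vertex or corner inside
  rect_edges <- list(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  for (key in unique(paste(v$name, v$part))) {
    p <- v[paste(v$name, v$part) == key, ]
    # cheap bbox reject
    if (max(p$lon) < w || min(p$lon) > e || max(p$lat) < s || min(p$lat) > n) next
    np <- nrow(p)
    for (i in seq_len(np)) {
      a <- c(p$lon[i], p$lat[i])
      b <- c(p$lon[i %% np + 1], p$lat[i %% np + 1])
      if (max(a[1], b[1]) < w || min(a[1], b[1]) > e ||
          max(a[2], b[2]) < s || min(a[2], b[2]) > n) next
      for (re in rect_edges) {
        if (segments_cross(a, b, corners[re[1], ], corners[re[2], ])) return(TRUE)
      }
    }
  }
  FALSE
}

#' Read / write polygon sets as CSV vertex tables
#'
#' The on-disk form is the tidy vertex table (`name,part,lon,lat`), with an
#' optional sibling `<stem>_attributes.csv` for the attribute table.
#'
#' @param ps a `polygon_set`.
#' @param path CSV path for the vertex table.
#' @export
write_polygon_set <- function(ps, path) {
  readr::write_csv(ps$vertices, path)
  if (!is.null(ps$attributes)) {
    readr::write_csv(ps$attributes, sub("\\.csv$", "_attributes.csv", path))
  }
  invisible(path)
}

#' @rdname write_polygon_set
#' @export
read_polygon_set <- function(path) {
  v <- readr::read_csv(path, show_col_types = FALSE)
  apath <- sub("\\.csv$", "_attributes.csv", path)
  a <- if (file.exists(apath)) readr::read_csv(apath, show_col_types = FALSE) else NULL
  polygon_set(v, a)
}

#' Rectangle helper
#'
#' Convenience constructor for a single rectangular feature.
#' @param name feature name.
#' @param w,s,e,n rectangle edges, degrees.
#' @export
rect_polygon <- function(name, w, s, e, n) {
  polygon_set(tibble::tibble(name = name, part = 1L,
                             lon = c(w, e, e, w), lat = c(s, s, n, n)))
}
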