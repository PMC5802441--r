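#' Gridded raster surfaces
#'
#' `grid_raster()` builds a lightweight georeferenced raster: a numeric
#' matrix in row-major map order (row 1 is the northernmost row, column 1
#' the westernmost column) plus a geotransform given by the origin (west
#' edge, north edge, decimal degrees WGS84) and the pixel resolution.
#' Missing data are held as `NA` internally; the `nodata` sentinel is only
#' used on disk.
#'
#' Pixel edge ownership is half-open: a point belongs to the pixel whose
#' interval `[west, east) x [south, north)` contains it, so west and south
#' edges are inclusive and shared edges are never double-counted.
#'
#' @param values numeric matrix; `NA` marks missing pixels.
#' @param west,north coordinates of the outer corner of pixel (1,1), degrees.
#' @param dlon,dlat pixel width and height in degrees (both > 0).
#' @param kind `"continuous"` or `"categorical"`.
#' @param nodata sentinel written to disk for `NA` pixels.
#' @param classes for categorical rasters, the declared class codes.
#' @return an object of class `grid_raster`.
#' @export
grid_raster <- function(values, west, north, dlon, dlat,
                        kind = c("continuous", "categorical"),
                        nodata = -9999, classes = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.matrix(values), dlon > 0, dlat > 0)
  if (kind == "categorical") {
    if (is.null(classes)) classes <- sort(unique(stats::na.omit(as.vector(values))))
    bad <- setdiff(unique(stats::na.omit(as.vector(values))), classes)
    if (length(bad) > 0) {
      stop("categorical raster contains undeclared class codes: ",
           paste(bad, collapse = ", "))
    }
  }
  structure(
    list(values = values, origin = c(west = west, north = north),
         res = c(dlon = dlon, dlat = dlat), nodata = nodata,
         kind = kind, classes = classes),
    class = "grid_raster"
  )
}

#' @export
print.grid_raster <- function(x, ...) {
  e <- raster_extent(x)
  cat(sprintf("<grid_raster> %d x %d %s pixels, res %.6g x %.6g deg\n",
              nrow(x$values), ncol(x$values), x$kind, x$res[1], x$res[2]))
  cat(sprintf("  extent: lon [%.4f, %.4f], lat [%.4f, %.4f]\n",
              e["west"], e["east"], e["south"], e["north"]))
  invisible(x)
}

#' Raster extent
#' @param r a `grid_raster`.
#' @return named vector `(west, south, east, north)` in degrees.
#' @export
raster_extent <- function(r) {
  c(west = unname(r$origin["west"]),
    south = unname(r$origin["north"]) - nrow(r$values) * unname(r$res["dlat"]),
    east = unname(r$origin["west"]) + ncol(r$values) * unname(r$res["dlon"]),
    north = unname(r$origin["north"]))
}

#' Map coordinates to pixel row/column indices
#'
#' Half-open edge rule: west and south pixel edges are inclusive, east and
#' north exclusive. Points outside the extent get `NA` indices.
#'
#' @param r a `grid_raster`.
#' @param lon,lat coordinate vectors, degrees.
#' @return tibble with `row`, `col` (`NA` outside the extent).
#' @export
raster_rowcol <- function(r, lon, lat) {
  e <- raster_extent(r)
  col <- floor((lon - e["west"]) / r$res["dlon"]) + 1L
  row <- nrow(r$values) - floor((lat - e["south"]) / r$res["dlat"])
  ok <- lon >= e["west"] & lon < e["east"] & lat >= e["south"] & lat < e["north"]
  col[!ok] <- NA_integer_
  row[!ok] <- NA_integer_
  tibble::tibble(row = as.integer(row), col = as.integer(col))
}

#' Pixel-centre coordinates for row/column indices
#' @param r a `grid_raster`.
#' @param row,col integer index vectors.
#' @return tibble with `lon`, `lat` of pixel centres.
#' @export
raster_centres <- function(r, row, col) {
  tibble::tibble(
    lon = unname(r$origin["west"]) + (col - 0.5) * unname(r$res["dlon"]),
    lat = unname(r$origin["north"]) - (row - 0.5) * unname(r$res["dlat"])
  )
}

#' @method as_tibble grid_raster
#' @export
as_tibble.grid_raster <- function(x, ..., drop_na = TRUE) {
  nr <- nrow(x$values); nc <- ncol(x$values)
  out <- tibble::tibble(
    row = rep(seq_len(nr), times = nc),
    col = rep(seq_len(nc), each = nr),
    value = as.vector(x$values)
  )
  out <- dplyr::bind_cols(out[, c("row", "col")],
                          raster_centres(x, out$row, out$col),
                          value = out$value)
  if (drop_na) out <- out[!is.na(out$value), ]
  out
}

#' Pixel area from latitude and angular resolution
#'
#' Spherical cosine-latitude approximation with 111.32 km per degree:
#' `area = (dlat * 111.32) * (dlon * 111.32 * cos(lat))`, evaluated at the
#' pixel-centre latitude. The error against an ellipsoidal computation is
#' below 0.6% in subtropical latitudes, and the formula is fully
#' deterministic.
#'
#' @param lat pixel-centre latitude, degrees (|lat| < 90).
#' @param res length-2 vector `(dlon, dlat)` in degrees.
#' @return pixel area in square kilometres.
#' @export
pixel_area_km2 <- function(lat, res) {
  stopifnot(all(abs(lat) < 90))
  kmdeg <- 111.32
  res <- unname(res)
  unname((res[2] * kmdeg) * (res[1] * kmdeg * cos(lat * pi / 180)))
}

#' Extract raster values at point locations
#'
#' Each record receives the value of the pixel containing it (half-open
#' edge rule). Records falling outside the extent or on a nodata pixel are
#' flagged `excluded` and carry `NA`.
#'
#' @param r a `grid_raster`.
#' @param points data frame with `lon`, `lat` columns (e.g. an occurrence
#'   table).
#' @return the input with `value` and `excluded` columns appended.
#' @export
extract_at_points <- function(r, points) {
  rc <- raster_rowcol(r, points$lon, points$lat)
  inside <- !is.na(rc$row)
  if (!any(inside)) stop("all points fall outside the raster extent")
  val <- rep(NA_real_, nrow(points))
  val[inside] <- r$values[cbind(rc$row[inside], rc$col[inside])]
  dplyr::mutate(tibble::as_tibble(points),
                value = val, excluded = is.na(val))
}

#' Read / write rasters as ASCII grids
#'
#' Plain-text Esri ASCII grid format (`ncols/nrows/xllcorner/yllcorner`
#' header). Square pixels use the `cellsize` keyword; rectangular pixels
#' the `dx`/`dy` extension. Values are written row-major from the
#' northernmost row, `NA` as the nodata sentinel.
#'
#' @param r a `grid_raster`.
#' @param path file path.
#' @param kind,classes passed to [grid_raster()] on read.
#' @return `write_ascii_grid()` returns `path` invisibly;
#'   `read_ascii_grid()` returns a `grid_raster`.
#' @export
write_ascii_grid <- function(r, path) {
  e <- raster_extent(r)
  hdr <- c(sprintf("ncols %d", ncol(r$values)),
           sprintf("nrows %d", nrow(r$values)),
           sprintf("xllcorner %.10g", e["west"]),
           sprintf("yllcorner %.10g", e["south"]))
  hdr <- c(hdr, if (isTRUE(all.equal(unname(r$res["dlon"]), unname(r$res["dlat"])))) {
    sprintf("cellsize %.10g", r$res["dlon"])
  } else {
    c(sprintf("dx %.10g", r$res["dlon"]), sprintf("dy %.10g", r$res["dlat"]))
  })
  hdr <- c(hdr, sprintf("NODATA_value %.10g", r$nodata))
  v <- r$values
  v[is.na(v)] <- r$nodata
  body <- apply(v, 1L, function(x) paste(format(x, scientific = FALSE, trim = TRUE),
                                         collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, kind = c("continuous", "categorical"),
                            classes = NULL) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1L
  }
  dlon <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dx
  dlat <- if (!is.null(hdr$cellsize)) hdr$cellsize else hdr$dy
  vals <- matrix(scan(text = paste(lines[i:length(lines)], collapse = "\n"),
                      quiet = TRUE),
                 nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  vals[vals == hdr$nodata_value] <- NA
  grid_raster(vals, west = hdr$xllcorner,
              north = hdr$yllcorner + hdr$nrows * dlat,
              dlon = dlon, dlat = dlat, kind = kind,
              nodata = hdr$nodata_value, classes = classes)
}
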