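#' Equal-variance breakpoints in PCA climate space
#'
#' Partitions each retained principal component into bins that each hold a
#' fixed fraction `theta` of the total explained variance, anchored at an
#' origin (default score 0). Each pixel's contribution is its squared
#' score divided by the total squared scores over all retained components,
#' so contributions sum to exactly 1. For each component the pixels are
#' walked outward from the origin separately in the positive and negative
#' directions in score order, accumulating contributions bin by bin; when
#' the running bin reaches `theta` it is closed with a breakpoint at the
#' midpoint between the pixel that completed it and the next pixel
#' outward, and the accumulator restarts, so every closed bin holds
#' `theta` plus at most one pixel's contribution. The outermost partial
#' accumulation forms a final, possibly thin, bin. Because later components explain less variance, the number
#' of bins never increases from one component to the next.
#'
#' @param model a [fit_pca()] model.
#' @param theta variance fraction per bin, in (0, 1] (default 0.10).
#' @param origin score value anchoring the walk on every component
#'   (default 0).
#' @return an object of class `climate_partition`: `theta`, `origin`,
#'   `breakpoints` (list per component, strictly increasing, containing
#'   the origin), `bins_per_component`, and the side shares.
#' @export
equal_variance_breakpoints <- function(model, theta = 0.10, origin = 0) {
  if (!inherits(model, "climate_pca")) stop("model must be a climate_pca")
  if (theta <= 0 || theta > 1) stop("theta must be in (0, 1]")
  comps <- paste0("PC", seq_len(model$retained))
  S <- as.matrix(model$scores[, comps, drop = FALSE])
  total_sq <- sum(S^2)
  eps <- 1e-12

  walk_side <- function(s_out, c_out) {
    # s_out: scores ordered outward from the origin. Accumulate per-bin:
    # once a bin holds >= theta it is closed (breakpoint midway to the next
    # pixel) and the accumulator restarts, so every closed bin carries
    # theta plus at most one pixel's contribution.
    n <- length(s_out)
    if (n == 0) return(list(breaks = numeric(0), share = 0))
    breaks <- numeric(0)
    acc <- 0
    for (i in seq_len(n)) {
      acc <- acc + c_out[i]
      if (acc >= theta - eps && i < n) {
        breaks <- c(breaks, (s_out[i] + s_out[i + 1]) / 2)
        acc <- 0
      }
    }
    list(breaks = breaks, share = sum(c_out))
  }

  breakpoints <- list()
  bins <- integer(model$retained)
  shares <- matrix(0, model$retained, 2, dimnames = list(comps, c("neg", "pos")))
  for (k in seq_len(model$retained)) {
    s <- S[, k]
    contrib <- s^2 / total_sq
    pos <- order(s)[s[order(s)] > origin]
    neg <- order(s, decreasing = TRUE)[s[order(s, decreasing = TRUE)] <= origin]
    wp <- walk_side(s[pos], contrib[pos])
    wn <- walk_side(s[neg], contrib[neg])
    breakpoints[[comps[k]]] <- sort(c(wn$breaks, origin, wp$breaks))
    shares[k, ] <- c(wn$share, wp$share)
    bins[k] <- length(breakpoints[[comps[k]]]) + 1L
  }
  structure(
    list(theta = theta, origin = origin, breakpoints = breakpoints,
         bins_per_component = bins, side_shares = shares,
         components = comps),
    class = "climate_partition"
  )
}

#' @export
print.climate_partition <- function(x, ...) {
  cat(sprintf("<climate_partition> theta = %g, origin = %g; bins per component: %s\n",
              x$theta, x$origin, paste(x$bins_per_component, collapse = " x ")))
  if (!is.null(x$labels)) {
    cat(sprintf("  %d pixels labelled into %d clusters\n",
                nrow(x$labels), prod(x$bins_per_component)))
  }
  invisible(x)
}

#' Assign climatic-cluster labels to study pixels
#'
#' Bins each pixel's score on every retained component with the half-open
#' lower-inclusive rule `[b_j, b_{j+1})`; the outer bins extend to
#' infinity, so scores beyond the outermost breakpoint are clamped into
#' the end bins. Cluster labels number the full bin grid from 1 upward,
#' left-to-right along PC1 and then bottom-to-top along PC2 (label 1 is
#' the bottom-left cell of climate space).
#'
#' @param model a [fit_pca()] model.
#' @param partition a [equal_variance_breakpoints()] partition.
#' @return the partition with a `labels` tibble (`row`, `col`, `lon`,
#'   `lat`, scores, per-component bins, `cluster`), the cluster raster
#'   (`label_raster`), and per-cluster pixel counts and areas.
#' @export
assign_clusters <- function(model, partition) {
  comps <- partition$components
  lab <- model$scores
  for (k in seq_along(comps)) {
    bp <- partition$breakpoints[[comps[k]]]
    lab[[paste0("bin", k)]] <- findInterval(lab[[comps[k]]], bp) + 1L
  }
  n1 <- partition$bins_per_component[1]
  lab$cluster <- lab$bin1
  if (length(comps) >= 2) lab$cluster <- (lab$bin2 - 1L) * n1 + lab$bin1
  vals <- matrix(NA_real_, model$raster_dim[1], model$raster_dim[2])
  vals[cbind(lab$row, lab$col)] <- lab$cluster
  label_raster <- grid_raster(
    vals,
    west = unname(model$raster_template$origin["west"]),
    north = unname(model$raster_template$origin["north"]),
    dlon = unname(model$raster_template$res["dlon"]),
    dlat = unname(model$raster_template$res["dlat"]),
    kind = "categorical", classes = seq_len(prod(partition$bins_per_component))
  )
  partition$labels <- lab
  partition$label_raster <- label_raster
  partition$cluster_areas <- lab |>
    dplyr::mutate(area = pixel_area_km2(.data$lat, model$raster_template$res)) |>
    dplyr::group_by(cluster = .data$cluster) |>
    dplyr::summarise(n_pixels = dplyr::n(), area_km2 = sum(.data$area),
                     .groups = "drop")
  partition
}

#' Sampling coverage of the climatic clusters
#'
#' For every cluster of the partition: the number of distinct species
#' recorded in it, the number of sampled localities (distinct analysis
#' pixels holding at least one record), the percentage of the cluster's
#' pixels sampled (2 decimal places, half-up) and its area in km².
#' Clusters with no records report zeroes.
#'
#' @param occ occurrence tibble.
#' @param partition a labelled partition from [assign_clusters()].
#' @return tibble: `cluster`, `n_species`, `n_localities`, `pct_sampled`,
#'   `area_km2`.
#' @export
cluster_coverage <- function(occ, partition) {
  if (is.null(partition$labels)) stop("partition has no labels; run assign_clusters()")
  r <- partition$label_raster
  ext <- extract_at_points(r, occ)
  rc <- raster_rowcol(r, occ$lon, occ$lat)
  pts <- dplyr::bind_cols(ext, rc) |>
    dplyr::filter(!.data$excluded)
  per_cluster <- pts |>
    dplyr::group_by(cluster = .data$value) |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species_id),
      n_localities = dplyr::n_distinct(paste(.data$row, .data$col)),
      .groups = "drop"
    )
  partition$cluster_areas |>
    dplyr::left_join(per_cluster, by = "cluster") |>
    tidyr::replace_na(list(n_species = 0L, n_localities = 0L)) |>
    dplyr::mutate(
      pct_sampled = percent(.data$n_localities, .data$n_pixels),
      area_km2 = round_half_up(.data$area_km2, 2)
    ) |>
    dplyr::select("cluster", "n_species", "n_localities", "n_pixels",
                  "pct_sampled", "area_km2") |>
    dplyr::arrange(.data$cluster)
}

#' Climatic-cluster representation inside protected areas
#'
#' Labels every protected-area pixel (pixel-centre containment) with its
#' climatic cluster and tallies per-cluster protected pixel counts;
#' clusters with zero protected pixels are reported as unprotected.
#'
#' @param partition a labelled partition from [assign_clusters()].
#' @param pas protected areas as a [polygon_set()].
#' @return tibble: `cluster`, `n_pixels`, `n_protected_pixels`,
#'   `protected` flag.
#' @export
cluster_protection <- function(partition, pas) {
  if (is.null(partition$labels)) stop("partition has no labels; run assign_clusters()")
  lab <- partition$labels
  inside <- points_in_any(pas, lab$lon, lab$lat)
  prot <- lab[inside, ] |>
    dplyr::count(cluster = .data$cluster, name = "n_protected_pixels")
  partition$cluster_areas |>
    dplyr::select("cluster", "n_pixels") |>
    dplyr::left_join(prot, by = "cluster") |>
    tidyr::replace_na(list(n_protected_pixels = 0L)) |>
    dplyr::mutate(protected = .data$n_protected_pixels > 0L) |>
    dplyr::arrange(.data$cluster)
}
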