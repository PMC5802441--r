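#' Half-up rounding
#'
#' Decimal rounding with ties away from zero (0.005 -> 0.01 at 2 dp),
#' the convention used for all printed percentages; base `round()`
#' rounds half to even.
#'
#' @param x numeric vector.
#' @param dp decimal places.
#' @export
round_half_up <- function(x, dp = 2) {
  p <- 10^dp
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Printed-percentage arithmetic
#'
#' `100 * numerator / denominator`, rounded half-up to `dp` decimal
#' places. All percentages reported by the package flow through this one
#' function. A zero denominator yields `NA` with a warning.
#'
#' @param numerator,denominator counts (or areas).
#' @param dp decimal places (default 2).
#' @return percentage on the 0–100 scale.
#' @export
percent <- function(numerator, denominator, dp = 2) {
  out <- rep(NA_real_, length(numerator))
  ok <- denominator > 0
  if (any(!ok)) warning("percent(): zero denominator yields NA")
  out[ok] <- round_half_up(100 * numerator[ok] / denominator[ok], dp)
  out
}

#' The IUCN category vocabulary used by the attribute table
#'
#' `LC*` marks species evaluated as Least Concern but still pending
#' publication in the Red List.
#' @export
iucn_categories <- c("NE", "DD", "LC", "LC*", "NT", "VU")

#' Validate a species attribute table
#'
#' @param attributes data frame with `species_id`, logical `endemic`,
#'   `venomous`, `island`, `described`, `iucn` (from [iucn_categories]),
#'   and `group`.
#' @return validated tibble.
#' @export
validate_attributes <- function(attributes) {
  attributes <- tibble::as_tibble(attributes)
  stopifnot("species_id" %in% names(attributes))
  if ("iucn" %in% names(attributes)) {
    bad <- setdiff(unique(attributes$iucn), iucn_categories)
    if (length(bad) > 0) {
      stop("unknown IUCN category code(s): ", paste(bad, collapse = ", "))
    }
  }
  attributes
}

#' Species richness per spatial unit
#'
#' Distinct species with at least one record per unit — grid cells of a
#' [build_grid()] grid, or polygon features (governorates, protected
#' areas). An optional attribute filter (e.g. endemics only) is applied
#' before counting. For polygon units a record on a shared boundary is
#' assigned to the first containing feature in file order.
#'
#' @param occ occurrence tibble.
#' @param units a `grid_system` or a [polygon_set()].
#' @param attributes optional attribute tibble for filtering.
#' @param filter optional one-sided formula or function on the attribute
#'   rows, e.g. `~ endemic`.
#' @return tibble: `unit` (cell id or feature name), `richness`.
#' @export
richness <- function(occ, units, attributes = NULL, filter = NULL) {
  if (!is.null(filter)) {
    if (is.null(attributes)) stop("an attribute filter needs an attribute table")
    keep_fun <- if (inherits(filter, "formula")) {
      f <- stats::as.formula(filter)
      function(df) rlang::eval_tidy(f[[2]], data = df)
    } else {
      filter
    }
    keep <- attributes$species_id[which(keep_fun(attributes))]
    occ <- occ[occ$species_id %in% keep, ]
  }
  if (inherits(units, "grid_system")) {
    joined <- spatial_join(occ, units)
    out <- joined |>
      dplyr::group_by(unit = .data$cell_id) |>
      dplyr::summarise(richness = dplyr::n_distinct(.data$species_id),
                       .groups = "drop")
  } else if (inherits(units, "polygon_set")) {
    unit <- first_containing(units, occ$lon, occ$lat)
    out <- tibble::tibble(species_id = occ$species_id, unit = unit) |>
      tidyr::drop_na() |>
      dplyr::group_by(.data$unit) |>
      dplyr::summarise(richness = dplyr::n_distinct(.data$species_id),
                       .groups = "drop")
    out <- dplyr::left_join(tibble::tibble(unit = ps_names(units)), out,
                            by = "unit") |>
      tidyr::replace_na(list(richness = 0L))
  } else {
    stop("units must be a grid_system or polygon_set")
  }
  dplyr::arrange(out, .data$unit)
}

#' Species representation inside the protected-area network
#'
#' A species is represented iff at least one of its records falls inside
#' any protected area. Reports counts and percentages overall and per
#' attribute subset (endemic, venomous, threatened = VU).
#'
#' @param occ occurrence tibble.
#' @param attributes attribute tibble (`species_id` plus any of
#'   `endemic`, `venomous`, `iucn`).
#' @param pas protected areas as a [polygon_set()].
#' @return tibble: `subset`, `n_total`, `n_represented`, `pct`.
#' @export
pa_representation <- function(occ, attributes, pas) {
  inside <- points_in_any(pas, occ$lon, occ$lat)
  rep_species <- unique(occ$species_id[inside])
  all_species <- unique(occ$species_id)
  attributes <- validate_attributes(attributes)
  subsets <- list(all = all_species)
  if ("endemic" %in% names(attributes)) {
    subsets$endemic <- intersect(all_species,
                                 attributes$species_id[attributes$endemic %in% TRUE])
  }
  if ("venomous" %in% names(attributes)) {
    subsets$venomous <- intersect(all_species,
                                  attributes$species_id[attributes$venomous %in% TRUE])
  }
  if ("iucn" %in% names(attributes)) {
    subsets$threatened <- intersect(all_species,
                                    attributes$species_id[attributes$iucn %in% "VU"])
  }
  purrr::imap_dfr(subsets, function(sp, nm) {
    tibble::tibble(
      subset = nm, n_total = length(sp),
      n_represented = length(intersect(sp, rep_species)),
      pct = if (length(sp) > 0) percent(length(intersect(sp, rep_species)),
                                        length(sp)) else NA_real_
    )
  })
}

#' Sampling coverage of the analysis grid
#'
#' Counts the grid cells holding at least one record, the corresponding
#' percentage of the study mask, and (when climate layers are supplied)
#' the record and background clouds in BIO1 x BIO12 space for
#' effort-in-climate-space plots.
#'
#' @param occ occurrence tibble.
#' @param grid a [build_grid()] grid.
#' @param bio1,bio12 optional [grid_raster()] layers.
#' @return list with `n_sampled`, `n_cells` (study-mask size),
#'   `pct_sampled`, and optional `climate_points` / `climate_background`.
#' @export
sampling_coverage <- function(occ, grid, bio1 = NULL, bio12 = NULL) {
  joined <- spatial_join(occ, grid)
  in_study <- grid$cells$cell_id[grid$cells$in_study]
  sampled <- intersect(unique(joined$cell_id), in_study)
  out <- list(n_sampled = length(sampled), n_cells = length(in_study),
              pct_sampled = percent(length(sampled), length(in_study)))
  if (!is.null(bio1) && !is.null(bio12)) {
    env <- climate_envelope(occ, bio1, bio12)
    out$climate_points <- env$points
    out$climate_background <- env$background
  }
  out
}

#' IUCN category tallies
#'
#' Counts species per Red List category, overall or within a region
#' scope, with LC and LC* reported separately.
#'
#' @param attributes attribute tibble with `iucn`.
#' @param species_ids optional subset of species defining the scope.
#' @return tibble: `iucn`, `n`, `pct` (of the scope), all categories
#'   present (zero rows included).
#' @export
iucn_tally <- function(attributes, species_ids = NULL) {
  attributes <- validate_attributes(attributes)
  if (!is.null(species_ids)) {
    attributes <- attributes[attributes$species_id %in% species_ids, ]
  }
  tot <- nrow(attributes)
  counts <- attributes |>
    dplyr::count(iucn = factor(.data$iucn, levels = iucn_categories),
                 name = "n", .drop = FALSE) |>
    dplyr::mutate(iucn = as.character(.data$iucn))
  counts$pct <- if (tot > 0) percent(counts$n, rep(tot, nrow(counts))) else NA_real_
  counts
}
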