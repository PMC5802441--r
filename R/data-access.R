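#' The published register of Oman's 22 protected areas
#'
#' Name, management type, area (km²), perimeter (km) and year of
#' establishment for each of the 22 protected areas of Oman, as published
#' by the Ministry of Environment and Climate Affairs. Individual areas
#' span five orders of magnitude (0.04–5,057.49 km²); together they cover
#' 12,916.52 km², 3.91% of the country's ~330,000 km². Used for
#' network-level accounting and as the size template for synthetic
#' protected-area networks.
#'
#' @return tibble with `name`, `management_type`, `area_km2`,
#'   `perimeter_km`, `year`.
#' @export
oman_protected_areas <- function() {
  readr::read_csv(
    system.file("extdata", "oman_protected_areas.csv", package = "gapscape"),
    show_col_types = FALSE
  )
}
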