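template_10x10 <- function() {
  grid_raster(matrix(100, 10, 10), west = 0, north = 10, dlon = 1, dlat = 1)
}

test_that("AOO collapses duplicate records and nests native pixels in blocks", {
  tpl <- template_10x10()
  occ2 <- tibble::tibble(species_id = "sp", lon = c(0.4, 0.6), lat = c(0.5, 0.5))
  a1 <- aoo(occ2, tpl)
  expect_equal(nrow(a1$pixels), 1)
  expect_equal(a1$area_km2, pixel_area_km2(0.5, tpl$res))
  # 4 records in 4 adjacent pixels under one 2x2 block
  occ4 <- tibble::tibble(species_id = "sp",
                         lon = c(0.5, 1.5, 0.5, 1.5), lat = c(0.5, 0.5, 1.5, 1.5))
  a_native <- aoo(occ4, tpl)
  a_block <- aoo(occ4, tpl, block = 2)
  expect_equal(nrow(a_native$pixels), 4)
  expect_equal(nrow(a_block$pixels), 4)
  expect_gte(a_block$area_km2, a_native$area_km2)
  # one record in one pixel occupies a whole block at the coarse resolution
  a_block1 <- aoo(occ2, tpl, block = 2)
  expect_equal(nrow(a_block1$pixels), 4)
  expect_gt(a_block1$area_km2, a1$area_km2)
})

test_that("AOO pixel sets equal brute-force coordinate binning", {
  set.seed(41)
  tpl <- template_10x10()
  occ <- tibble::tibble(species_id = "sp", lon = runif(200, 0, 10),
                        lat = runif(200, 0, 10))
  a <- aoo(occ, tpl)
  oracle <- unique(data.frame(row = 10 - floor(occ$lat),
                              col = floor(occ$lon) + 1))
  expect_equal(nrow(a$pixels), nrow(oracle))
  expect_setequal(paste(a$pixels$row, a$pixels$col),
                  paste(oracle$row, oracle$col))
})

test_that("MCP gives the hull for >= 3 non-collinear points, else a fallback", {
  tri <- tibble::tibble(species_id = "sp", lon = c(0, 1, 0), lat = c(0, 0, 1))
  h <- mcp(tri)
  expect_true(h$ok)
  expect_equal(h$area_deg2, 0.5)
  coll <- tibble::tibble(species_id = "sp", lon = c(0, 1, 2), lat = c(0, 1, 2))
  expect_false(mcp(coll)$ok)
  two <- tri[1:2, ]
  expect_false(mcp(two)$ok)
})

test_that("hull vertices equal the gift-wrapping oracle on 50 random points", {
  set.seed(43)
  occ <- tibble::tibble(species_id = "sp", lon = runif(50), lat = runif(50))
  h <- mcp(occ)
  oracle <- oracle_gift_wrap(occ$lon, occ$lat)
  expect_setequal(paste(h$vertices$lon, h$vertices$lat),
                  paste(oracle[, 1], oracle[, 2]))
})

test_that("EOO on a flat world fills the MCP; elevation filtering excludes mountains", {
  flat <- template_10x10()
  occ <- tibble::tibble(species_id = "sp",
                        lon = c(0.5, 8.5, 0.5), lat = c(0.5, 0.5, 8.5))
  e_flat <- eoo(occ, flat)
  # every pixel whose centre is in the triangle, plus the occupied pixels
  hull <- mcp(occ)
  hp <- polygon_set(tibble::tibble(name = "m", part = 1L,
                                   lon = hull$vertices$lon,
                                   lat = hull$vertices$lat))
  cells <- tidyr::expand_grid(row = 1:10, col = 1:10)
  cc <- raster_centres(flat, cells$row, cells$col)
  expected <- cells[points_in_feature(hp, "m", cc$lon, cc$lat), ]
  expected <- dplyr::distinct(dplyr::bind_rows(expected, aoo(occ, flat)$pixels))
  expect_setequal(paste(e_flat$pixels$row, e_flat$pixels$col),
                  paste(expected$row, expected$col))
  # mountain in the hull's interior: excluded under the observed-range filter
  vals <- matrix(100, 10, 10); vals[7:8, 3:4] <- 3000
  mountain <- grid_raster(vals, west = 0, north = 10, dlon = 1, dlat = 1)
  e_mnt <- eoo(occ, mountain)
  expect_false(any(e_mnt$pixels$row %in% 7:8 & e_mnt$pixels$col %in% 3:4))
  expect_lt(e_mnt$area_km2, e_flat$area_km2)
  expect_equal(e_mnt$elevation_band, c(100, 100))
})

test_that("species with too few points fall back to the occupied-pixel set", {
  tpl <- template_10x10()
  occ <- tibble::tibble(species_id = "sp", lon = c(0.5, 5.5), lat = c(0.5, 5.5))
  e <- eoo(occ, tpl)
  a <- aoo(occ, tpl)
  expect_true(e$fallback_used)
  expect_equal(e$pixels, a$pixels)
  expect_equal(e$area_km2, a$area_km2)
})

test_that("protected fractions hit 0 and 100 at the extremes", {
  tpl <- template_10x10()
  occ <- tibble::tibble(species_id = "sp", lon = c(2.5, 7.5), lat = c(2.5, 7.5))
  a <- aoo(occ, tpl)
  everywhere <- rect_polygon("pa", -1, -1, 11, 11)
  expect_equal(protected_fraction(a, everywhere, tpl)$percent_protected, 100)
  nowhere <- rect_polygon("pa", 20, 20, 21, 21)
  expect_equal(protected_fraction(a, nowhere, tpl)$percent_protected, 0)
  # protection is by pixel-centre containment
  half <- rect_polygon("pa", 0, 0, 5, 5)
  pf <- protected_fraction(a, half, tpl)
  expect_equal(pf$protected_km2, pixel_area_km2(2.5, tpl$res))
  expect_equal(pf$percent_protected,
               round(100 * pf$protected_km2 / pf$area_km2, 2), tolerance = 0.01)
})

test_that("enlarging a protected area never decreases a species' protection", {
  set.seed(47)
  tpl <- template_10x10()
  occ <- tibble::tibble(species_id = "sp", lon = runif(30, 0, 10),
                        lat = runif(30, 0, 10))
  a <- aoo(occ, tpl)
  sizes <- c(2, 4, 6, 8, 10)
  pcts <- sapply(sizes, function(s) {
    protected_fraction(a, rect_polygon("pa", 0, 0, s, s), tpl)$percent_protected
  })
  expect_true(all(diff(pcts) >= 0))
})

test_that("gap report threshold counts and the either-approach union rule", {
  tpl <- template_10x10()
  # engineer species at 0%, ~12.5%, ~20% protection under AOO
  pa <- rect_polygon("pa", 0, 0, 10, 1.5)   # protects lat < 1.5 pixel centres
  occ <- dplyr::bind_rows(
    tibble::tibble(species_id = "zero", lon = runif(8, 0, 10),
                   lat = rep(5.5, 8)),
    tibble::tibble(species_id = "mid",
                   lon = 0.5 + 0:7, lat = c(0.5, rep(5.5, 7))),  # 1/8 = 12.5%
    tibble::tibble(species_id = "high",
                   lon = 0.5 + 0:4, lat = c(0.5, rep(5.5, 4)))   # 1/5 = 20%
  )
  attrs <- tibble::tibble(species_id = c("zero", "mid", "high"),
                          endemic = c(TRUE, FALSE, FALSE))
  rep <- gap_report(occ, attrs, pa, tpl)
  all17 <- rep$counts[rep$counts$scope == "all" & rep$counts$target == 17, ]
  all12 <- rep$counts[rep$counts$scope == "all" & rep$counts$target == 12, ]
  expect_equal(all17$aoo_pass, 1)
  expect_equal(all12$aoo_pass, 2)
  expect_equal(all17$aoo_zero, 1)
  # union rule: either-approach count is at least each single approach
  expect_gte(all17$either_pass, max(all17$aoo_pass, all17$eoo_pass))
  expect_gte(all12$either_pass, max(all12$aoo_pass, all12$eoo_pass))
  # endemic breakdown only counts the endemic species
  end17 <- rep$counts[rep$counts$scope == "endemic" & rep$counts$target == 17, ]
  expect_equal(end17$n_species, 1)
  expect_equal(end17$aoo_pass, 0)
})

test_that("gap counts equal brute-force recomputation from the species table", {
  w <- fixture_world()
  sp <- fixture_species()
  rep <- gap_report(sp$occurrences, sp$attributes, w$protected_areas,
                    w$elevation)
  wide <- tidyr::pivot_wider(
    rep$species[, c("species_id", "method", "percent_protected")],
    names_from = "method", values_from = "percent_protected")
  for (tg in c(17, 12)) {
    row <- rep$counts[rep$counts$scope == "all" & rep$counts$target == tg, ]
    expect_equal(row$aoo_pass, sum(wide$AOO >= tg))
    expect_equal(row$eoo_pass, sum(wide$EOO >= tg))
    expect_equal(row$either_pass, sum(wide$AOO >= tg | wide$EOO >= tg))
  }
  expect_true(all(rep$species$protected_km2 <= rep$species$area_km2 + 1e-9))
  expect_true(all(rep$species$percent_protected >= 0 &
                    rep$species$percent_protected <= 100))
})
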