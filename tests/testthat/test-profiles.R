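test_that("elevation histogram bins records with the upper-edge rule", {
  elev <- grid_raster(matrix(c(50, 150, 250, 100), 1, 4),
                      west = 0, north = 1, dlon = 1, dlat = 1)
  occ <- tibble::tibble(species_id = "sp", lon = c(0.5, 1.5, 2.5),
                        lat = rep(0.5, 3))
  h <- elevation_histogram(occ, elev)
  expect_equal(h$bin_lower, c(0, 100, 200))
  expect_equal(h$count, c(1L, 1L, 1L))
  expect_equal(attr(h, "n_valid"), 3L)
  # record at exactly 100 m belongs to [100, 200)
  occ100 <- tibble::tibble(species_id = "sp", lon = 3.5, lat = 0.5)
  h100 <- elevation_histogram(occ100, elev)
  expect_equal(h100$bin_lower, 100)
  # all-nodata records warn and give an empty profile
  elev_na <- grid_raster(matrix(NA_real_, 1, 1), 0, 1, 1, 1)
  occ_na <- tibble::tibble(species_id = "sp", lon = 0.5, lat = 0.5)
  expect_warning(h0 <- elevation_histogram(occ_na, elev_na), "empty profile")
  expect_equal(nrow(h0), 0)
})

test_that("a montane specialist's elevation mode sits above the domain median", {
  w <- fixture_world()
  ex <- fixture_exhaustive()
  montane <- ex$truth$niche$species_id[ex$truth$niche$type == "montane"]
  skip_if(length(montane) == 0, "no montane species drawn at this seed")
  occ <- ex$occurrences[ex$occurrences$species_id == montane[1], ]
  h <- elevation_histogram(occ, w$elevation)
  mode_elev <- h$bin_lower[which.max(h$count)]
  domain_median <- stats::median(w$elevation$values, na.rm = TRUE)
  expect_gt(mode_elev, domain_median)
})

test_that("climate envelopes cover the background for generalists and degenerate for singletons", {
  w <- fixture_world()
  sp <- fixture_species()
  env_area <- function(pts) {
    if (nrow(unique(pts)) < 3) return(0)
    h <- grDevices::chull(pts[[1]], pts[[2]])
    v <- pts[h, ]
    n <- nrow(v); j <- c(n, seq_len(n - 1))
    abs(sum(v[[1]][j] * v[[2]] - v[[1]] * v[[2]][j])) / 2
  }
  # an effectively infinite niche width samples the background uniformly,
  # so its envelope hull nearly fills the background hull
  px <- as_tibble(w$bioclim$BIO1)
  b1 <- px$value
  b12 <- w$bioclim$BIO12$values[cbind(px$row, px$col)]
  suit <- niche_suitability(b1, b12, centre = c(stats::median(b1),
                                                stats::median(b12)),
                            width = c(1e3 * sd(b1), 1e3 * sd(b12)))
  set.seed(53)
  idx <- sample(length(b1), 200, replace = TRUE, prob = suit)
  occ <- tibble::tibble(species_id = "wide", lon = px$lon[idx],
                        lat = px$lat[idx])
  env <- climate_envelope(occ, w$bioclim$BIO1, w$bioclim$BIO12)
  # scale both axes by the background spread before comparing hull areas
  bg <- env$background
  scale2 <- function(d) tibble::tibble(x = d$BIO1 / sd(bg$BIO1),
                                       y = d$BIO12 / sd(bg$BIO12))
  expect_gte(env_area(scale2(env$points)), 0.8 * env_area(scale2(bg)))
  # envelope quantiles stay within the background range
  expect_gte(min(env$summary$min), min(bg$BIO1, bg$BIO12))
  # single record gives a degenerate min = max summary
  one <- occ[1, ]
  env1 <- climate_envelope(one, w$bioclim$BIO1, w$bioclim$BIO12)
  expect_equal(env1$summary$min, env1$summary$max)
})

test_that("distance transform equals the all-pixel scan on a random raster", {
  set.seed(31)
  vals <- matrix(sample(1:9, 50 * 50, replace = TRUE,
                        prob = c(1, 1, 1, 2, 2, 3, 8, 8, 0.5)), 50, 50)
  r <- grid_raster(vals, west = 10, north = 20, dlon = 0.02, dlat = 0.02,
                   kind = "categorical", classes = 1:9)
  pts <- tibble::tibble(lon = runif(20, 10, 11), lat = runif(20, 19, 20))
  rc <- raster_rowcol(r, pts$lon, pts$lat)
  for (cl in c(1, 5, 7)) {
    d <- distance_to_class(r, cl)
    for (i in seq_len(nrow(pts))) {
      centre <- raster_centres(r, rc$row[i], rc$col[i])
      expect_equal(d[rc$row[i], rc$col[i]],
                   oracle_class_distance(r, cl, centre$lon, centre$lat),
                   tolerance = 1e-9)
    }
  }
})

test_that("land-cover distances are zero on-class and handle absent classes", {
  vals <- matrix(7, 10, 10)
  vals[1, 1] <- 2   # a single cropland pixel in the far northwest
  r <- grid_raster(vals, west = 0, north = 10, dlon = 1, dlat = 1,
                   kind = "categorical", classes = 1:9)
  occ <- tibble::tibble(species_id = "sp", lon = 5.5, lat = 0.5)  # row 10, col 6
  d <- landcover_distances(occ, r)
  expect_equal(d$min[d$class == 7], 0)
  # single-pixel class at a known offset: planar metric distance
  expected <- sqrt((5 * 111.32)^2 + (9 * 111.32)^2)
  expect_equal(d$min[d$class == 2], expected, tolerance = 1e-9)
  # absent classes are reported with n = 0
  expect_equal(d$n[d$class == 1], 0L)
  expect_true(is.na(d$min[d$class == 1]))
})

test_that("every record is at distance zero from its own pixel's class", {
  w <- fixture_world()
  sp <- fixture_species()
  occ <- sp$occurrences[sample(nrow(sp$occurrences), 50), ]
  stack <- class_distance_stack(w$landcover)
  rc <- raster_rowcol(w$landcover, occ$lon, occ$lat)
  for (i in seq_len(nrow(occ))) {
    cl <- w$landcover$values[rc$row[i], rc$col[i]]
    if (is.na(cl)) next
    expect_equal(stack[[as.character(cl)]][rc$row[i], rc$col[i]], 0)
  }
})

test_that("species_profile bundles all three characterisations", {
  w <- fixture_world()
  sp <- fixture_species()
  occ <- sp$occurrences[sp$occurrences$species_id == "species_001", ]
  pr <- species_profile(occ, w$elevation, w$bioclim$BIO1, w$bioclim$BIO12,
                        w$landcover)
  expect_s3_class(pr, "species_profile")
  expect_equal(sum(pr$elevation_hist$count), attr(pr$elevation_hist, "n_valid"))
  expect_equal(nrow(pr$landcover), 9)
  expect_true(all(pr$landcover$min >= 0, na.rm = TRUE))
  # the min over classes of the per-record distance is zero
  expect_equal(min(pr$landcover$min, na.rm = TRUE), 0)
})
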