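test_that("percent reproduces published ratios at two decimals, half-up", {
  expect_equal(percent(20, 101), 19.80)
  expect_equal(percent(21, 101), 20.79)
  expect_equal(percent(429, 1108), 38.72)
  expect_equal(percent(64, 101), 63.37)
  expect_equal(percent(7, 9), 77.78)
  expect_equal(percent(19, 101), 18.81)
  expect_equal(percent(0, 7), 0)
  # half-up at the boundary, where round() would go half-even
  expect_equal(percent(125, 1000, dp = 1), 12.5)
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_warning(expect_true(is.na(percent(1, 0))), "zero denominator")
})

test_that("percent is scale-invariant", {
  for (k in c(2, 5, 10)) {
    expect_equal(percent(20 * k, 101 * k), percent(20, 101))
  }
})

test_that("richness counts distinct species per grid cell", {
  sq <- rect_polygon("study", 0, 0, 1, 1)
  g <- build_grid(sq, cell_size_arcmin = 30)
  occ <- tibble::tibble(species_id = "only",
                        lon = c(0.25, 0.75, 0.25), lat = c(0.25, 0.25, 0.75))
  r <- richness(occ, g)
  expect_equal(nrow(r), 3)
  expect_true(all(r$richness == 1))
})

test_that("attribute filters restrict richness and empty filters give zero", {
  sq <- rect_polygon("study", 0, 0, 1, 1)
  g <- build_grid(sq, cell_size_arcmin = 60)
  occ <- tibble::tibble(species_id = c("a", "b"), lon = c(0.5, 0.5),
                        lat = c(0.5, 0.5))
  attrs <- tibble::tibble(species_id = c("a", "b"), endemic = c(FALSE, FALSE))
  r <- richness(occ, g, attrs, ~endemic)
  expect_equal(nrow(r), 0)
  attrs$endemic[1] <- TRUE
  r2 <- richness(occ, g, attrs, ~endemic)
  expect_equal(r2$richness, 1)
  expect_error(richness(occ, g, filter = ~endemic), "attribute table")
})

test_that("per-region richness equals brute-force nested loops", {
  w <- fixture_world()
  sp <- fixture_species()
  r <- richness(sp$occurrences, w$regions)
  for (nm in ps_names(w$regions)) {
    count <- 0
    for (s in unique(sp$occurrences$species_id)) {
      o <- sp$occurrences[sp$occurrences$species_id == s, ]
      inside <- points_in_feature(w$regions, nm, o$lon, o$lat)
      # replicate the first-containing tie-break for points in earlier regions
      for (prior in ps_names(w$regions)) {
        if (prior == nm) break
        inside <- inside & !points_in_feature(w$regions, prior, o$lon, o$lat)
      }
      if (any(inside)) count <- count + 1
    }
    expect_equal(r$richness[r$unit == nm], count)
  }
})

test_that("protected-area representation counts species with any record inside", {
  w <- fixture_world()
  sp <- fixture_species()
  pr <- pa_representation(sp$occurrences, sp$attributes, w$protected_areas)
  expect_setequal(pr$subset, c("all", "endemic", "venomous", "threatened"))
  # oracle for the overall row
  inside <- points_in_any(w$protected_areas, sp$occurrences$lon,
                          sp$occurrences$lat)
  n_rep <- length(unique(sp$occurrences$species_id[inside]))
  all_row <- pr[pr$subset == "all", ]
  expect_equal(all_row$n_represented, n_rep)
  expect_equal(all_row$pct, percent(n_rep, all_row$n_total))
  # no protected areas at all: zero species represented
  nowhere <- rect_polygon("pa", 100, 80, 101, 81)
  pr0 <- pa_representation(sp$occurrences, sp$attributes, nowhere)
  expect_equal(pr0$n_represented[pr0$subset == "all"], 0)
  expect_equal(pr0$pct[pr0$subset == "all"], 0)
})

test_that("sampling coverage counts occupied study cells", {
  sq <- rect_polygon("study", 0, 0, 1, 1)
  g <- build_grid(sq, cell_size_arcmin = 30)   # 4 cells
  occ <- tibble::tibble(species_id = "a",
                        lon = c(0.25, 0.75, 0.25, 0.75),
                        lat = c(0.25, 0.25, 0.75, 0.75))
  cov <- sampling_coverage(occ, g)
  expect_equal(cov$n_sampled, 4)
  expect_equal(cov$pct_sampled, 100)
  cov1 <- sampling_coverage(occ[1, ], g)
  expect_equal(cov1$pct_sampled, 25)
})

test_that("sampled cells equal the union of the species' cell sets", {
  w <- fixture_world()
  sp <- fixture_species()
  g <- build_grid(w$boundary)
  joined <- spatial_join(sp$occurrences, g)
  per_species_union <- unique(joined$cell_id)
  cov <- sampling_coverage(sp$occurrences, g)
  expect_equal(cov$n_sampled,
               length(intersect(per_species_union,
                                g$cells$cell_id[g$cells$in_study])))
})

test_that("IUCN tallies cover all categories, split LC from LC*, and sum to n", {
  attrs <- tibble::tibble(
    species_id = sprintf("s%02d", 1:12),
    iucn = c(rep("NE", 3), "DD", rep("LC", 4), rep("LC*", 2), "NT", "VU")
  )
  t <- iucn_tally(attrs)
  expect_setequal(t$iucn, iucn_categories)
  expect_equal(sum(t$n), 12)
  expect_equal(t$n[t$iucn == "LC"], 4)
  expect_equal(t$n[t$iucn == "LC*"], 2)
  # scoped tally with no species gives an all-zero table
  t0 <- iucn_tally(attrs, species_ids = character(0))
  expect_true(all(t0$n == 0))
  expect_error(iucn_tally(tibble::tibble(species_id = "x", iucn = "EX")),
               "unknown IUCN")
})
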