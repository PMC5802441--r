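test_that("symmetric two-point-mass scores split into two bins at the origin", {
  m <- fake_pca(tibble::tibble(PC1 = c(-1, -1, 1, 1)))
  p <- equal_variance_breakpoints(m, theta = 0.5)
  expect_equal(p$breakpoints$PC1, 0)
  expect_equal(p$bins_per_component, 2L)
  expect_equal(unname(p$side_shares[1, ]), c(0.5, 0.5))
})

test_that("breakpoints equal the cumulative-sum oracle on random scores", {
  set.seed(17)
  scores <- tibble::tibble(PC1 = rnorm(10000, sd = 2), PC2 = rnorm(10000))
  m <- fake_pca(scores)
  p <- equal_variance_breakpoints(m, theta = 0.1)
  for (k in c("PC1", "PC2")) {
    expect_equal(p$breakpoints[[k]],
                 oracle_breakpoints(scores, k, theta = 0.1))
  }
  # skewed scores and a different theta
  scores2 <- tibble::tibble(PC1 = rexp(5000) - 0.3, PC2 = 0.4 * rnorm(5000))
  p2 <- equal_variance_breakpoints(fake_pca(scores2), theta = 0.07)
  for (k in c("PC1", "PC2")) {
    expect_equal(p2$breakpoints[[k]],
                 oracle_breakpoints(scores2, k, theta = 0.07))
  }
})

test_that("each fully accumulated bin holds theta up to one pixel's contribution", {
  set.seed(23)
  scores <- tibble::tibble(PC1 = rnorm(3000, sd = 1.5), PC2 = rnorm(3000))
  theta <- 0.1
  m <- fake_pca(scores)
  p <- equal_variance_breakpoints(m, theta = theta)
  total <- sum(as.matrix(scores)^2)
  for (k in c("PC1", "PC2")) {
    s <- scores[[k]]
    contrib <- s^2 / total
    bp <- p$breakpoints[[k]]
    edges <- c(-Inf, bp, Inf)
    sums <- sapply(seq_len(length(edges) - 1), function(i) {
      sum(contrib[s >= edges[i] & s < edges[i + 1]])
    })
    expect_equal(sum(sums), sum(contrib), tolerance = 1e-12)
    # interior bins on each side are full bins
    n_neg <- sum(bp < 0)
    full <- setdiff(seq_along(sums), c(1, n_neg + 1, n_neg + 2, length(sums)))
    side_max <- function(i) max(contrib[if (i <= n_neg + 1) s < 0 else s > 0])
    for (i in full) {
      expect_gte(sums[i], theta - 1e-12)
      expect_lt(sums[i], theta + side_max(i))
    }
  }
  # contributions over both components sum to one
  expect_equal(sum(as.matrix(scores)^2 / total), 1, tolerance = 1e-12)
})

test_that("bins per component never increase for later components or larger theta", {
  m <- fixture_pca()
  p <- equal_variance_breakpoints(m, theta = 0.1)
  expect_true(all(diff(p$bins_per_component) <= 0))
  thetas <- c(0.05, 0.1, 0.2, 0.5)
  bins <- sapply(thetas, function(th) {
    equal_variance_breakpoints(m, theta = th)$bins_per_component
  })
  expect_true(all(diff(bins[1, ]) <= 0))
  expect_true(all(diff(bins[2, ]) <= 0))
})

test_that("cluster numbering is row-major from the bottom-left of climate space", {
  m <- fake_pca(tibble::tibble(PC1 = c(-1, 1, -1, 1), PC2 = c(-1, -1, 1, 1)))
  p <- equal_variance_breakpoints(m, theta = 0.5)
  expect_equal(p$bins_per_component, c(2L, 2L))
  lab <- assign_clusters(m, p)$labels
  expect_equal(lab$cluster, c(1L, 2L, 3L, 4L))
})

test_that("label assignment equals a brute-force double loop over breakpoints", {
  m <- fixture_pca()
  p <- fixture_partition()
  lab <- p$labels
  bp1 <- p$breakpoints$PC1; bp2 <- p$breakpoints$PC2
  n1 <- p$bins_per_component[1]
  idx <- sample(nrow(lab), 300)
  for (i in idx) {
    b1 <- sum(lab$PC1[i] >= bp1) + 1L
    b2 <- sum(lab$PC2[i] >= bp2) + 1L
    expect_identical(lab$cluster[i], (b2 - 1L) * n1 + b1)
  }
})

test_that("every study pixel gets exactly one label and areas conserve", {
  m <- fixture_pca()
  p <- fixture_partition()
  expect_equal(nrow(p$labels), m$n_pixels)
  expect_false(any(is.na(p$labels$cluster)))
  expect_equal(sum(p$cluster_areas$n_pixels), m$n_pixels)
  expect_false(any(duplicated(p$labels[, c("row", "col")])))
})

test_that("cluster sampling coverage matches nested-loop recomputation", {
  sp <- fixture_species()
  p <- fixture_partition()
  cov <- cluster_coverage(sp$occurrences, p)
  r <- p$label_raster
  rc <- raster_rowcol(r, sp$occurrences$lon, sp$occurrences$lat)
  lab_at <- r$values[cbind(rc$row, rc$col)]
  for (cl in cov$cluster) {
    in_cl <- which(!is.na(lab_at) & lab_at == cl)
    n_species <- length(unique(sp$occurrences$species_id[in_cl]))
    n_local <- length(unique(paste(rc$row[in_cl], rc$col[in_cl])))
    row <- cov[cov$cluster == cl, ]
    expect_equal(row$n_species, n_species)
    expect_equal(row$n_localities, n_local)
    expect_equal(row$pct_sampled,
                 round(100 * n_local / row$n_pixels * 100) / 100,
                 tolerance = 0.01)
  }
})

test_that("a three-pixel cluster with two sampled localities reports 66.67%", {
  m <- fake_pca(tibble::tibble(PC1 = c(-1, -1.1, -0.9, 2, 2.1, 1.9)))
  p <- assign_clusters(m, equal_variance_breakpoints(m, theta = 0.5))
  # records in two of the three pixels of the first cluster
  pix <- p$labels[p$labels$cluster == p$labels$cluster[1], ][1:2, ]
  occ <- tibble::tibble(species_id = c("a", "b"), lon = pix$lon, lat = pix$lat)
  cov <- cluster_coverage(occ, p)
  row <- cov[cov$n_localities > 0, ]
  expect_equal(row$n_pixels, 3L)
  expect_equal(row$pct_sampled, 66.67)
  empty <- cov[cov$n_localities == 0, ]
  expect_true(all(empty$n_species == 0 & empty$pct_sampled == 0))
})

test_that("protected-area projection reports unprotected clusters as such", {
  w <- fixture_world()
  p <- fixture_partition()
  cp <- cluster_protection(p, w$protected_areas)
  expect_setequal(cp$cluster, p$cluster_areas$cluster)
  # direct label lookup oracle: protected pixel count per cluster
  inside <- points_in_any(w$protected_areas, p$labels$lon, p$labels$lat)
  oracle <- table(p$labels$cluster[inside])
  for (cl in cp$cluster) {
    expect_equal(cp$n_protected_pixels[cp$cluster == cl],
                 if (as.character(cl) %in% names(oracle))
                   unname(oracle[as.character(cl)]) else 0L)
  }
  expect_equal(cp$protected, cp$n_protected_pixels > 0)
  expect_true(any(!cp$protected))   # small PAs leave some clusters uncovered
})
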