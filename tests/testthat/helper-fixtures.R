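# Shared fixtures, built once per test run and cached.
.fixtures <- new.env(parent = emptyenv())

# small synthetic world (60 x 80 pixels) + a niche-driven species set
fixture_world <- function() {
  if (is.null(.fixtures$world)) {
    .fixtures$world <- generate_world(seed = 42, resolution = 0.08)
  }
  .fixtures$world
}

fixture_species <- function() {
  if (is.null(.fixtures$species)) {
    .fixtures$species <- generate_species(fixture_world(), seed = 7,
                                          n_species = 20)
  }
  .fixtures$species
}

# same world sampled exhaustively (every truly occupied pixel holds a record)
fixture_exhaustive <- function() {
  if (is.null(.fixtures$exhaustive)) {
    .fixtures$exhaustive <- generate_species(fixture_world(), seed = 7,
                                             n_species = 12,
                                             sampling = "exhaustive")
  }
  .fixtures$exhaustive
}

fixture_pca <- function() {
  if (is.null(.fixtures$pca)) {
    .fixtures$pca <- fit_pca(fixture_world()$bioclim)
  }
  .fixtures$pca
}

fixture_partition <- function() {
  if (is.null(.fixtures$partition)) {
    .fixtures$partition <- assign_clusters(
      fixture_pca(), equal_variance_breakpoints(fixture_pca()))
  }
  .fixtures$partition
}

# minimal stand-in for a fitted PCA: hand-set scores on a one-column
# raster lattice, for breakpoint and labelling tests
fake_pca <- function(scores, resolution = 0.1, north = 20) {
  n <- nrow(scores)
  structure(
    list(scores = tibble::tibble(row = seq_len(n), col = rep(1L, n),
                                 lon = rep(resolution / 2, n),
                                 lat = north - (seq_len(n) - 0.5) * resolution,
                                 !!!scores),
         retained = ncol(scores),
         raster_template = list(origin = c(west = 0, north = north),
                                res = c(dlon = resolution, dlat = resolution)),
         raster_dim = c(n, 1L)),
    class = "climate_pca"
  )
}

# constant-valued raster helper
const_raster <- function(value, nr = 10, nc = 10, west = 0, north = 10,
                         res = 0.5, kind = "continuous", classes = NULL) {
  grid_raster(matrix(value, nr, nc), west = west, north = north,
              dlon = res, dlat = res, kind = kind, classes = classes)
}
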