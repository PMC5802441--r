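#' The 12 bioclimatic variables used for climate-space analysis
#'
#' Annual mean temperature (BIO1), temperature seasonality (BIO4), max and
#' min temperature of warmest/coldest month (BIO5, BIO6), annual range
#' (BIO7), mean temperature of warmest/coldest quarter (BIO10, BIO11),
#' annual precipitation (BIO12), precipitation of wettest month (BIO13),
#' wettest quarter (BIO16), and warmest/coldest quarter (BIO18, BIO19).
#' The remaining seven bioclim variables are excluded by fixed
#' configuration: in sparsely gauged arid regions their interpolated
#' surfaces show atypical artefacts.
#' @export
bioclim_variables <- c("BIO1", "BIO4", "BIO5", "BIO6", "BIO7", "BIO10",
                       "BIO11", "BIO12", "BIO13", "BIO16", "BIO18", "BIO19")

#' Standardized PCA of the bioclimatic climate space
#'
#' Z-standardizes the 12 bioclim variables over the study-area pixels
#' (mean 0, sd 1) and eigen-decomposes them with [stats::prcomp()].
#' Components are signed so that each column's largest-magnitude loading
#' is positive, which makes runs reproducible regardless of LAPACK sign
#' choices. Per-pixel scores on the retained components are stored for
#' downstream clustering.
#'
#' @param bioclim named list of [grid_raster()] layers; names must cover
#'   `variables`.
#' @param study_mask optional logical matrix (same shape as the rasters);
#'   `TRUE` pixels enter the fit. Default: pixels complete in all layers.
#' @param variables ordered variable list (default [bioclim_variables]).
#' @param retained number of retained components (default 2).
#' @return an object of class `climate_pca`: variables, `means`, `sds`,
#'   `loadings` (variable x component), `eigenvalues`,
#'   `explained_fraction`, `scores` (tibble: `row`, `col`, `lon`, `lat`,
#'   `PC1`, ...), `retained`, `n_pixels`.
#' @export
fit_pca <- function(bioclim, study_mask = NULL,
                    variables = bioclim_variables, retained = 2) {
  missing <- setdiff(variables, names(bioclim))
  if (length(missing) > 0) {
    stop("bioclim stack lacks variable(s): ", paste(missing, collapse = ", "))
  }
  ref <- bioclim[[variables[1]]]
  X <- sapply(variables, function(v) as.vector(bioclim[[v]]$values))
  keep <- stats::complete.cases(X)
  if (!is.null(study_mask)) keep <- keep & as.vector(study_mask)
  if (sum(keep) < length(variables)) {
    stop("need at least ", length(variables), " pixels with complete data")
  }
  X <- X[keep, , drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant variable(s) in study area: ",
         paste(variables[sds == 0], collapse = ", "))
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  # sign convention: dominant loading of each component positive
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  pc$rotation <- sweep(pc$rotation, 2, flip, `*`)
  pc$x <- sweep(pc$x, 2, flip, `*`)
  eig <- pc$sdev^2
  nr <- nrow(ref$values)
  idx <- which(matrix(keep, nrow = nr), arr.ind = TRUE)
  scores <- dplyr::bind_cols(
    tibble::tibble(row = idx[, 1], col = idx[, 2]),
    raster_centres(ref, idx[, 1], idx[, 2]),
    tibble::as_tibble(pc$x[, seq_len(retained), drop = FALSE])
  )
  structure(
    list(variables = variables, means = pc$center, sds = pc$scale,
         loadings = pc$rotation, eigenvalues = eig,
         explained_fraction = eig / sum(eig), scores = scores,
         retained = retained, n_pixels = sum(keep),
         raster_template = ref[c("origin", "res")],
         raster_dim = dim(ref$values)),
    class = "climate_pca"
  )
}

#' @export
print.climate_pca <- function(x, ...) {
  cat(sprintf("<climate_pca> %d variables over %d pixels; %d retained components\n",
              length(x$variables), x$n_pixels, x$retained))
  cat(sprintf("  explained: %s\n",
              paste(sprintf("PC%d %.1f%%", seq_len(x$retained),
                            100 * x$explained_fraction[seq_len(x$retained)]),
                    collapse = ", ")))
  invisible(x)
}

#' Project climate values into a fitted PCA space
#'
#' Standardizes new observations with the model's stored means and
#' standard deviations and multiplies by the loadings — no refit, so
#' projecting the training pixels reproduces their stored scores exactly.
#'
#' @param model a `climate_pca`.
#' @param newdata data frame with one column per model variable.
#' @return tibble of scores on the retained components.
#' @export
project_pca <- function(model, newdata) {
  missing <- setdiff(model$variables, names(newdata))
  if (length(missing) > 0) {
    stop("newdata lacks variable(s): ", paste(missing, collapse = ", "))
  }
  X <- as.matrix(newdata[, model$variables, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$means), 2, model$sds, `/`)
  S <- Z %*% model$loadings[, seq_len(model$retained), drop = FALSE]
  tibble::as_tibble(S)
}

#' @method tidy climate_pca
#' @export
tidy.climate_pca <- function(x, ...) {
  tibble::tibble(
    variable = rep(x$variables, times = ncol(x$loadings)),
    component = rep(colnames(x$loadings), each = length(x$variables)),
    loading = as.vector(x$loadings)
  )
}

#' @method glance climate_pca
#' @export
glance.climate_pca <- function(x, ...) {
  tibble::tibble(
    n_pixels = x$n_pixels,
    n_variables = length(x$variables),
    retained = x$retained,
    eigenvalue_sum = sum(x$eigenvalues),
    explained_retained = sum(x$explained_fraction[seq_len(x$retained)])
  )
}

#' Loadings / eigenvalue summary table
#'
#' The conventional reporting table: loadings of each variable on the
#' retained components, with eigenvalues and percent variance explained.
#'
#' @param model a `climate_pca`.
#' @return tibble, variables as rows plus eigenvalue / explained rows.
#' @export
pca_summary_table <- function(model) {
  k <- seq_len(model$retained)
  L <- model$loadings[, k, drop = FALSE]
  dplyr::bind_rows(
    tibble::as_tibble(L) |> dplyr::mutate(term = model$variables, .before = 1),
    tibble::tibble(term = "eigenvalue",
                   !!!stats::setNames(as.list(model$eigenvalues[k]), colnames(L))),
    tibble::tibble(term = "explained_pct",
                   !!!stats::setNames(as.list(100 * model$explained_fraction[k]),
                                      colnames(L)))
  )
}
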