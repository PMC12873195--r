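#' Configuration of the classical preprocessing stages
#'
#' @param scale_range Target intensity range of the normalisation step,
#'   strictly increasing (default `[0.01, 1]`).
#' @param filter_kernel_voxels Odd box-filter kernel size per axis (voxels).
#' @param gmm_components Number of mixture components (>= 2; the foreground
#'   stage uses a 2-component mixture).
#' @param min_component_voxels Connected components smaller than this are
#'   removed.
#' @param max_gmm_sample Maximum number of voxels used to fit the mixture
#'   (random subsample under `seed` for determinism and speed).
#' @param seed Integer seed.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(scale_range = c(0.01, 1),
                              filter_kernel_voxels = c(3L, 3L, 3L),
                              gmm_components = 2L,
                              min_component_voxels = 64L,
                              max_gmm_sample = 2e5,
                              seed = 1L) {
  if (length(scale_range) != 2L || diff(scale_range) <= 0)
    stop("`scale_range` must be strictly increasing")
  filter_kernel_voxels <- as.integer(filter_kernel_voxels)
  if (length(filter_kernel_voxels) == 1L)
    filter_kernel_voxels <- rep(filter_kernel_voxels, 3L)
  if (any(filter_kernel_voxels %% 2L == 0L) || any(filter_kernel_voxels < 1L))
    stop("`filter_kernel_voxels` must be odd positive integers")
  if (gmm_components < 2L) stop("`gmm_components` must be >= 2")
  if (min_component_voxels < 1L) stop("`min_component_voxels` must be >= 1")
  structure(list(scale_range = as.numeric(scale_range),
                 filter_kernel_voxels = filter_kernel_voxels,
                 gmm_components = as.integer(gmm_components),
                 min_component_voxels = as.integer(min_component_voxels),
                 max_gmm_sample = max_gmm_sample,
                 seed = as.integer(seed)),
            class = "preprocess_config")
}

#' Intensity normalisation and noise reduction
#'
#' Rescales the signal linearly onto `cfg$scale_range` (default
#' `[0.01, 1]`), then applies a normalized box-average filter of the
#' configured kernel size. A constant input cannot be rescaled and is mapped
#' entirely to the lower bound, with a warning.
#'
#' @param vol An [intensity_volume()].
#' @param cfg A [preprocess_config()].
#' @return The preprocessed [intensity_volume()].
#' @export
preprocess_intensity <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "intensity_volume"))
  g <- vol$grid
  rng <- range(g)
  lo <- cfg$scale_range[1]; hi <- cfg$scale_range[2]
  if (diff(rng) == 0) {
    warning("constant intensity volume: mapping all voxels to the lower bound")
    g[] <- lo
  } else {
    g <- lo + (g - rng[1]) / diff(rng) * (hi - lo)
  }
  dims <- dim(g)
  g <- array(box_filter_cpp(as.numeric(g), as.integer(dims),
                            cfg$filter_kernel_voxels), dims)
  intensity_volume(g, vol$spacing_mm, vol$channel)
}

#' Foreground extraction by Gaussian mixture and connected components
#'
#' Fits a 2-component univariate Gaussian mixture to the voxel intensities
#' (on a random subsample of at most `cfg$max_gmm_sample` voxels, fixed
#' seed), classifies the component with the higher mean as foreground, and
#' removes connected components smaller than `cfg$min_component_voxels`
#' (26-connectivity). Deterministic under `cfg$seed`.
#'
#' @param vol A preprocessed [intensity_volume()].
#' @param cfg A [preprocess_config()].
#' @return A binary [label_volume()] (codes 0 background, 1 foreground).
#' @importFrom mclust Mclust mclustBIC
#' @export
foreground_gmm <- function(vol, cfg = preprocess_config()) {
  stopifnot(inherits(vol, "intensity_volume"))
  vals <- as.vector(vol$grid)
  if (stats::sd(vals) < 1e-8) stop("degenerate mixture: intensities have no spread")
  fit <- with_seed(cfg$seed, {
    idx <- if (length(vals) > cfg$max_gmm_sample)
      sample.int(length(vals), cfg$max_gmm_sample) else seq_along(vals)
    mclust::Mclust(vals[idx], G = 2, modelNames = "V", verbose = FALSE)
  })
  if (is.null(fit)) stop("degenerate mixture: mixture fit failed")
  pro <- fit$parameters$pro
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1L) sdv <- rep(sdv, 2L)
  if (min(pro) < 1e-3 || abs(diff(mu)) < 1e-6 * max(diff(range(vals)), 1e-12))
    stop("degenerate mixture: vanishing weight or equal component means")
  hi <- which.max(mu); lo <- 3L - hi
  p_hi <- pro[hi] * stats::dnorm(vals, mu[hi], sdv[hi])
  p_lo <- pro[lo] * stats::dnorm(vals, mu[lo], sdv[lo])
  fg <- array(as.integer(p_hi > p_lo), dim = dim(vol$grid))
  mask <- label_volume(fg, vol$spacing_mm, binary_label_map())
  largest_components(mask, cfg$min_component_voxels)
}

#' Connected-component cleanup of label masks
#'
#' For each non-background label independently, removes connected components
#' (26-connectivity in 3-D) smaller than `min_component_voxels`; if `keep_k`
#' is given, only the `keep_k` largest surviving components are retained.
#' The output mask is always a subset of the input mask (voxel counts never
#' increase) and the operation is idempotent.
#'
#' @param mask A [label_volume()].
#' @param min_component_voxels Minimum component size in voxels.
#' @param keep_k Optional number of largest components to keep per label.
#' @return The cleaned [label_volume()].
#' @export
largest_components <- function(mask, min_component_voxels, keep_k = NULL) {
  stopifnot(inherits(mask, "label_volume"))
  dims <- dim(mask$grid)
  grid <- mask$grid
  for (code in setdiff(unique(as.vector(grid)), 0L)) {
    m <- grid == code
    lab <- label_components_cpp(as.vector(m), as.integer(dims), 26L)
    if (!any(lab > 0L)) next
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_component_voxels)
    if (!is.null(keep_k) && length(keep) > keep_k)
      keep <- keep[order(sizes[keep], decreasing = TRUE)[seq_len(keep_k)]]
    drop <- m & !array(lab %in% keep, dims)
    grid[drop] <- 0L
  }
  label_volume(grid, mask$spacing_mm, mask$label_map)
}
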