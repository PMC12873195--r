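compartment_measures <- function(rp_volume_cm3, rsf_volume_cm3, side, method) {
  ratio <- if (rp_volume_cm3 > 0) rsf_volume_cm3 / rp_volume_cm3 else NA_real_
  structure(data.frame(rp_volume_cm3 = rp_volume_cm3,
                       rsf_volume_cm3 = rsf_volume_cm3,
                       rsf_rp_ratio = ratio,
                       side = side, method = method,
                       stringsAsFactors = FALSE),
            class = c("compartment_measures", "data.frame"))
}

#' Assign kidney sides to an unsided or partially labelled volume
#'
#' Computes the connected components (26-connectivity) of the combined
#' kidney tissue (RP and RSF); the two largest components are taken as the
#' kidneys and sided by the position of their centroids along the
#' right-left axis (increasing index = subject left). Any smaller satellite
#' component is assigned to the side of the nearest kidney centroid. If the
#' kidney tissue forms a single connected component, the volume is split at
#' the grid midplane with a warning.
#'
#' @param vol A [label_volume()] containing RP voxels.
#' @return A sided [label_volume()] using the [default_label_map()] codes.
#' @export
split_left_right <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  if (!any(compartment_mask(vol, "RP"))) stop("volume contains no RP voxels")
  dims <- dim(vol$grid)
  kidney <- compartment_mask(vol, "kidney")
  rsf <- compartment_mask(vol, "RSF")
  lab <- array(label_components_cpp(as.vector(kidney), as.integer(dims), 26L),
               dims)
  ncomp <- max(lab)
  is_left <- array(FALSE, dims)
  if (ncomp == 1L) {
    warning("single connected kidney component: falling back to a midline split")
    ix <- slice.index(lab, 1L)
    is_left[kidney] <- ix[kidney] > dims[1] / 2
  } else {
    sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
    main <- order(sizes, decreasing = TRUE)[1:2]
    centroid <- function(comp) {
      w <- which(lab == comp)
      i0 <- w - 1L
      c(mean(i0 %% dims[1]) + 1,
        mean((i0 %/% dims[1]) %% dims[2]) + 1,
        mean(i0 %/% (dims[1] * dims[2])) + 1) * vol$spacing_mm
    }
    cents <- vapply(seq_len(ncomp), centroid, numeric(3))
    left_main <- main[which.max(cents[1, main])]
    side_of <- vapply(seq_len(ncomp), function(comp) {
      if (comp %in% main) return(comp == left_main)
      d <- colSums((cents[, main, drop = FALSE] - cents[, comp])^2)
      main[which.min(d)] == left_main
    }, logical(1))
    is_left[kidney] <- side_of[lab[kidney]]
  }
  grid <- array(0L, dims)
  grid[kidney] <- ifelse(is_left[kidney], 2L, 1L)
  grid[rsf] <- ifelse(is_left[rsf], 4L, 3L)
  label_volume(grid, vol$spacing_mm, default_label_map())
}

#' Whole-kidney compartment volumes
#'
#' Volumes are the voxel counts of each compartment summed across all axial
#' slices, times the voxel volume, reported in cm^3; the RSF-RP ratio is the
#' RSF volume divided by the RP volume (undefined, `NA`, when no RP is
#' present).
#'
#' @param vol A [label_volume()].
#' @param side `"left"`, `"right"` or `"both"`.
#' @return A one-row `compartment_measures` data frame
#'   (method `"whole_kidney"`).
#' @export
compartment_volumes <- function(vol, side = "both") {
  stopifnot(inherits(vol, "label_volume"))
  vv <- voxel_volume_mm3(vol) / 1000
  rp <- sum(compartment_mask(vol, "RP", side)) * vv
  rsf <- sum(compartment_mask(vol, "RSF", side)) * vv
  compartment_measures(rp, rsf, side, "whole_kidney")
}

#' Single-slice compartment estimates
#'
#' For each kidney independently, selects the axial slice with the largest
#' total (RP + RSF) cross-sectional area — the conventional renal-pelvis
#' level — and measures RP and RSF on that same slice. Areas are stored as
#' area x slice-thickness pseudo-volumes (cm^3) so that the RSF-RP ratio is
#' comparable with the whole-kidney ratio; the two sides are summed before
#' the ratio is formed. An empty side contributes zero with a warning.
#'
#' @param vol A sided [label_volume()].
#' @return A one-row `compartment_measures` data frame
#'   (method `"single_slice"`), with the chosen slice indices in the
#'   `"slices"` attribute.
#' @export
single_slice_measures <- function(vol) {
  stopifnot(inherits(vol, "label_volume"))
  vv <- voxel_volume_mm3(vol) / 1000
  rp_tot <- 0; rsf_tot <- 0
  slices <- c(left = NA_integer_, right = NA_integer_)
  for (s in c("left", "right")) {
    tot <- slice_areas(vol, c("RP", "RSF"), s)
    if (!any(tot > 0)) {
      warning(sprintf("no kidney tissue on the %s side: contributes 0", s))
      next
    }
    k <- which.max(tot)
    slices[s] <- k
    rp_tot <- rp_tot + sum(vol$grid[, , k] %in% codes_for(vol, "RP", s)) * vv
    rsf_tot <- rsf_tot + sum(vol$grid[, , k] %in% codes_for(vol, "RSF", s)) * vv
  }
  out <- compartment_measures(rp_tot, rsf_tot, "both", "single_slice")
  attr(out, "slices") <- slices
  out
}

#' Percentage difference between two method values
#'
#' `(reference - comparison) / comparison * 100`. With the whole-kidney
#' value as reference and the single-slice value as comparison this is
#' negative when the single-slice method overestimates. Cohort summaries
#' average per-subject percentage differences, not the difference of means.
#'
#' @param reference_method_value,comparison_method_value Numeric vectors.
#' @return Numeric vector of percentage differences; `NA` where the
#'   comparison value is zero.
#' @export
percent_difference <- function(reference_method_value, comparison_method_value) {
  out <- (reference_method_value - comparison_method_value) /
    comparison_method_value * 100
  out[comparison_method_value == 0] <- NA_real_
  out
}
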