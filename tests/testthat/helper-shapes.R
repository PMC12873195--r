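# Geometric fixtures built in code.

# Logical 3-D mask of an axis-aligned ellipsoid digitized at voxel centres,
# centred in a grid that encloses it with `margin` voxels on each side.
digitize_ellipsoid <- function(semi_axes_mm, spacing_mm, margin = 3L) {
  dims <- as.integer(ceiling(2 * semi_axes_mm / spacing_mm) + 2L * margin)
  ctr <- dims * spacing_mm / 2
  xs <- (seq_len(dims[1]) - 0.5) * spacing_mm[1] - ctr[1]
  ys <- (seq_len(dims[2]) - 0.5) * spacing_mm[2] - ctr[2]
  zs <- (seq_len(dims[3]) - 0.5) * spacing_mm[3] - ctr[3]
  m <- outer(outer((xs / semi_axes_mm[1])^2, (ys / semi_axes_mm[2])^2, "+"),
             (zs / semi_axes_mm[3])^2, "+")
  m <= 1
}

# Sided label volume holding one cylindrical "kidney" per side with a
# constant cross-section and a fixed per-slice RSF fraction; z extent in
# slices [z1, z2].
make_cylinder_pair <- function(dims = c(40L, 24L, 30L), spacing = c(2, 2, 2),
                               radius_vox = 6, rsf_radius_vox = 3,
                               z1 = 6L, z2 = 25L) {
  grid <- array(0L, dims)
  centres <- list(right = dims[1] / 4, left = 3 * dims[1] / 4)
  for (s in names(centres)) {
    cx <- centres[[s]]; cy <- dims[2] / 2
    d2 <- outer((seq_len(dims[1]) - cx)^2, (seq_len(dims[2]) - cy)^2, "+")
    rp_code <- if (s == "left") 2L else 1L
    rsf_code <- if (s == "left") 4L else 3L
    sl <- matrix(0L, dims[1], dims[2])
    sl[d2 <= radius_vox^2] <- rp_code
    if (rsf_radius_vox > 0) sl[d2 <= rsf_radius_vox^2] <- rsf_code
    for (k in z1:z2) grid[, , k][sl > 0L] <- sl[sl > 0L]
  }
  label_volume(grid, spacing)
}

# Small phantom parameters for fast tests.
small_phantom_params <- function(...) {
  phantom_params(grid_shape = c(48L, 32L, 40L), spacing_mm = c(2, 2, 2),
                 kidney_halfaxes_mm = c(12, 16, 30), kidney_gap_mm = 16,
                 ...)
}

small_cohort_spec <- function(...) {
  cohort_spec(base_params = small_phantom_params(), ...)
}

# Brute-force confusion counts, voxel by voxel in an explicit loop-free but
# independent formulation (arithmetic on 0/1 vectors).
brute_confusion <- function(pred_mask, ref_mask) {
  p <- as.integer(pred_mask); r <- as.integer(ref_mask)
  c(tp = sum(p * r), fp = sum(p * (1 - r)), fn = sum((1 - p) * r),
    tn = sum((1 - p) * (1 - r)))
}
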