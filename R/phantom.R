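#' Parameters of the synthetic kidney phantom
#'
#' The phantom places two superellipsoid kidney bodies (renal parenchyma, RP)
#' symmetrically about the midline, each enclosing an interior renal sinus
#' fat (RSF) region anchored at the hilum (the medial, mid-craniocaudal
#' aspect of the kidney). The craniocaudal RSF distribution is governed by a
#' Gaussian kernel whose sharpness is `hilum_concentration`; the total RSF
#' burden is calibrated to `target_rsf_rp_ratio` and split between the
#' kidneys according to `left_right_rsf_factor`.
#'
#' @param grid_shape Integer length-3 grid size in voxels
#'   (right-left, anterior-posterior, inferior-superior).
#' @param spacing_mm Voxel spacing in mm.
#' @param kidney_halfaxes_mm Superellipsoid half-axes (mm) of each kidney
#'   along the three axes.
#' @param target_rsf_rp_ratio Target whole-volume RSF/RP volume ratio,
#'   in (0, 0.5).
#' @param hilum_concentration Craniocaudal concentration of RSF: 0 gives a
#'   constant per-slice RSF fraction; larger values concentrate RSF near the
#'   hilum slice (per-slice weight `exp(-hilum_concentration * (z/c)^2)`).
#' @param left_right_rsf_factor Expected left/right RSF volume ratio (> 0).
#' @param intensity_snr If non-`NULL`, paired water/fat intensity channels
#'   are generated with Gaussian noise of standard deviation
#'   (peak tissue signal)/`intensity_snr`.
#' @param seed Integer seed; the phantom is a pure function of
#'   (parameters, seed).
#' @param kidney_gap_mm Distance between the medial kidney surfaces (mm).
#' @param shell_fraction Relative superellipsoid radius enclosing the region
#'   eligible for RSF; the remaining outer shell is always RP.
#' @param superellipse_exponent Superellipsoid shape exponent (2 = ellipsoid).
#' @return An object of class `phantom_params`.
#' @export
phantom_params <- function(grid_shape = c(80L, 48L, 64L),
                           spacing_mm = c(1.5, 1.5, 2),
                           kidney_halfaxes_mm = c(20, 28, 52),
                           target_rsf_rp_ratio = 0.10,
                           hilum_concentration = 4,
                           left_right_rsf_factor = 1.3,
                           intensity_snr = NULL,
                           seed = 1L,
                           kidney_gap_mm = 24,
                           shell_fraction = 0.85,
                           superellipse_exponent = 2.5) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 8L))
    stop("`grid_shape` must be three integers >= 8")
  if (length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three positive reals")
  if (length(kidney_halfaxes_mm) != 3L || any(kidney_halfaxes_mm <= 0))
    stop("`kidney_halfaxes_mm` must be three positive reals")
  if (!(target_rsf_rp_ratio > 0 && target_rsf_rp_ratio < 0.5))
    stop("`target_rsf_rp_ratio` must lie in (0, 0.5)")
  if (hilum_concentration < 0) stop("`hilum_concentration` must be >= 0")
  if (left_right_rsf_factor <= 0) stop("`left_right_rsf_factor` must be > 0")
  if (!is.null(intensity_snr) && intensity_snr <= 0)
    stop("`intensity_snr` must be > 0")
  if (shell_fraction <= 0 || shell_fraction >= 1)
    stop("`shell_fraction` must lie in (0, 1)")

  a <- kidney_halfaxes_mm[1]; b <- kidney_halfaxes_mm[2]; c3 <- kidney_halfaxes_mm[3]
  half <- grid_shape * spacing_mm / 2
  margin <- 2 * spacing_mm
  if (kidney_gap_mm / 2 + 2 * a + margin[1] > half[1] ||
      b + margin[2] > half[2] || c3 + margin[3] > half[3])
    stop("kidneys do not fit inside the grid with a 2-voxel margin")

  # coarse attainability check: the RSF-eligible core is ~shell_fraction^3 of
  # each kidney; the more loaded kidney must fit its share with headroom
  f <- left_right_rsf_factor
  need <- target_rsf_rp_ratio / (1 + target_rsf_rp_ratio) *
    2 * max(f, 1) / (1 + f)
  if (need > 0.9 * shell_fraction^3)
    stop("kidney geometry infeasible for requested RSF-RP ratio and ",
         "left/right factor")

  structure(list(grid_shape = grid_shape, spacing_mm = as.numeric(spacing_mm),
                 kidney_halfaxes_mm = as.numeric(kidney_halfaxes_mm),
                 target_rsf_rp_ratio = target_rsf_rp_ratio,
                 hilum_concentration = hilum_concentration,
                 left_right_rsf_factor = left_right_rsf_factor,
                 intensity_snr = intensity_snr,
                 seed = as.integer(seed),
                 kidney_gap_mm = kidney_gap_mm,
                 shell_fraction = shell_fraction,
                 superellipse_exponent = superellipse_exponent),
            class = "phantom_params")
}

# Integer per-slice quotas proportional to `weight`, bounded by `cap`,
# summing to `total`; largest-remainder rounding.
allocate_slice_quota <- function(weight, cap, total) {
  if (total > sum(cap))
    stop("kidney geometry infeasible for requested RSF-RP ratio")
  alloc <- numeric(length(weight))
  remaining <- total
  repeat {
    room <- cap - alloc
    active <- room > 1e-12 & weight > 0
    if (remaining <= 1e-9) break
    if (!any(active)) active <- room > 1e-12
    w <- if (any(weight[active] > 0)) weight[active] else rep(1, sum(active))
    add <- pmin(room[active], remaining * w / sum(w))
    alloc[active] <- alloc[active] + add
    remaining <- remaining - sum(add)
    if (sum(add) <= 1e-12) break
  }
  k <- floor(alloc + 1e-9)
  deficit <- round(total - sum(k))
  while (deficit > 0) {
    room <- cap - k
    cand <- which(room > 0)
    if (!length(cand))
      stop("kidney geometry infeasible for requested RSF-RP ratio")
    frac <- alloc - k
    take <- cand[order(frac[cand], weight[cand], decreasing = TRUE)]
    take <- take[seq_len(min(deficit, length(take)))]
    k[take] <- k[take] + 1L
    deficit <- deficit - length(take)
  }
  as.integer(k)
}

#' Generate a synthetic two-kidney phantom
#'
#' Builds a sided [label_volume()] containing two kidney bodies (RP shells
#' with interior RSF) whose realized RSF-RP ratio matches
#' `target_rsf_rp_ratio` up to voxel rounding, with the left/right RSF split
#' set by `left_right_rsf_factor` and the craniocaudal RSF profile peaked at
#' the hilum slice for `hilum_concentration > 0`. Optionally generates paired
#' water/fat intensity channels (RP bright in water, RSF bright in fat) with
#' Gaussian noise. Identical parameters and seed give bit-identical output.
#'
#' @param params A [phantom_params()] object.
#' @return An object of class `kidney_phantom`: a list with elements
#'   `labels` (a sided [label_volume()]; attribute `"hilum_slice"` marks the
#'   hilum slice index), and `water`/`fat` ([intensity_volume()] or `NULL`).
#' @export
generate_phantom <- function(params) {
  if (!inherits(params, "phantom_params"))
    params <- do.call(phantom_params, params)
  p <- params
  with_seed(p$seed, {
    dims <- p$grid_shape; sp <- p$spacing_mm
    nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
    xs <- (seq_len(nx) - 0.5) * sp[1] - nx * sp[1] / 2
    ys <- (seq_len(ny) - 0.5) * sp[2] - ny * sp[2] / 2
    zs <- (seq_len(nz) - 0.5) * sp[3] - nz * sp[3] / 2
    a <- p$kidney_halfaxes_mm[1]; b <- p$kidney_halfaxes_mm[2]
    cc <- p$kidney_halfaxes_mm[3]
    e <- p$superellipse_exponent
    cx0 <- p$kidney_gap_mm / 2 + a

    sides <- list(right = -1, left = +1)
    kid <- lapply(sides, function(sgn) {
      cx <- sgn * cx0
      mx <- (abs(xs - cx) / a)^e
      my <- (abs(ys) / b)^e
      mz <- (abs(zs) / cc)^e
      M <- outer(outer(mx, my, "+"), mz, "+")
      # RSF eligibility is judged in-plane, per slice: the fat may occupy the
      # inner shell_fraction of each axial cross-section, leaving an RP rim on
      # every slice; a 3-D criterion would exclude the polar slices entirely
      # and skew the craniocaudal fat distribution even at concentration 0
      thr_z <- p$shell_fraction^e + mz * (1 - p$shell_fraction^e)
      list(mask = M <= 1, elig = sweep(M, 3L, thr_z, FUN = "<="),
           cx = cx, sgn = sgn)
    })
    n_right <- sum(kid$right$mask); n_left <- sum(kid$left$mask)
    n_tot <- n_right + n_left

    t <- p$target_rsf_rp_ratio; f <- p$left_right_rsf_factor
    rsf_tot <- round(t * n_tot / (1 + t))
    rsf_left <- round(rsf_tot * f / (1 + f))
    rsf_right <- rsf_tot - rsf_left

    grid <- array(0L, dims)
    wz <- exp(-p$hilum_concentration * (zs / cc)^2)

    for (sname in names(kid)) {
      k <- kid[[sname]]
      k_rsf <- if (sname == "left") rsf_left else rsf_right
      rp_code <- if (sname == "left") 2L else 1L
      rsf_code <- if (sname == "left") 4L else 3L
      grid[k$mask] <- rp_code

      elig_idx <- which(k$elig)
      if (k_rsf > sum(k$elig))
        stop("kidney geometry infeasible for requested RSF-RP ratio")
      i0 <- elig_idx - 1L
      ix <- i0 %% nx + 1L
      iy <- (i0 %/% nx) %% ny + 1L
      iz <- i0 %/% (nx * ny) + 1L

      area_k <- tabulate((which(k$mask) - 1L) %/% (nx * ny) + 1L, nbins = nz)
      cap_k <- tabulate(iz, nbins = nz)
      quota <- allocate_slice_quota(area_k * wz, cap_k, k_rsf)

      # in-plane score: proximity to a jittered hilar anchor on the medial
      # side, modulated by a smooth random field for shape variability
      ax <- k$cx - k$sgn * 0.45 * a + stats::runif(1, -1, 1) * 0.08 * a
      ay <- stats::runif(1, -1, 1) * 0.15 * b
      sigma <- 0.6 * b
      # fine-grained texture fragments the fat into lobules between vessels;
      # correlation length ~ a few mm, shorter along z than the slab
      # thickness of typical partial-coverage protocols
      field <- smooth_random_field(dims, kernel = c(5L, 5L, 3L))
      score <- exp(-((xs[ix] - ax)^2 + (ys[iy] - ay)^2) / (2 * sigma^2)) *
        exp(1.5 * field[elig_idx])

      by_slice <- split(seq_along(elig_idx), iz)
      for (kz in names(by_slice)) {
        q <- quota[as.integer(kz)]
        if (q > 0L) {
          ii <- by_slice[[kz]]
          take <- ii[order(score[ii], decreasing = TRUE)[seq_len(q)]]
          grid[elig_idx[take]] <- rsf_code
        }
      }
    }

    labels <- label_volume(grid, sp)
    attr(labels, "hilum_slice") <- which.min(abs(zs))
    attr(labels, "kidney_centers_mm") <- c(right = -cx0, left = cx0)

    water <- fat <- NULL
    if (!is.null(p$intensity_snr)) {
      rp <- grid == 1L | grid == 2L
      rsf <- grid == 3L | grid == 4L
      wmean <- array(0.05, dims); wmean[rp] <- 0.8; wmean[rsf] <- 0.2
      fmean <- array(0.05, dims); fmean[rp] <- 0.1; fmean[rsf] <- 0.9
      water <- intensity_volume(
        wmean + array(stats::rnorm(prod(dims), sd = 0.8 / p$intensity_snr), dims),
        sp, "water")
      fat <- intensity_volume(
        fmean + array(stats::rnorm(prod(dims), sd = 0.9 / p$intensity_snr), dims),
        sp, "fat")
    }
    structure(list(labels = labels, water = water, fat = fat, params = p),
              class = "kidney_phantom")
  })
}

#' @export
print.kidney_phantom <- function(x, ...) {
  cat("kidney_phantom\n")
  m <- compartment_volumes(x$labels)
  cat(sprintf("  RP %.1f cm^3, RSF %.2f cm^3, RSF-RP ratio %.3f (target %.3f)\n",
              m$rp_volume_cm3, m$rsf_volume_cm3, m$rsf_rp_ratio,
              x$params$target_rsf_rp_ratio))
  cat(sprintf("  intensity channels: %s\n",
              if (is.null(x$water)) "none" else "water, fat"))
  invisible(x)
}

#' Degrade a reference segmentation
#'
#' Emulates an imperfect automatic segmentation of a reference mask:
#' every compartment surface (outer kidney boundary and the RP/RSF
#' interface) is displaced by a smooth random field of amplitude up to
#' `boundary_shift_mm`, and voxels adjacent to a label boundary are
#' additionally flipped to a neighbouring label with probability
#' `label_noise_rate`. With both parameters 0 the input is returned
#' unchanged. Deterministic under `seed`.
#'
#' @param truth A sided [label_volume()].
#' @param boundary_shift_mm Maximum boundary displacement (mm, >= 0).
#' @param label_noise_rate Voxel flip probability near boundaries, in [0, 1).
#' @param seed Integer seed.
#' @return A perturbed [label_volume()] on the same grid.
#' @export
degrade_mask <- function(truth, boundary_shift_mm, label_noise_rate, seed) {
  stopifnot(inherits(truth, "label_volume"))
  if (boundary_shift_mm < 0) stop("`boundary_shift_mm` must be >= 0")
  if (label_noise_rate < 0 || label_noise_rate >= 1)
    stop("`label_noise_rate` must lie in [0, 1)")
  if (boundary_shift_mm == 0 && label_noise_rate == 0) return(truth)

  with_seed(seed, {
    dims <- dim(truth$grid); sp <- truth$spacing_mm
    grid <- truth$grid

    if (boundary_shift_mm > 0) {
      kidney <- compartment_mask(truth, "kidney")
      rsf <- compartment_mask(truth, "RSF")
      # half signed distance places the surface midway between voxel centres;
      # the uniform sub-voxel dither stands for the unknown position of the
      # true surface within a boundary voxel, so that displacements smaller
      # than the voxel size still flip a graded fraction of boundary voxels
      # (the dither alone never flips anything)
      f1 <- smooth_random_field(dims) * boundary_shift_mm
      f2 <- smooth_random_field(dims) * boundary_shift_mm
      half <- 0.5 * min(sp)
      d1 <- array(stats::runif(prod(dims), -half, half), dims)
      d2 <- array(stats::runif(prod(dims), -half, half), dims)
      new_kid <- signed_distance(kidney, sp) / 2 + f1 + d1 < 0
      new_rsf <- (signed_distance(rsf, sp) / 2 + f2 + d2 < 0) & new_kid

      # side of each voxel: original side where defined, else by the midline
      # between the kidney centroids along the right-left axis
      ix <- slice.index(array(0, dims), 1L)
      left_orig <- compartment_mask(truth, "kidney", side = "left")
      right_orig <- kidney & !left_orig
      xmid <- if (any(left_orig) && any(right_orig))
        (mean(ix[left_orig]) + mean(ix[right_orig])) / 2 else (dims[1] + 1) / 2
      is_left <- array(FALSE, dims)
      is_left[kidney] <- left_orig[kidney]
      outside <- new_kid & !kidney
      is_left[outside] <- ix[outside] > xmid

      grid <- array(0L, dims)
      grid[new_kid] <- ifelse(is_left[new_kid], 2L, 1L)
      grid[new_rsf] <- ifelse(is_left[new_rsf], 4L, 3L)
    }

    if (label_noise_rate > 0) {
      nb <- neighbour_codes(grid)
      boundary <- which(nb$differs)
      flip <- boundary[stats::runif(length(boundary)) < label_noise_rate]
      if (length(flip)) {
        pick <- sample.int(6L, length(flip), replace = TRUE)
        grid[flip] <- nb$codes[cbind(flip, pick)]
      }
    }

    out <- label_volume(grid, sp, truth$label_map)
    attr(out, "hilum_slice") <- attr(truth, "hilum_slice")
    out
  })
}

# 6-neighbour label codes of every voxel (edge voxels replicate themselves)
# and whether any neighbour's label differs.
neighbour_codes <- function(grid) {
  dims <- dim(grid)
  n <- length(grid)
  codes <- matrix(0L, n, 6L)
  shift <- function(d, along) {
    idx <- lapply(dims, seq_len)
    i <- idx[[along]] - d
    i <- pmin(pmax(i, 1L), dims[along])
    idx[[along]] <- i
    do.call(`[`, c(list(grid), idx))
  }
  k <- 0L
  for (along in 1:3) for (d in c(-1L, 1L)) {
    k <- k + 1L
    codes[, k] <- as.vector(shift(d, along))
  }
  differs <- codes[, 1] != as.vector(grid)
  for (k in 2:6) differs <- differs | (codes[, k] != as.vector(grid))
  list(codes = codes, differs = array(differs, dims))
}
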