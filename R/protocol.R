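#' Virtual acquisition protocol geometry
#'
#' Describes a thick-slice axial acquisition with interslice gaps: slabs of
#' width `slice_thickness_mm` repeated with period
#' `slice_thickness_mm + interslice_gap_mm`, the first slab starting at
#' `first_slice_offset_mm` from the inferior grid face. Dense reference
#' volumes are resampled onto this geometry by
#' [simulate_gapped_acquisition()].
#'
#' The default forward model (`sampling = "partial_volume"`) emulates the
#' loss of small structures on thick slices: at each in-plane position a
#' structure is detected in a slab only if it fills at least
#' `detection_fraction` of the slab thickness; otherwise its partial-volume
#' diluted signal is treated as undetectable. `sampling = "average"` records
#' instead the mean per-slice area of the dense slices inside the slab
#' (linear, mass-preserving), and `"point"` samples the dense slice nearest
#' the slab centre.
#'
#' @param slice_thickness_mm Slab thickness (mm, > 0).
#' @param interslice_gap_mm Gap between consecutive slabs (mm, >= 0).
#' @param inplane_spacing_mm Nominal in-plane spacing of the protocol (mm);
#'   recorded for provenance (in-plane resampling is not modelled).
#' @param first_slice_offset_mm Start of the first slab (mm, >= 0).
#' @param sampling Forward model; see Details.
#' @param detection_fraction Minimum within-slab thickness fraction for a
#'   structure to be detected under `"partial_volume"` sampling.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(slice_thickness_mm = 5,
                            interslice_gap_mm = 5,
                            inplane_spacing_mm = c(1.5, 1.5),
                            first_slice_offset_mm = 0,
                            sampling = c("partial_volume", "average", "point"),
                            detection_fraction = 0.6) {
  sampling <- match.arg(sampling)
  if (slice_thickness_mm <= 0) stop("`slice_thickness_mm` must be > 0")
  if (interslice_gap_mm < 0) stop("`interslice_gap_mm` must be >= 0")
  if (first_slice_offset_mm < 0) stop("`first_slice_offset_mm` must be >= 0")
  if (detection_fraction < 0 || detection_fraction > 1)
    stop("`detection_fraction` must lie in [0, 1]")
  structure(list(slice_thickness_mm = slice_thickness_mm,
                 interslice_gap_mm = interslice_gap_mm,
                 inplane_spacing_mm = as.numeric(inplane_spacing_mm),
                 first_slice_offset_mm = first_slice_offset_mm,
                 sampling = sampling,
                 detection_fraction = detection_fraction),
            class = "protocol_config")
}

#' Simulate a partial-coverage (interslice-gap) acquisition
#'
#' Resamples a dense sided reference volume onto the protocol's slab
#' geometry, recording for every structure (RP and RSF, per side) the
#' cross-sectional area seen on each acquired slab. Dense slices falling
#' inside gaps contribute nothing. See [protocol_config()] for the three
#' forward models.
#'
#' @param truth A dense sided [label_volume()] whose slice spacing is finer
#'   than the slab thickness.
#' @param cfg A [protocol_config()].
#' @return An object of class `gapped_series`: a data frame with columns
#'   `structure`, `side`, `z_mm` (slab centre) and `area_mm2`, with the
#'   protocol geometry in attributes.
#' @export
simulate_gapped_acquisition <- function(truth, cfg = protocol_config()) {
  stopifnot(inherits(truth, "label_volume"), inherits(cfg, "protocol_config"))
  sp <- truth$spacing_mm
  dz <- sp[3]
  period <- cfg$slice_thickness_mm + cfg$interslice_gap_mm
  if (period < dz) stop("slab period is smaller than the dense slice spacing")
  if (cfg$slice_thickness_mm < dz)
    stop("slab thickness is smaller than the dense slice spacing")
  dims <- dim(truth$grid)
  zc <- slice_centers_mm(truth)
  z_max <- dims[3] * dz
  starts <- seq(cfg$first_slice_offset_mm, z_max - 1e-9, by = period)
  # dense slices sampled by each slab: slice centres inside the slab for the
  # "average"/"point" models; geometric slab/slice overlap (mm) for the
  # partial-volume model, where the slab signal integrates over its full
  # thickness
  slabs <- lapply(starts, function(s) which(zc >= s & zc < s + cfg$slice_thickness_mm))
  overlaps <- lapply(starts, function(s) {
    ov <- pmin(zc + dz / 2, s + cfg$slice_thickness_mm) - pmax(zc - dz / 2, s)
    ov[ov < 0] <- 0
    ov
  })
  keep <- vapply(slabs, length, 1L) > 0L
  starts <- starts[keep]; slabs <- slabs[keep]; overlaps <- overlaps[keep]

  inplane <- sp[1] * sp[2]
  rows <- list()
  for (structure_ in c("RP", "RSF")) for (s in c("right", "left")) {
    codes <- codes_for(truth, structure_, s)
    ind <- matrix(truth$grid %in% codes, dims[1] * dims[2], dims[3])
    areas <- vapply(seq_along(slabs), function(j) {
      idx <- slabs[[j]]
      if (cfg$sampling == "average") {
        mean(colSums(ind[, idx, drop = FALSE])) * inplane
      } else if (cfg$sampling == "point") {
        centre <- starts[j] + cfg$slice_thickness_mm / 2
        sum(ind[, idx[which.min(abs(zc[idx] - centre))]]) * inplane
      } else {
        ov <- overlaps[[j]]
        frac <- as.vector(ind %*% ov) / cfg$slice_thickness_mm
        sum(frac >= cfg$detection_fraction - 1e-9) * inplane
      }
    }, numeric(1))
    rows[[paste(structure_, s)]] <- data.frame(
      structure = structure_, side = s,
      z_mm = starts + cfg$slice_thickness_mm / 2,
      area_mm2 = areas, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("gapped_series", "data.frame"),
            period_mm = period, config = cfg, z_extent_mm = z_max)
}

#' Gap-compensated volume estimate from an acquired series
#'
#' Per structure and side, the acquired cross-sectional areas are linearly
#' interpolated in z between slab centres, tapered linearly to zero at half
#' a slab period beyond the outermost non-zero slab (to avoid systematic
#' truncation at the kidney poles), and integrated by the trapezoidal rule.
#' The RSF-RP ratio is formed from the side-summed volumes.
#'
#' @param series A `gapped_series` from [simulate_gapped_acquisition()].
#' @return A one-row `compartment_measures` data frame (method `"gapped"`).
#' @export
gapped_volume_estimate <- function(series) {
  stopifnot(inherits(series, "gapped_series"))
  period <- attr(series, "period_mm")
  vol_of <- function(structure_) {
    total <- 0
    for (s in c("right", "left")) {
      sub <- series[series$structure == structure_ & series$side == s, ]
      nz <- which(sub$area_mm2 > 0)
      if (!length(nz)) next
      sub <- sub[nz[1]:nz[length(nz)], ]
      z <- c(sub$z_mm[1] - period / 2, sub$z_mm, sub$z_mm[nrow(sub)] + period / 2)
      a <- c(0, sub$area_mm2, 0)
      total <- total + trapz(z, a)
    }
    total / 1000
  }
  rp <- vol_of("RP"); rsf <- vol_of("RSF")
  if (rp == 0 && rsf == 0)
    warning("no structure visible in the acquired series: zero measures")
  compartment_measures(rp, rsf, "both", "gapped")
}

#' Fit the regression-based protocol adjustment
#'
#' Ordinary least squares of the full-coverage reference volumes on the
#' gapped-protocol measurements, fitted separately for RP and RSF volume.
#' The fitted coefficients map measurements from the partial-coverage
#' protocol onto the reference protocol's scale ([apply_adjustment()]).
#'
#' @param measured Data frame of gapped measurements with columns
#'   `rp_volume_cm3` and `rsf_volume_cm3` (one row per subject).
#' @param reference Data frame of reference measurements, same columns and
#'   row order.
#' @return An object of class `adjustment_model` with per-quantity
#'   intercept, slope and r^2, and `n_fit`.
#' @export
fit_adjustment <- function(measured, reference) {
  if (nrow(measured) != nrow(reference))
    stop("measured and reference must have one row per subject, aligned")
  n <- nrow(measured)
  if (n < 3L) stop("at least 3 paired measurements are required")
  fit_one <- function(x, y) {
    if (stats::sd(x) == 0) stop("zero variance in measured values")
    fit <- stats::lm(y ~ x)
    list(intercept = unname(stats::coef(fit)[1]),
         slope = unname(stats::coef(fit)[2]),
         r2 = summary(fit)$r.squared)
  }
  structure(list(
    rp_volume = fit_one(measured$rp_volume_cm3, reference$rp_volume_cm3),
    rsf_volume = fit_one(measured$rsf_volume_cm3, reference$rsf_volume_cm3),
    n_fit = n), class = "adjustment_model")
}

#' @export
print.adjustment_model <- function(x, ...) {
  cat(sprintf("adjustment_model (OLS of reference on measured, n = %d)\n", x$n_fit))
  for (q in c("rp_volume", "rsf_volume"))
    cat(sprintf("  %s: intercept %.3f, slope %.3f, r^2 %.4f\n",
                q, x[[q]]$intercept, x[[q]]$slope, x[[q]]$r2))
  invisible(x)
}

#' @export
coef.adjustment_model <- function(object, ...) {
  rbind(rp_volume = c(intercept = object$rp_volume$intercept,
                      slope = object$rp_volume$slope),
        rsf_volume = c(intercept = object$rsf_volume$intercept,
                       slope = object$rsf_volume$slope))
}

#' @export
predict.adjustment_model <- function(object, newdata, ...) {
  apply_adjustment(object, newdata)
}

#' Apply a fitted protocol adjustment
#'
#' Maps gapped-protocol RP and RSF volumes onto the reference scale with the
#' fitted linear coefficients; the RSF-RP ratio is recomputed from the
#' adjusted volumes. Negative adjusted volumes are clamped to zero with a
#' warning.
#'
#' @param model An [fit_adjustment()] model.
#' @param measures A `compartment_measures` data frame (one or more rows).
#' @return The adjusted measures (method `"gapped_adjusted"`).
#' @export
apply_adjustment <- function(model, measures) {
  stopifnot(inherits(model, "adjustment_model"))
  rp <- model$rp_volume$intercept + model$rp_volume$slope * measures$rp_volume_cm3
  rsf <- model$rsf_volume$intercept + model$rsf_volume$slope * measures$rsf_volume_cm3
  if (any(rp < 0) || any(rsf < 0)) {
    warning("negative adjusted volume clamped to 0")
    rp <- pmax(rp, 0); rsf <- pmax(rsf, 0)
  }
  out <- data.frame(rp_volume_cm3 = rp, rsf_volume_cm3 = rsf,
                    rsf_rp_ratio = ifelse(rp > 0, rsf / rp, NA_real_),
                    side = measures$side, method = "gapped_adjusted",
                    stringsAsFactors = FALSE)
  class(out) <- c("compartment_measures", "data.frame")
  out
}
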