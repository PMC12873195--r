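#' Default label coding for sided kidney compartment volumes
#'
#' Codes: 0 background, 1 renal parenchyma (RP) right, 2 RP left,
#' 3 renal sinus fat (RSF) right, 4 RSF left. The first image axis runs
#' right-to-left (increasing index = subject left), the second
#' anterior-posterior and the third inferior-superior (the axial slice axis).
#'
#' @return A data frame with columns `code`, `role` and `side`.
#' @export
default_label_map <- function() {
  data.frame(
    code = 0:4,
    role = c("background", "RP", "RP", "RSF", "RSF"),
    side = c(NA, "right", "left", "right", "left"),
    stringsAsFactors = FALSE
  )
}

#' Binary (foreground/background) label coding
#' @return A data frame with columns `code`, `role`, `side`.
#' @export
binary_label_map <- function() {
  data.frame(code = 0:1, role = c("background", "foreground"),
             side = c(NA_character_, NA_character_), stringsAsFactors = FALSE)
}

#' Labelled 3-D volume
#'
#' The universal container of the pipeline: an integer label grid with voxel
#' spacing in mm and a label map associating codes with compartment roles and,
#' optionally, kidney sides. Slices are axial; the slice axis is the third
#' array dimension.
#'
#' @param grid 3-D integer array of label codes.
#' @param spacing_mm Numeric length-3 voxel spacing in mm, strictly positive.
#' @param label_map Data frame with columns `code`, `role`, `side`;
#'   see [default_label_map()].
#' @param slice_axis Index of the superior-inferior (axial slice) axis; fixed
#'   to 3 in this package.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(grid, spacing_mm, label_map = default_label_map(),
                         slice_axis = 3L) {
  if (length(dim(grid)) != 3L) stop("`grid` must be a 3-D array")
  if (length(grid) == 0L) stop("`grid` must be non-empty")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive values")
  if (slice_axis != 3L) stop("the slice axis is fixed to the third array axis")
  storage.mode(grid) <- "integer"
  codes <- unique(as.vector(grid))
  if (!all(codes %in% label_map$code))
    stop("grid contains codes absent from `label_map`: ",
         paste(setdiff(codes, label_map$code), collapse = ", "))
  structure(list(grid = grid, spacing_mm = as.numeric(spacing_mm),
                 label_map = label_map, slice_axis = 3L),
            class = "label_volume")
}

#' Intensity volume (water- or fat-like channel)
#'
#' @param grid 3-D numeric array, all values finite.
#' @param spacing_mm Numeric length-3 voxel spacing in mm.
#' @param channel One of `"water"` or `"fat"`.
#' @return An object of class `intensity_volume`.
#' @export
intensity_volume <- function(grid, spacing_mm, channel = c("water", "fat")) {
  channel <- match.arg(channel)
  if (length(dim(grid)) != 3L) stop("`grid` must be a 3-D array")
  if (!all(is.finite(grid))) stop("intensity values must be finite")
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 3L || any(spacing_mm <= 0))
    stop("`spacing_mm` must be three strictly positive values")
  structure(list(grid = grid, spacing_mm = as.numeric(spacing_mm),
                 channel = channel),
            class = "intensity_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("label_volume: %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3]))
  tab <- table(factor(x$grid, levels = x$label_map$code))
  lab <- ifelse(is.na(x$label_map$side), x$label_map$role,
                paste(x$label_map$role, x$label_map$side))
  for (i in seq_along(lab))
    cat(sprintf("  %d (%s): %d voxels\n", x$label_map$code[i], lab[i], tab[i]))
  invisible(x)
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("intensity_volume (%s): %d x %d x %d voxels, range [%.3g, %.3g]\n",
              x$channel, d[1], d[2], d[3], min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$grid)

voxel_volume_mm3 <- function(vol) prod(vol$spacing_mm)

codes_for <- function(vol, role, side = "both") {
  lm <- vol$label_map
  keep <- lm$role %in% role
  if (!identical(side, "both")) keep <- keep & !is.na(lm$side) & lm$side %in% side
  lm$code[keep]
}

#' Logical mask of a compartment
#'
#' @param vol A [label_volume()].
#' @param role Compartment role(s): `"RP"`, `"RSF"`, `"kidney"` (RP and RSF),
#'   or any role present in the label map.
#' @param side `"left"`, `"right"` or `"both"`.
#' @return A logical array of the grid's shape.
#' @export
compartment_mask <- function(vol, role, side = "both") {
  if (identical(role, "kidney")) role <- c("RP", "RSF")
  codes <- codes_for(vol, role, side)
  array(vol$grid %in% codes, dim = dim(vol$grid))
}

# Per-axial-slice cross-sectional areas (mm^2) of a compartment.
slice_areas <- function(vol, role, side = "both") {
  m <- compartment_mask(vol, role, side)
  apply(m, 3L, sum) * vol$spacing_mm[1] * vol$spacing_mm[2]
}

# Axial slice-center positions in mm (first slice centered at dz/2).
slice_centers_mm <- function(vol) {
  (seq_len(dim(vol$grid)[3]) - 0.5) * vol$spacing_mm[3]
}
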