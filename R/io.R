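sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

#' Write a label volume as NIfTI with a JSON label-map sidecar
#'
#' @param vol A [label_volume()].
#' @param path Output path (`.nii` or `.nii.gz`); the label map and slice
#'   axis are written to a JSON sidecar next to it.
#' @return The path, invisibly.
#' @export
write_label_volume <- function(vol, path) {
  stopifnot(inherits(vol, "label_volume"))
  g <- vol$grid
  attr(g, "pixdim") <- vol$spacing_mm
  img <- RNifti::asNifti(g, datatype = "int16")
  RNifti::writeNifti(img, path)
  jsonlite::write_json(
    list(label_map = vol$label_map, slice_axis = vol$slice_axis),
    sidecar_path(path), auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' Read a label volume from NIfTI
#'
#' The voxel data must be integer-valued and the header spacing strictly
#' positive. The label map is taken from the JSON sidecar if present, else
#' the default coding is assumed.
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @return A [label_volume()].
#' @export
read_label_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI '", path,
                                           "': ", conditionMessage(e)))
  data <- as.array(img)
  if (any(data != round(data))) stop("non-integer label data in ", path)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or non-positive voxel spacing in ", path)
  label_map <- default_label_map()
  slice_axis <- 3L
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    lm <- as.data.frame(meta$label_map, stringsAsFactors = FALSE)
    if (!"side" %in% names(lm)) lm$side <- NA_character_
    label_map <- lm
    slice_axis <- as.integer(meta$slice_axis)
  }
  label_volume(array(as.integer(round(data)), dim(data)), spacing,
               label_map, slice_axis)
}

#' Write an intensity volume as NIfTI
#'
#' @param vol An [intensity_volume()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_intensity_volume <- function(vol, path) {
  stopifnot(inherits(vol, "intensity_volume"))
  g <- vol$grid
  attr(g, "pixdim") <- vol$spacing_mm
  img <- RNifti::asNifti(g, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an intensity volume from NIfTI
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param channel Channel label to record (`"water"` or `"fat"`).
#' @return An [intensity_volume()].
#' @export
read_intensity_volume <- function(path, channel = "water") {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("failed to read NIfTI '", path,
                                           "': ", conditionMessage(e)))
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("missing or non-positive voxel spacing in ", path)
  intensity_volume(as.array(img), spacing, channel)
}

#' Export a cohort to NIfTI files plus a CSV manifest
#'
#' Writes each subject's label volume (and intensity channels, if present)
#' under `dir` and a manifest CSV with columns `subject_id`, `sex`, `group`
#' and file paths.
#'
#' @param cohort A `kidney_cohort`.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(s) {
    lab <- file.path(dir, paste0(s$subject_id, "_labels.nii.gz"))
    write_label_volume(s$phantom$labels, lab)
    water <- fat <- NA_character_
    if (!is.null(s$phantom$water)) {
      water <- file.path(dir, paste0(s$subject_id, "_water.nii.gz"))
      fat <- file.path(dir, paste0(s$subject_id, "_fat.nii.gz"))
      write_intensity_volume(s$phantom$water, water)
      write_intensity_volume(s$phantom$fat, fat)
    }
    data.frame(subject_id = s$subject_id, sex = s$sex, group = s$group,
               labels_path = lab, water_path = water, fat_path = fat,
               stringsAsFactors = FALSE)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
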