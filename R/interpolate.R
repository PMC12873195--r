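#' Sparse slice annotation
#'
#' Represents a manual annotation protocol in which only every `stride`-th
#' axial slice is delineated; the remaining slices are filled in later by
#' shape-based interpolation ([interpolate_sparse_annotation()]).
#'
#' @param slices List of 2-D integer label matrices, one per annotated slice.
#' @param annotated_indices Strictly increasing slice indices along the
#'   slice axis; consecutive indices differ by `stride` (the last interval
#'   may be shorter).
#' @param stride Annotation stride (the protocol's default is every fourth
#'   slice).
#' @return An object of class `sparse_annotation`.
#' @export
sparse_annotation <- function(slices, annotated_indices, stride = 4L) {
  annotated_indices <- as.integer(annotated_indices)
  if (length(slices) != length(annotated_indices))
    stop("one label matrix per annotated index is required")
  if (is.unsorted(annotated_indices, strictly = TRUE))
    stop("`annotated_indices` must be strictly increasing")
  d <- diff(annotated_indices)
  if (length(d) > 1L && any(utils::head(d, -1) != stride))
    stop("consecutive annotated indices must differ by `stride`")
  if (length(d) >= 1L && utils::tail(d, 1) > stride)
    stop("the last annotation interval may not exceed `stride`")
  dims <- unique(t(vapply(slices, dim, integer(2))))
  if (nrow(dims) != 1L) stop("all annotated slices must share one shape")
  slices <- lapply(slices, function(s) { storage.mode(s) <- "integer"; s })
  structure(list(slices = slices, annotated_indices = annotated_indices,
                 stride = as.integer(stride), slice_shape = dims[1, ]),
            class = "sparse_annotation")
}

#' Densify a sparse annotation by shape-based interpolation
#'
#' Reconstructs a dense label volume from annotations on a subset of slices.
#' Annotated slices are copied verbatim. For each slice between two
#' annotated ones, the signed 2-D Euclidean distance map of every label
#' present on the bounding slices (negative inside) is interpolated linearly
#' along the slice axis and thresholded at zero; where several labels claim
#' a pixel, the most negative interpolated distance wins. Slices beyond the
#' outermost annotated slices remain empty.
#'
#' @param sparse A [sparse_annotation()].
#' @param target_shape Integer length-3 grid shape of the output volume.
#' @param spacing_mm Voxel spacing of the output volume (mm).
#' @param label_map Label map of the output volume.
#' @return A dense [label_volume()].
#' @export
interpolate_sparse_annotation <- function(sparse, target_shape, spacing_mm,
                                          label_map = default_label_map()) {
  stopifnot(inherits(sparse, "sparse_annotation"))
  target_shape <- as.integer(target_shape)
  idx <- sparse$annotated_indices
  if (length(idx) < 2L) stop("at least 2 annotated slices are required")
  if (any(idx < 1L) || any(idx > target_shape[3]))
    stop("annotated slice indices fall outside the target grid")
  if (!all(sparse$slice_shape == target_shape[1:2]))
    stop("annotated slice shape does not match the target grid")

  grid <- array(0L, target_shape)
  for (i in seq_along(idx)) grid[, , idx[i]] <- sparse$slices[[i]]

  sd2d <- function(mask2d) {
    if (!any(mask2d)) return(matrix(Inf, nrow(mask2d), ncol(mask2d)))
    if (all(mask2d)) return(matrix(-Inf, nrow(mask2d), ncol(mask2d)))
    dims <- c(dim(mask2d), 1L)
    dout <- sqrt(edt_sq_cpp(as.vector(mask2d), dims, c(spacing_mm[1:2], 1)))
    din <- sqrt(edt_sq_cpp(as.vector(!mask2d), dims, c(spacing_mm[1:2], 1)))
    matrix(dout - din, nrow(mask2d))
  }

  for (i in seq_len(length(idx) - 1L)) {
    i1 <- idx[i]; i2 <- idx[i + 1L]
    if (i2 - i1 < 2L) next
    s1 <- grid[, , i1]; s2 <- grid[, , i2]
    labels <- setdiff(unique(c(s1, s2)), 0L)
    if (!length(labels)) next
    d1 <- lapply(labels, function(l) sd2d(s1 == l))
    d2 <- lapply(labels, function(l) sd2d(s2 == l))
    for (j in seq(i1 + 1L, i2 - 1L)) {
      t <- (j - i1) / (i2 - i1)
      best_d <- matrix(Inf, target_shape[1], target_shape[2])
      best_l <- matrix(0L, target_shape[1], target_shape[2])
      for (k in seq_along(labels)) {
        dk <- (1 - t) * d1[[k]] + t * d2[[k]]
        dk[is.nan(dk)] <- Inf  # Inf + -Inf mixtures: label undecided, stay out
        upd <- dk < 0 & dk < best_d
        best_d[upd] <- dk[upd]
        best_l[upd] <- labels[k]
      }
      grid[, , j] <- best_l
    }
  }
  label_volume(grid, spacing_mm, label_map)
}
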