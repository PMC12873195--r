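#' Confusion counts and segmentation metrics for one label
#'
#' Computes the voxel-wise confusion matrix of a predicted mask against a
#' reference mask (the reference is the ground truth) and the six derived
#' metrics: Dice similarity coefficient (DSC), intersection over union
#' (IoU), accuracy, sensitivity, precision and specificity. A label empty in
#' both volumes is scored as perfect agreement on absence (DSC, IoU,
#' sensitivity and precision 1, by convention); a label empty in exactly one
#' volume scores 0 on those metrics.
#'
#' @param pred,ref [label_volume()]s on the same grid and spacing.
#' @param label A compartment role (`"RP"`, `"RSF"`, `"foreground"`, ...) or
#'   integer label code(s); sided codes of the same role are pooled.
#' @param side `"left"`, `"right"` or `"both"`.
#' @return An object of class `seg_metrics`: a list with `counts`
#'   (tp, fp, fn, tn) and `metrics` (the six metrics).
#' @export
label_metrics <- function(pred, ref, label, side = "both") {
  stopifnot(inherits(pred, "label_volume"), inherits(ref, "label_volume"))
  if (!identical(dim(pred$grid), dim(ref$grid)))
    stop("prediction and reference grids differ in shape")
  if (!isTRUE(all.equal(pred$spacing_mm, ref$spacing_mm)))
    stop("prediction and reference differ in voxel spacing")
  as_mask <- function(vol) {
    if (is.numeric(label)) array(vol$grid %in% as.integer(label), dim(vol$grid))
    else compartment_mask(vol, label, side)
  }
  p <- as_mask(pred); r <- as_mask(ref)
  tp <- sum(p & r); fp <- sum(p & !r); fn <- sum(!p & r)
  tn <- length(p) - tp - fp - fn
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)

  safe <- function(num, den, empty_value) if (den == 0) empty_value else num / den
  if (tp + fp + fn == 0L) {
    message("label empty in both volumes: overlap metrics set to 1 by convention")
    dsc <- iou <- sens <- prec <- 1
  } else {
    dsc <- 2 * tp / (2 * tp + fp + fn)
    iou <- tp / (tp + fp + fn)
    sens <- safe(tp, tp + fn, 0)
    prec <- safe(tp, tp + fp, 0)
  }
  metrics <- c(dsc = dsc, iou = iou,
               accuracy = (tp + tn) / length(p),
               sensitivity = sens, precision = prec,
               specificity = safe(tn, tn + fp, 1))
  structure(list(counts = counts, metrics = metrics, label = label),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("seg_metrics (label %s): tp=%d fp=%d fn=%d tn=%d\n",
              paste(x$label, collapse = "/"),
              x$counts["tp"], x$counts["fp"], x$counts["fn"], x$counts["tn"]))
  print(round(x$metrics, 4))
  invisible(x)
}

#' Cohort-level segmentation-metrics report
#'
#' Aggregates [label_metrics()] over a collection of (prediction, reference)
#' volume pairs: one row per label with the mean and sample standard
#' deviation of each metric (SD reported as 0 for a single pair). The
#' per-case values are retained in the `"per_case"` attribute for audit.
#'
#' @param pairs List of pairs; each element a list with components `pred`
#'   and `ref` ([label_volume()]s).
#' @param labels Labels to report (roles or codes).
#' @return A data frame of class `metrics_report`.
#' @export
metrics_report <- function(pairs, labels = c("RP", "RSF")) {
  if (!length(pairs)) stop("at least one (pred, ref) pair is required")
  metric_names <- c("dsc", "iou", "accuracy", "sensitivity", "precision",
                    "specificity")
  per_case <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    do.call(rbind, lapply(labels, function(l) {
      m <- label_metrics(pairs[[i]]$pred, pairs[[i]]$ref, l)
      data.frame(case = i, label = as.character(l),
                 t(m$metrics), stringsAsFactors = FALSE)
    }))
  }))
  rows <- lapply(unique(per_case$label), function(l) {
    sub <- per_case[per_case$label == l, , drop = FALSE]
    out <- data.frame(label = l, stringsAsFactors = FALSE)
    for (m in metric_names) {
      out[[paste0(m, "_mean")]] <- mean(sub[[m]])
      out[[paste0(m, "_sd")]] <- sample_sd(sub[[m]])
    }
    out
  })
  report <- do.call(rbind, rows)
  attr(report, "per_case") <- per_case
  class(report) <- c("metrics_report", "data.frame")
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("metrics_report over %d case(s)\n",
              max(attr(x, "per_case")$case)))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a metrics report as CSV
#'
#' @param report A [metrics_report()].
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  invisible(path)
}
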