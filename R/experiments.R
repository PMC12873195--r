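#' Configuration of an end-to-end experiment run
#'
#' Bundles the cohort specification, processing configurations and output
#' location of one reproducible run; a run is a pure function of
#' (configuration, seed).
#'
#' @param output_dir Directory for report files (created if needed).
#' @param cohort A [cohort_spec()].
#' @param preprocess A [preprocess_config()].
#' @param protocol A [protocol_config()].
#' @param degradation List with `boundary_shift_mm` and `label_noise_rate`
#'   for the segmentation-degradation model of the agreement experiment.
#' @param train_fraction Fraction of subjects used to fit the protocol
#'   adjustment (remainder is the held-out set).
#' @param seed Global seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(output_dir = tempfile("renalvol_run_"),
                       cohort = cohort_spec(),
                       preprocess = preprocess_config(),
                       protocol = protocol_config(),
                       degradation = list(boundary_shift_mm = 1,
                                          label_noise_rate = 0.02),
                       train_fraction = 0.5,
                       seed = 1L) {
  stopifnot(inherits(cohort, "cohort_spec"),
            inherits(preprocess, "preprocess_config"),
            inherits(protocol, "protocol_config"))
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must lie in (0, 1)")
  structure(list(output_dir = output_dir, cohort = cohort,
                 preprocess = preprocess, protocol = protocol,
                 degradation = degradation, train_fraction = train_fraction,
                 seed = as.integer(seed)),
            class = "run_config")
}

config_hash <- function(config) {
  x <- config
  x$output_dir <- NULL
  fnv1a_hash(paste(deparse(x, control = "all"), collapse = "\n"))
}

write_provenance <- function(config, experiment, dir) {
  prov <- list(
    experiment = experiment,
    config_hash = config_hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("renalvol")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  path <- file.path(dir, "provenance.json")
  jsonlite::write_json(prov, path, auto_unbox = TRUE)
  path
}

subject_measures_table <- function(rows, ids, method) {
  out <- do.call(rbind, rows)
  out$subject_id <- ids
  out$method <- method
  out[, c("subject_id", "method", "side", "rp_volume_cm3", "rsf_volume_cm3",
          "rsf_rp_ratio")]
}

agreement_json <- function(x) {
  list(icc = x$icc$icc, icc_ci = c(x$icc$ci_lower, x$icc$ci_upper),
       icc_model = x$icc$model_label,
       mean_difference = x$bland_altman$mean_difference,
       loa = c(x$bland_altman$loa_lower, x$bland_altman$loa_upper),
       pearson_r = x$pearson$r,
       pearson_ci = c(x$pearson$ci_lower, x$pearson$ci_upper),
       n = x$bland_altman$n)
}

group_summary <- function(df, value_cols, groups) {
  out <- lapply(c(list(all = rep(TRUE, nrow(df))),
                  stats::setNames(lapply(groups, function(g) df$group == g),
                                  groups)),
                function(sel) {
    row <- list(n = sum(sel))
    for (v in value_cols) {
      row[[paste0(v, "_mean")]] <- mean(df[[v]][sel], na.rm = TRUE)
      row[[paste0(v, "_sd")]] <- sample_sd(df[[v]][sel][!is.na(df[[v]][sel])])
    }
    as.data.frame(row)
  })
  cbind(data.frame(group = c("all", groups), stringsAsFactors = FALSE),
        do.call(rbind, out))
}

#' Run one of the three pipeline experiments
#'
#' * `"agreement"`: generates the cohort, degrades each subject's reference
#'   mask with the configured segmentation-degradation model, and reports
#'   per-label segmentation metrics (mean +/- SD) plus Bland-Altman/ICC
#'   agreement of RP and RSF volumes between reference and degraded masks.
#' * `"slicewise"`: compares whole-kidney with single-slice morphometry per
#'   subject; reports Pearson/ICC/Bland-Altman agreement and a per-group
#'   summary of both ratios and the per-subject percentage difference.
#' * `"protocol"`: simulates the partial-coverage acquisition per subject,
#'   fits the regression adjustment on a training split, applies it to the
#'   held-out subjects, and reports original/adjusted/reference values with
#'   per-group summaries.
#'
#' Every run writes CSV reports plus a provenance record (configuration
#' hash, seed, versions) into `config$output_dir`, and returns the computed
#' objects invisibly. Identical configuration and seed give identical
#' reports.
#'
#' @param config A [run_config()].
#' @param experiment One of `"agreement"`, `"slicewise"`, `"protocol"`.
#' @return Invisibly, a list with the computed results and written files.
#' @export
run_experiment <- function(config,
                           experiment = c("agreement", "slicewise", "protocol")) {
  stopifnot(inherits(config, "run_config"))
  experiment <- match.arg(experiment)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  spec <- config$cohort
  spec$seed <- config$seed
  cohort <- generate_cohort(spec)
  if (!length(cohort)) stop("empty cohort: nothing to analyse")
  ids <- vapply(cohort, `[[`, "", "subject_id")
  info <- cohort_table(cohort)
  groups <- c("control", "T1D", "T2D")
  files <- character(0)

  result <- switch(
    experiment,
    agreement = {
      seeds <- with_seed(config$seed + 1L,
                         sample.int(.Machine$integer.max - 1L, length(cohort)))
      preds <- lapply(seq_along(cohort), function(i)
        degrade_mask(cohort[[i]]$phantom$labels,
                     config$degradation$boundary_shift_mm,
                     config$degradation$label_noise_rate, seeds[i]))
      pairs <- lapply(seq_along(cohort), function(i)
        list(pred = preds[[i]], ref = cohort[[i]]$phantom$labels))
      report <- metrics_report(pairs)
      f1 <- file.path(config$output_dir, "segmentation_metrics.csv")
      write_metrics_report(report, f1)

      ref <- do.call(rbind, lapply(cohort, function(s)
        compartment_volumes(s$phantom$labels)))
      prd <- do.call(rbind, lapply(preds, compartment_volumes))
      agr <- list(rp_volume = agreement_report(ref$rp_volume_cm3, prd$rp_volume_cm3),
                  rsf_volume = agreement_report(ref$rsf_volume_cm3, prd$rsf_volume_cm3))
      f2 <- file.path(config$output_dir, "volume_agreement.json")
      jsonlite::write_json(lapply(agr, agreement_json), f2, auto_unbox = TRUE,
                           digits = NA)
      subj <- rbind(
        subject_measures_table(lapply(seq_len(nrow(ref)), function(i) ref[i, ]),
                               ids, "reference"),
        subject_measures_table(lapply(seq_len(nrow(prd)), function(i) prd[i, ]),
                               ids, "predicted"))
      f3 <- file.path(config$output_dir, "subject_measures.csv")
      utils::write.csv(subj, f3, row.names = FALSE)
      files <- c(f1, f2, f3)
      list(metrics = report, agreement = agr, subjects = subj)
    },
    slicewise = {
      whole <- do.call(rbind, lapply(cohort, function(s)
        compartment_volumes(s$phantom$labels)))
      single <- do.call(rbind, lapply(cohort, function(s)
        single_slice_measures(s$phantom$labels)))
      agr <- list(
        rp_volume = pearson_ci(whole$rp_volume_cm3, single$rp_volume_cm3),
        rsf_volume = pearson_ci(whole$rsf_volume_cm3, single$rsf_volume_cm3),
        ratio_icc = icc_absolute(whole$rsf_rp_ratio, single$rsf_rp_ratio),
        ratio_ba = bland_altman(single$rsf_rp_ratio, whole$rsf_rp_ratio))
      df <- cbind(info,
                  whole_ratio = whole$rsf_rp_ratio,
                  single_ratio = single$rsf_rp_ratio,
                  delta_pct = percent_difference(whole$rsf_rp_ratio,
                                                 single$rsf_rp_ratio))
      summ <- group_summary(df, c("single_ratio", "whole_ratio", "delta_pct"),
                            groups)
      f1 <- file.path(config$output_dir, "slicewise_group_summary.csv")
      utils::write.csv(summ, f1, row.names = FALSE)
      f2 <- file.path(config$output_dir, "slicewise_subjects.csv")
      utils::write.csv(df, f2, row.names = FALSE)
      f3 <- file.path(config$output_dir, "slicewise_agreement.json")
      jsonlite::write_json(
        list(rp_volume_r = agr$rp_volume$r, rsf_volume_r = agr$rsf_volume$r,
             ratio_icc = agr$ratio_icc$icc,
             ratio_mean_difference = agr$ratio_ba$mean_difference,
             ratio_loa = c(agr$ratio_ba$loa_lower, agr$ratio_ba$loa_upper)),
        f3, auto_unbox = TRUE, digits = NA)
      files <- c(f1, f2, f3)
      list(summary = summ, subjects = df, agreement = agr)
    },
    protocol = {
      ref <- do.call(rbind, lapply(cohort, function(s)
        compartment_volumes(s$phantom$labels)))
      gap <- do.call(rbind, lapply(cohort, function(s)
        gapped_volume_estimate(
          simulate_gapped_acquisition(s$phantom$labels, config$protocol))))
      n <- nrow(ref)
      train <- seq_len(n) %% round(1 / config$train_fraction) == 1L
      if (sum(train) < 3L) train <- seq_len(n) <= max(3L, round(n / 2))
      model <- fit_adjustment(gap[train, ], ref[train, ])
      adj <- apply_adjustment(model, gap)
      df <- cbind(info, train = train,
                  ref_rp = ref$rp_volume_cm3, ref_rsf = ref$rsf_volume_cm3,
                  orig_rp = gap$rp_volume_cm3, orig_rsf = gap$rsf_volume_cm3,
                  orig_ratio = gap$rsf_rp_ratio,
                  adj_rp = adj$rp_volume_cm3, adj_rsf = adj$rsf_volume_cm3,
                  adj_ratio = adj$rsf_rp_ratio,
                  delta_rp_pct = percent_difference(adj$rp_volume_cm3,
                                                    gap$rp_volume_cm3),
                  delta_rsf_pct = percent_difference(adj$rsf_volume_cm3,
                                                     gap$rsf_volume_cm3),
                  delta_ratio_pct = percent_difference(adj$rsf_rp_ratio,
                                                       gap$rsf_rp_ratio))
      summ <- group_summary(df, c("orig_rp", "orig_rsf", "orig_ratio",
                                  "adj_rp", "adj_rsf", "adj_ratio",
                                  "delta_rp_pct", "delta_rsf_pct",
                                  "delta_ratio_pct"), groups)
      held <- !train
      heldout <- list(
        n_test = sum(held),
        rsf_bias_original = mean(gap$rsf_volume_cm3[held] - ref$rsf_volume_cm3[held]),
        rsf_bias_adjusted = mean(adj$rsf_volume_cm3[held] - ref$rsf_volume_cm3[held]),
        rp_bias_original = mean(gap$rp_volume_cm3[held] - ref$rp_volume_cm3[held]),
        rp_bias_adjusted = mean(adj$rp_volume_cm3[held] - ref$rp_volume_cm3[held]),
        ref_rsf_mean = mean(ref$rsf_volume_cm3[held]),
        ref_rp_mean = mean(ref$rp_volume_cm3[held]))
      f1 <- file.path(config$output_dir, "protocol_group_summary.csv")
      utils::write.csv(summ, f1, row.names = FALSE)
      f2 <- file.path(config$output_dir, "protocol_subjects.csv")
      utils::write.csv(df, f2, row.names = FALSE)
      f3 <- file.path(config$output_dir, "protocol_adjustment.json")
      jsonlite::write_json(
        list(model = list(rp_volume = model$rp_volume,
                          rsf_volume = model$rsf_volume, n_fit = model$n_fit),
             heldout = heldout),
        f3, auto_unbox = TRUE, digits = NA)
      files <- c(f1, f2, f3)
      list(summary = summ, subjects = df, model = model, heldout = heldout)
    })

  prov <- write_provenance(config, experiment, config$output_dir)
  invisible(c(result, list(files = c(files, prov), cohort_info = info)))
}
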