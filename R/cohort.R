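#' Specification of a synthetic study cohort
#'
#' Describes a cohort with three glycaemic groups (control, T1D, T2D) and
#' balanced sexes. Group and sex act multiplicatively on each subject's
#' target RSF-RP ratio; subject-level heterogeneity is lognormal with
#' coefficient of variation `subject_cv`, and kidney size is jittered around
#' the base geometry. Defaults reflect the pattern reported for renal sinus
#' fat in diabetes cohorts: T2D highest, T1D lowest, males above females,
#' with male kidneys slightly larger.
#'
#' @param n_per_group Non-negative number of subjects per glycaemic group.
#' @param group_rsf_multipliers Named multiplicative RSF effects for
#'   `control`, `T1D`, `T2D` (all > 0).
#' @param sex_rsf_multipliers Named multiplicative RSF effects for `male`
#'   and `female`.
#' @param sex_size_factors Multiplicative kidney half-axis factors per sex.
#' @param subject_cv Lognormal coefficient of variation of the per-subject
#'   RSF-RP ratio around its group/sex mean.
#' @param halfaxis_jitter Uniform relative jitter applied independently to
#'   each kidney half-axis per subject.
#' @param base_params A [phantom_params()] object giving the base geometry.
#' @param seed Integer seed; subject sub-seeds are derived deterministically.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 20L,
                        group_rsf_multipliers = c(control = 1.0, T1D = 0.85, T2D = 1.3),
                        sex_rsf_multipliers = c(male = 1.15, female = 0.85),
                        sex_size_factors = c(male = 1.03, female = 0.97),
                        subject_cv = 0.25,
                        halfaxis_jitter = 0.06,
                        base_params = phantom_params(),
                        seed = 1L) {
  n_per_group <- as.integer(n_per_group)
  if (n_per_group < 0L) stop("`n_per_group` must be non-negative")
  if (!all(c("control", "T1D", "T2D") %in% names(group_rsf_multipliers)))
    stop("`group_rsf_multipliers` must name control, T1D and T2D")
  if (any(group_rsf_multipliers <= 0)) stop("group multipliers must be > 0")
  if (!all(c("male", "female") %in% names(sex_rsf_multipliers)))
    stop("`sex_rsf_multipliers` must name male and female")
  if (!inherits(base_params, "phantom_params"))
    stop("`base_params` must be a phantom_params object")
  structure(list(n_per_group = n_per_group,
                 group_rsf_multipliers = group_rsf_multipliers,
                 sex_rsf_multipliers = sex_rsf_multipliers,
                 sex_size_factors = sex_size_factors,
                 subject_cv = subject_cv,
                 halfaxis_jitter = halfaxis_jitter,
                 base_params = base_params,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort of kidney phantoms
#'
#' Produces `n_per_group` subjects in each glycaemic group with sexes
#' balanced within group. Each subject's phantom parameters are drawn from
#' the cohort specification (group/sex multipliers on the RSF-RP ratio,
#' lognormal subject heterogeneity, kidney-size jitter) and the phantom is
#' generated from a per-subject sub-seed, so identical spec and seed yield
#' identical cohorts.
#'
#' @param spec A [cohort_spec()].
#' @param intensity Logical; generate water/fat intensity channels per
#'   subject (off by default to keep cohorts light).
#' @return An object of class `kidney_cohort`: a list of subjects, each with
#'   `subject_id`, `sex`, `group`, `params` and `phantom`.
#' @export
generate_cohort <- function(spec, intensity = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c("control", "T1D", "T2D")
  n <- spec$n_per_group
  if (n == 0L)
    return(structure(list(), class = "kidney_cohort", spec = spec))

  subjects <- with_seed(spec$seed, {
    total <- 3L * n
    sub_seeds <- sample.int(.Machine$integer.max - 1L, total)
    sdlog <- sqrt(log(1 + spec$subject_cv^2))
    out <- vector("list", total)
    i <- 0L
    for (g in groups) {
      sexes <- rep(c("male", "female"), length.out = n)
      for (s in sexes) {
        i <- i + 1L
        bp <- spec$base_params
        mult <- spec$group_rsf_multipliers[[g]] * spec$sex_rsf_multipliers[[s]] *
          exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
        ratio <- min(max(bp$target_rsf_rp_ratio * mult, 0.01), 0.45)
        axes <- bp$kidney_halfaxes_mm * spec$sex_size_factors[[s]] *
          (1 + stats::runif(3, -spec$halfaxis_jitter, spec$halfaxis_jitter))
        lr <- bp$left_right_rsf_factor * exp(stats::rnorm(1, 0, 0.04))
        params <- phantom_params(
          grid_shape = bp$grid_shape, spacing_mm = bp$spacing_mm,
          kidney_halfaxes_mm = axes, target_rsf_rp_ratio = ratio,
          hilum_concentration = bp$hilum_concentration,
          left_right_rsf_factor = lr,
          intensity_snr = if (intensity) bp$intensity_snr %||% 20 else NULL,
          seed = sub_seeds[i], kidney_gap_mm = bp$kidney_gap_mm,
          shell_fraction = bp$shell_fraction,
          superellipse_exponent = bp$superellipse_exponent)
        out[[i]] <- list(subject_id = sprintf("S%03d", i), sex = s, group = g,
                         params = params)
      }
    }
    out
  })
  for (i in seq_along(subjects))
    subjects[[i]]$phantom <- generate_phantom(subjects[[i]]$params)
  structure(subjects, class = "kidney_cohort", spec = spec)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.kidney_cohort <- function(x, ...) {
  if (!length(x)) {
    cat("kidney_cohort: empty\n")
    return(invisible(x))
  }
  df <- cohort_table(x)
  cat(sprintf("kidney_cohort: %d subjects\n", nrow(df)))
  print(table(df$group, df$sex))
  invisible(x)
}

#' Subject descriptor table of a cohort
#'
#' @param cohort A `kidney_cohort`.
#' @return Data frame with one row per subject: `subject_id`, `sex`, `group`.
#' @export
cohort_table <- function(cohort) {
  data.frame(
    subject_id = vapply(cohort, `[[`, "", "subject_id"),
    sex = vapply(cohort, `[[`, "", "sex"),
    group = vapply(cohort, `[[`, "", "group"),
    stringsAsFactors = FALSE
  )
}
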