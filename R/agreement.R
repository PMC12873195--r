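#' Bland-Altman agreement analysis
#'
#' Differences are taken as `values_b - values_a`, with `values_a` the
#' reference method; the limits of agreement are the mean difference plus or
#' minus 1.96 sample standard deviations of the differences (the
#' conventional large-sample definition).
#'
#' @param values_a Reference-method values.
#' @param values_b Comparison-method values, same length.
#' @return An object of class `bland_altman` with `mean_difference`,
#'   `loa_lower`, `loa_upper`, `sd_difference` and `n`.
#' @export
bland_altman <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("sequences must be paired")
  n <- length(values_a)
  if (n < 2L) stop("at least 2 paired values are required")
  d <- values_b - values_a
  md <- mean(d); s <- stats::sd(d)
  structure(list(mean_difference = md,
                 loa_lower = md - 1.96 * s, loa_upper = md + 1.96 * s,
                 sd_difference = s, n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference %.4g [LoA: %.4g; %.4g]\n",
              x$n, x$mean_difference, x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Intraclass correlation for method agreement
#'
#' Single-measure ICC from the two-way (subjects x methods) mean squares.
#' The default form is two-way random effects, absolute agreement, ICC(A,1),
#' which penalizes systematic offsets between methods — the appropriate
#' form for method-comparison studies. The consistency form ICC(C,1) is
#' available for contrast. Confidence intervals follow the F-based
#' approximations of McGraw & Wong.
#'
#' @param values_a,values_b Paired measurements (n >= 5).
#' @param type `"agreement"` (ICC(A,1), default) or `"consistency"`
#'   (ICC(C,1)).
#' @param conf_level Confidence level of the interval.
#' @return An object of class `icc_result` with `icc`, `ci_lower`,
#'   `ci_upper`, `model_label` and `n`.
#' @export
icc_absolute <- function(values_a, values_b, type = c("agreement", "consistency"),
                         conf_level = 0.95) {
  type <- match.arg(type)
  if (length(values_a) != length(values_b)) stop("sequences must be paired")
  n <- length(values_a)
  if (n < 5L) stop("at least 5 paired observations are required")
  Y <- cbind(values_a, values_b)
  k <- 2L
  grand <- mean(Y)
  if (sum((Y - grand)^2) < 1e-24) stop("zero total variance")
  ri <- rowMeans(Y); cj <- colMeans(Y)
  ssr <- k * sum((ri - grand)^2)
  ssc <- n * sum((cj - grand)^2)
  sse <- sum((Y - grand)^2) - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level

  if (type == "agreement") {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    if (icc >= 1 - 1e-12) {
      ci <- c(icc, icc)
    } else {
      a <- (k * icc) / (n * (1 - icc))
      b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
      v <- (a * msc + b * mse)^2 /
        ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
      fl <- stats::qf(1 - alpha / 2, n - 1, v)
      fu <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (msr - fl * mse) /
        (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
      upper <- n * (fu * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * fu * msr)
      ci <- c(max(-1, lower), min(1, upper))
    }
    label <- "two-way random, absolute agreement, single measures (ICC(A,1))"
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    if (mse < 1e-24) {
      ci <- c(icc, icc)
    } else {
      fobs <- msr / mse
      fl <- fobs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
      fu <- fobs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
      ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    }
    label <- "two-way mixed, consistency, single measures (ICC(C,1))"
  }
  structure(list(icc = icc, ci_lower = ci[1], ci_upper = ci[2],
                 model_label = label, n = n,
                 mean_squares = c(msr = msr, msc = msc, mse = mse)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC = %.4f [95%% CI: %.4f; %.4f]\n  %s (n = %d)\n",
              x$icc, x$ci_lower, x$ci_upper, x$model_label, x$n))
  invisible(x)
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with the interval
#' `tanh(atanh(r) +/- 1.96 / sqrt(n - 3))`. Exact collinearity returns the
#' degenerate interval `[r, r]` with a warning.
#'
#' @param values_a,values_b Paired values (n >= 4), both with non-zero
#'   variance.
#' @return An object of class `correlation_result` with `r`, `ci_lower`,
#'   `ci_upper` and `n`.
#' @export
pearson_ci <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) stop("sequences must be paired")
  n <- length(values_a)
  if (n < 4L) stop("at least 4 paired values are required")
  if (stats::sd(values_a) == 0 || stats::sd(values_b) == 0)
    stop("zero variance in one of the sequences")
  r <- stats::cor(values_a, values_b)
  if (abs(r) >= 1 - 1e-12) {
    warning("values are exactly collinear: degenerate confidence interval")
    ci <- c(r, r)
  } else {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    ci <- tanh(c(z - 1.96 * se, z + 1.96 * se))
  }
  structure(list(r = r, ci_lower = ci[1], ci_upper = ci[2], n = n),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.4f [95%% CI: %.4f; %.4f] (n = %d)\n",
              x$r, x$ci_lower, x$ci_upper, x$n))
  invisible(x)
}

#' Two-way ANOVA with Bonferroni post-hoc contrasts
#'
#' Fits `values ~ sex + group` (optionally with interaction) and reports
#' Type-II F tests for the main effects, plus Bonferroni-adjusted pairwise
#' mean differences with confidence intervals for the glycaemic-group
#' factor.
#'
#' @param values Numeric response (e.g. RSF volume per subject).
#' @param sex_factor,group_factor Factors with at least 2 levels each.
#' @param include_interaction Include the sex x group interaction.
#' @param pairwise Compute the Bonferroni pairwise table for `group_factor`
#'   (can be switched off in simulations).
#' @param conf_level Confidence level of the pairwise intervals.
#' @return An object of class `anova_table` with components `effects`
#'   (effect, F, df1, df2, p) and `pairwise` (contrast, estimate, ci_lower,
#'   ci_upper, p_adjusted).
#' @export
anova_two_way <- function(values, sex_factor, group_factor,
                          include_interaction = FALSE, pairwise = TRUE,
                          conf_level = 0.95) {
  df <- data.frame(y = values, sex = factor(sex_factor),
                   grp = factor(group_factor))
  if (nlevels(df$sex) < 2L || nlevels(df$grp) < 2L)
    stop("both factors need at least 2 levels")
  if (include_interaction && any(table(df$sex, df$grp) == 0L))
    stop("empty cell: interaction model is not estimable")
  form <- if (include_interaction) y ~ sex * grp else y ~ sex + grp
  fit <- stats::lm(form, data = df)
  an <- car::Anova(fit, type = 2)
  rows <- setdiff(rownames(an), "Residuals")
  effects <- data.frame(
    effect = sub("^grp$", "group", sub("^sex$", "sex", rows)),
    F = an[rows, "F value"],
    df1 = an[rows, "Df"],
    df2 = an["Residuals", "Df"],
    p = an[rows, "Pr(>F)"],
    stringsAsFactors = FALSE)
  effects$effect <- sub("sex:grp", "sex:group", effects$effect)

  pw <- NULL
  if (pairwise) {
    emm <- emmeans::emmeans(fit, ~grp)
    cmp <- emmeans::contrast(emm, method = "pairwise", adjust = "bonferroni")
    ci <- stats::confint(cmp, level = conf_level)
    cmp_s <- summary(cmp)
    pw <- data.frame(contrast = as.character(cmp_s$contrast),
                     estimate = cmp_s$estimate,
                     ci_lower = ci$lower.CL, ci_upper = ci$upper.CL,
                     p_adjusted = cmp_s$p.value,
                     stringsAsFactors = FALSE)
  }
  structure(list(effects = effects, pairwise = pw,
                 include_interaction = include_interaction),
            class = "anova_table")
}

#' @export
print.anova_table <- function(x, ...) {
  cat("Two-way ANOVA (Type-II sums of squares)\n")
  e <- x$effects
  for (i in seq_len(nrow(e)))
    cat(sprintf("  %s: F(%d) = %.2f, p = %.4g\n",
                e$effect[i], e$df1[i], e$F[i], e$p[i]))
  if (!is.null(x$pairwise)) {
    cat("Bonferroni pairwise comparisons (group):\n")
    p <- x$pairwise
    for (i in seq_len(nrow(p)))
      cat(sprintf("  %s: %.3f [%.3f; %.3f], p = %.4g\n",
                  p$contrast[i], p$estimate[i], p$ci_lower[i], p$ci_upper[i],
                  p$p_adjusted[i]))
  }
  invisible(x)
}

#' Bundle agreement statistics for a paired comparison
#'
#' Convenience wrapper mirroring the reporting style of method-comparison
#' studies: ICC with CI, Bland-Altman mean difference with LoA, and Pearson
#' r with CI for one compared quantity.
#'
#' @param reference,comparison Paired values (reference method first).
#' @return A list of class `agreement_report` with elements `icc`,
#'   `bland_altman` and `pearson`.
#' @export
agreement_report <- function(reference, comparison) {
  structure(list(icc = icc_absolute(reference, comparison),
                 bland_altman = bland_altman(reference, comparison),
                 pearson = pearson_ci(reference, comparison)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  print(x$icc); print(x$bland_altman); print(x$pearson)
  invisible(x)
}
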