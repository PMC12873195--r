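test_that("Bland-Altman reproduces hand-computed limits and the translation property", {
  a <- c(1, 2, 3)
  b <- a + c(2, -2, 3)
  res <- bland_altman(a, b)
  expect_equal(res$mean_difference, 1)
  expect_equal(res$sd_difference, sqrt(7), tolerance = 1e-12)
  expect_equal(res$loa_lower, 1 - 1.96 * sqrt(7), tolerance = 1e-12)
  expect_equal(res$loa_upper, 1 + 1.96 * sqrt(7), tolerance = 1e-12)

  ident <- bland_altman(a, a)
  expect_equal(ident$mean_difference, 0)
  expect_equal(c(ident$loa_lower, ident$loa_upper), c(0, 0))

  shifted <- bland_altman(a, b + 5)
  expect_equal(shifted$mean_difference, res$mean_difference + 5)
  expect_equal(shifted$loa_upper - shifted$loa_lower,
               res$loa_upper - res$loa_lower)

  expect_error(bland_altman(1, 1), "at least 2")
  expect_error(bland_altman(1:3, 1:4), "paired")
})

test_that("LoA cover about 95% of Gaussian differences", {
  set.seed(7)
  a <- rnorm(5000, 100, 10)
  b <- a + rnorm(5000, 1, 2)
  res <- bland_altman(a, b)
  d <- b - a
  cover <- mean(d >= res$loa_lower & d <= res$loa_upper)
  expect_gte(cover, 0.92)
  expect_lte(cover, 0.98)
})

test_that("ICC(A,1) matches explicit variance-component arithmetic", {
  # constructed 6-subject table; oracle computed from first principles
  a <- c(9, 6, 8, 7, 10, 6)
  b <- c(2, 1, 4, 1, 5, 2)
  res <- icc_absolute(a, b)
  Y <- cbind(a, b); n <- 6; k <- 2
  gm <- mean(Y)
  msr <- k * sum((rowMeans(Y) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(Y) - gm)^2) / (k - 1)
  mse <- (sum((Y - gm)^2) - (n - 1) * msr - (k - 1) * msc) / ((n - 1) * (k - 1))
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(res$icc, oracle, tolerance = 1e-10)
  expect_lte(res$ci_lower, res$icc)
  expect_gte(res$ci_upper, res$icc)

  # identical pairs with spread: perfect agreement
  perfect <- icc_absolute(a, a)
  expect_equal(perfect$icc, 1)

  # a constant offset is penalized by absolute agreement, not by consistency
  off_a <- icc_absolute(a * 3, a * 3 + 10)$icc
  off_c <- icc_absolute(a * 3, a * 3 + 10, type = "consistency")$icc
  expect_lt(off_a, off_c)

  expect_error(icc_absolute(rep(1, 6), rep(1, 6)), "zero total variance")
  expect_error(icc_absolute(1:4, 1:4), "at least 5")
})

test_that("ICC decreases monotonically with a growing constant offset", {
  a <- c(12, 15, 19, 22, 27, 31, 36, 40)
  iccs <- vapply(c(0, 2, 5, 10), function(off)
    icc_absolute(a, a + off)$icc, numeric(1))
  expect_true(all(diff(iccs) < 0))
  expect_equal(iccs[1], 1)
})

test_that("Pearson r and its Fisher-z interval match the classical oracle", {
  x <- c(1, 2, 3); y <- c(2, 4, 5)
  # n = 4 needed: extend with a fourth point and check against cor.test
  x4 <- c(x, 5); y4 <- c(y, 9)
  res <- pearson_ci(x4, y4)
  ct <- cor.test(x4, y4)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  # cor.test uses the exact normal quantile where the convention here is the
  # literal 1.96; intervals agree to ~1e-4
  expect_equal(c(res$ci_lower, res$ci_upper), unname(ct$conf.int),
               tolerance = 1e-3, ignore_attr = TRUE)
  # hand product-moment value for the 3-point classic
  r3 <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r3, 0.9819805, tolerance = 1e-6)

  expect_warning(col <- pearson_ci(c(1, 2, 3, 4), c(2, 4, 6, 8)), "collinear")
  expect_equal(c(col$r, col$ci_lower, col$ci_upper), c(1, 1, 1))

  set.seed(3)
  xs <- rnorm(30); ys <- 0.5 * xs + rnorm(30)
  base <- pearson_ci(xs, ys)
  perm <- sample(30)
  expect_equal(pearson_ci(xs[perm], ys[perm])$r, base$r)

  expect_error(pearson_ci(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_ci(1:3, 1:3), "at least 4")
})

test_that("Pearson CI coverage sits near the nominal level", {
  set.seed(11)
  rho <- 0.5
  hits <- vapply(1:2000, function(i) {
    x <- rnorm(50)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(50)
    ci <- pearson_ci(x, y)
    ci$ci_lower <= rho && rho <= ci$ci_upper
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("two-way ANOVA detects constructed group effects with Bonferroni contrasts", {
  set.seed(5)
  grp <- rep(c("control", "T1D", "T2D"), each = 20)
  sex <- rep(rep(c("male", "female"), each = 10), 3)
  mu <- c(control = 10, T1D = 10, T2D = 20)[grp]
  y <- mu + rnorm(60, sd = 0.5)
  res <- anova_two_way(y, sex, grp)
  eff <- res$effects
  expect_lt(eff$p[eff$effect == "group"], 1e-6)
  pw <- res$pairwise
  big <- pw[grep("control - T2D|T2D - control", pw$contrast), ]
  expect_false(big$ci_lower <= 0 && big$ci_upper >= 0)
  near <- pw[grep("control - T1D|T1D - control", pw$contrast), ]
  expect_true(near$ci_lower <= 0 && near$ci_upper >= 0)

  # Bonferroni arithmetic: adjusted p = min(1, m * p_raw)
  raw <- summary(emmeans::contrast(
    emmeans::emmeans(stats::lm(y ~ sex + grp,
                               data = data.frame(y = y, sex = sex, grp = grp)),
                     ~grp), method = "pairwise", adjust = "none"))$p.value
  expect_equal(pw$p_adjusted, pmin(1, 3 * raw), tolerance = 1e-10)

  expect_error(anova_two_way(y[1:20], sex[1:20], grp[1:20]), "2 levels")
  grp2 <- grp; grp2[sex == "male" & grp == "T2D"] <- "T1D"
  expect_error(anova_two_way(y, sex, grp2, include_interaction = TRUE),
               "empty cell")
})

test_that("the glycaemic main effect keeps its nominal type-I error under the null", {
  set.seed(19)
  grp <- rep(c("control", "T1D", "T2D"), each = 12)
  sex <- rep(rep(c("male", "female"), each = 6), 3)
  rejections <- vapply(1:1000, function(i) {
    y <- rnorm(36)
    res <- anova_two_way(y, sex, grp, pairwise = FALSE)
    res$effects$p[res$effects$effect == "group"] < 0.05
  }, logical(1))
  rate <- mean(rejections)
  band <- 1.96 * sqrt(0.05 * 0.95 / 1000)
  expect_gte(rate, 0.05 - band)
  expect_lte(rate, 0.05 + band)
})
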