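test_that("realized RSF-RP ratio tracks the target and respects sides", {
  ph <- generate_phantom(small_phantom_params(target_rsf_rp_ratio = 0.08, seed = 7))
  m <- compartment_volumes(ph$labels)
  expect_gt(m$rsf_rp_ratio, 0.8 * 0.08)
  expect_lt(m$rsf_rp_ratio, 1.2 * 0.08)

  # mirror-symmetric geometry with factor 1: sides equal within 2%
  ph1 <- generate_phantom(small_phantom_params(left_right_rsf_factor = 1, seed = 3))
  l <- compartment_volumes(ph1$labels, "left")$rsf_volume_cm3
  r <- compartment_volumes(ph1$labels, "right")$rsf_volume_cm3
  expect_lt(abs(l / r - 1), 0.02)
})

test_that("every voxel carries exactly one label and kidneys are sided", {
  ph <- generate_phantom(small_phantom_params(seed = 11))
  g <- ph$labels$grid
  expect_true(all(g %in% 0:4))
  # two kidney bodies, one per side
  for (s in c("left", "right")) {
    expect_gt(sum(compartment_mask(ph$labels, "RP", s)), 0)
    expect_gt(sum(compartment_mask(ph$labels, "RSF", s)), 0)
  }
  # RP and RSF are disjoint by construction of the single code per voxel
  expect_identical(sum(compartment_mask(ph$labels, "RP") &
                         compartment_mask(ph$labels, "RSF")), 0L)
})

test_that("strong hilum concentration gives a unimodal per-slice RSF profile peaking at the hilum", {
  ph <- generate_phantom(small_phantom_params(hilum_concentration = 6, seed = 5))
  prof <- renalvol:::slice_areas(ph$labels, "RSF")
  hilum <- attr(ph$labels, "hilum_slice")
  expect_equal(which.max(prof), hilum)
  # unimodal: non-decreasing up to the peak, non-increasing after
  peak <- which.max(prof)
  expect_true(all(diff(prof[1:peak]) >= 0))
  expect_true(all(diff(prof[peak:length(prof)]) <= 0))
})

test_that("phantoms are pure functions of (params, seed)", {
  p <- small_phantom_params(seed = 42, intensity_snr = 15)
  a <- generate_phantom(p)
  b <- generate_phantom(p)
  expect_identical(a$labels$grid, b$labels$grid)
  expect_identical(a$water$grid, b$water$grid)
  expect_identical(a$fat$grid, b$fat$grid)
  c <- generate_phantom(small_phantom_params(seed = 43, intensity_snr = 15))
  expect_false(identical(a$labels$grid, c$labels$grid))
})

test_that("intensity channels show the expected contrast", {
  ph <- generate_phantom(small_phantom_params(seed = 2, intensity_snr = 25))
  rp <- compartment_mask(ph$labels, "RP")
  rsf <- compartment_mask(ph$labels, "RSF")
  expect_gt(mean(ph$water$grid[rp]), mean(ph$water$grid[rsf]))
  expect_gt(mean(ph$fat$grid[rsf]), mean(ph$fat$grid[rp]))
})

test_that("infeasible geometry is rejected with an explicit error", {
  expect_error(phantom_params(target_rsf_rp_ratio = 0.45,
                              left_right_rsf_factor = 20),
               "infeasible")
  expect_error(phantom_params(grid_shape = c(20L, 20L, 20L)), "margin|fit")
})

test_that("ratio calibration holds in the mean over seeds", {
  ratios <- vapply(1:20, function(s) {
    compartment_volumes(
      generate_phantom(small_phantom_params(seed = s))$labels)$rsf_rp_ratio
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.10), 0.01)
})

test_that("left/right asymmetry calibration matches the requested factor", {
  lr <- vapply(1:20, function(s) {
    ph <- generate_phantom(small_phantom_params(seed = s))
    compartment_volumes(ph$labels, "left")$rsf_volume_cm3 /
      compartment_volumes(ph$labels, "right")$rsf_volume_cm3
  }, numeric(1))
  expect_gt(mean(lr), 1.25)
  expect_lt(mean(lr), 1.35)
})

test_that("degradation 0/0 is the identity and fixed seeds reproduce", {
  ph <- generate_phantom(small_phantom_params(seed = 9))
  expect_identical(degrade_mask(ph$labels, 0, 0, seed = 1)$grid, ph$labels$grid)
  a <- degrade_mask(ph$labels, 1, 0.02, seed = 5)
  b <- degrade_mask(ph$labels, 1, 0.02, seed = 5)
  expect_identical(a$grid, b$grid)
  expect_false(identical(a$grid, degrade_mask(ph$labels, 1, 0.02, seed = 6)$grid))
})

test_that("mean DSC decreases strictly with boundary shift", {
  ph <- generate_phantom(small_phantom_params(seed = 4))
  mean_dsc <- vapply(c(0.5, 1, 2), function(sh) {
    mean(vapply(1:8, function(s) {
      d <- degrade_mask(ph$labels, sh, 0, seed = s)
      label_metrics(d, ph$labels, "RP")$metrics[["dsc"]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_dsc) < 0))
})

test_that("cohorts reflect group effects, balance sexes and reproduce under seed", {
  spec <- small_cohort_spec(n_per_group = 6, seed = 21)
  coh <- generate_cohort(spec)
  info <- cohort_table(coh)
  expect_equal(nrow(info), 18)
  expect_true(all(table(info$group, info$sex) == 3))

  coh2 <- generate_cohort(spec)
  expect_identical(lapply(coh, function(s) s$phantom$labels$grid),
                   lapply(coh2, function(s) s$phantom$labels$grid))

  expect_length(generate_cohort(small_cohort_spec(n_per_group = 0)), 0)
})

test_that("a strong T2D multiplier shifts the realized group mean RSF", {
  spec <- small_cohort_spec(
    n_per_group = 30, seed = 8,
    group_rsf_multipliers = c(control = 1, T1D = 1, T2D = 1.5),
    sex_rsf_multipliers = c(male = 1, female = 1))
  coh <- generate_cohort(spec)
  info <- cohort_table(coh)
  rsf <- vapply(coh, function(s)
    compartment_volumes(s$phantom$labels)$rsf_volume_cm3, numeric(1))
  ratio <- mean(rsf[info$group == "T2D"]) / mean(rsf[info$group == "control"])
  expect_gt(ratio, 1.35)
  expect_lt(ratio, 1.65)
})
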