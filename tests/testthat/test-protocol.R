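test_that("the identity protocol reproduces the dense per-slice areas", {
  vol <- make_cylinder_pair(spacing = c(2, 2, 2))
  cfg <- protocol_config(slice_thickness_mm = 2, interslice_gap_mm = 0)
  ser <- simulate_gapped_acquisition(vol, cfg)
  rp_right <- ser[ser$structure == "RP" & ser$side == "right", ]
  dense <- renalvol:::slice_areas(vol, "RP", "right")
  expect_equal(rp_right$area_mm2, dense, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("a constant-area cylinder reports constant areas at the slab period", {
  vol <- make_cylinder_pair(spacing = c(2, 2, 2), z1 = 1L, z2 = 30L)
  ser <- simulate_gapped_acquisition(vol, protocol_config(5, 5))
  sub <- ser[ser$structure == "RP" & ser$side == "right", ]
  expect_true(all(diff(sub$z_mm) == 10))
  expect_equal(length(unique(sub$area_mm2)), 1L)
})

test_that("a thin fat depot lying inside a gap is missed entirely", {
  dims <- c(16L, 16L, 30L)
  g <- array(0L, dims)
  g[4:12, 4:12, 1:30] <- 1L       # right RP column
  g[6:10, 6:10, 14:15] <- 3L      # 4 mm depot at z in [26, 30] mm
  vol <- label_volume(g, c(1, 1, 2))
  # slabs [0,5), [10,15), [20,25), ...: the gap [25, 30) swallows the depot
  cfg <- protocol_config(slice_thickness_mm = 5, interslice_gap_mm = 5,
                         first_slice_offset_mm = 0)
  ser <- simulate_gapped_acquisition(vol, cfg)
  rsf <- ser[ser$structure == "RSF", ]
  expect_true(all(rsf$area_mm2 == 0))
})

test_that("gapped estimates recover analytic volumes within tolerance", {
  # cylinder fully spanned by slabs: end taper is the only error source
  vol <- make_cylinder_pair(spacing = c(2, 2, 2), z1 = 6L, z2 = 25L)
  truth <- compartment_volumes(vol)
  est <- gapped_volume_estimate(
    simulate_gapped_acquisition(vol, protocol_config(4, 0, sampling = "average")))
  expect_lt(abs(est$rp_volume_cm3 / truth$rp_volume_cm3 - 1), 0.05)

  # digitized ellipsoid at 5 mm slabs / 5 mm gaps, over an offset sweep
  mask <- digitize_ellipsoid(c(20, 15, 30), c(1, 1, 1))
  grid <- array(0L, dim(mask)); grid[mask] <- 1L
  evol <- label_volume(grid, c(1, 1, 1))
  analytic <- 4 / 3 * pi * 20 * 15 * 30 / 1000
  ests <- vapply(0:9, function(off) {
    gapped_volume_estimate(simulate_gapped_acquisition(
      evol, protocol_config(5, 5, first_slice_offset_mm = off,
                            sampling = "average")))$rp_volume_cm3
  }, numeric(1))
  expect_true(all(abs(ests / analytic - 1) < 0.10))
})

test_that("full coverage degenerates to the dense whole-kidney volume", {
  ph <- generate_phantom(small_phantom_params(seed = 19))
  dense <- compartment_volumes(ph$labels)
  est <- gapped_volume_estimate(simulate_gapped_acquisition(
    ph$labels, protocol_config(slice_thickness_mm = 2, interslice_gap_mm = 0)))
  expect_lt(abs(est$rp_volume_cm3 / dense$rp_volume_cm3 - 1), 0.01)
  expect_lt(abs(est$rsf_volume_cm3 / dense$rsf_volume_cm3 - 1), 0.01)
})

test_that("protocols coarser than the dense grid are rejected", {
  vol <- make_cylinder_pair(spacing = c(2, 2, 4))
  expect_error(simulate_gapped_acquisition(vol, protocol_config(3, 0)),
               "spacing")
})

test_that("exact linear relations are recovered by the adjustment fit", {
  x <- c(10, 20, 30, 40, 55)
  measured <- data.frame(rp_volume_cm3 = x, rsf_volume_cm3 = x / 10)
  reference <- data.frame(rp_volume_cm3 = 0.6 * x + 2,
                          rsf_volume_cm3 = 0.6 * x / 10 + 2)
  fit <- fit_adjustment(measured, reference)
  expect_equal(fit$rp_volume$slope, 0.6, tolerance = 1e-10)
  expect_equal(fit$rp_volume$intercept, 2, tolerance = 1e-10)
  expect_equal(fit$rp_volume$r2, 1, tolerance = 1e-10)
  expect_equal(unname(coef(fit)["rsf_volume", "slope"]), 0.6, tolerance = 1e-10)

  expect_error(fit_adjustment(measured[1:2, ], reference[1:2, ]), "at least 3")
  flat <- data.frame(rp_volume_cm3 = rep(1, 5), rsf_volume_cm3 = rep(1, 5))
  expect_error(fit_adjustment(flat, reference), "zero variance")
})

test_that("noisy slopes are recovered within tolerance", {
  set.seed(42)
  x <- runif(60, 50, 300)
  y <- 0.65 * x + rnorm(60, sd = 0.05 * diff(range(x)))
  fit <- fit_adjustment(data.frame(rp_volume_cm3 = x, rsf_volume_cm3 = x),
                        data.frame(rp_volume_cm3 = y, rsf_volume_cm3 = y))
  expect_lt(abs(fit$rp_volume$slope - 0.65), 0.05)
})

test_that("applying an adjustment rescales volumes and recomputes the ratio", {
  id <- structure(list(rp_volume = list(intercept = 0, slope = 1, r2 = 1),
                       rsf_volume = list(intercept = 0, slope = 1, r2 = 1),
                       n_fit = 5L), class = "adjustment_model")
  m <- renalvol:::compartment_measures(100, 15, "both", "gapped")
  out <- apply_adjustment(id, m)
  expect_equal(out$rp_volume_cm3, 100)
  expect_equal(out$rsf_volume_cm3, 15)
  expect_equal(out$method, "gapped_adjusted")

  sc <- structure(list(rp_volume = list(intercept = 0, slope = 1, r2 = 1),
                       rsf_volume = list(intercept = 3, slope = 1.2, r2 = 1),
                       n_fit = 5L), class = "adjustment_model")
  out2 <- apply_adjustment(sc, m)
  expect_equal(out2$rsf_volume_cm3, 21)
  expect_equal(out2$rsf_rp_ratio, 21 / 100)

  neg <- structure(list(rp_volume = list(intercept = -500, slope = 1, r2 = 1),
                        rsf_volume = list(intercept = 0, slope = 1, r2 = 1),
                        n_fit = 5L), class = "adjustment_model")
  expect_warning(out3 <- apply_adjustment(neg, m), "clamped")
  expect_equal(out3$rp_volume_cm3, 0)
})

test_that("gapped protocols underestimate lobulated fat but barely affect parenchyma", {
  # full-size kidneys: the relative end-slab loss scales with slab period
  # over kidney length, so the RP/RSF contrast is a property of realistic
  # geometry
  biases <- t(vapply(1:10, function(s) {
    ph <- generate_phantom(phantom_params(seed = s))
    truth <- compartment_volumes(ph$labels)
    est <- gapped_volume_estimate(simulate_gapped_acquisition(
      ph$labels, protocol_config(5, 5)))
    c(rp = est$rp_volume_cm3 / truth$rp_volume_cm3 - 1,
      rsf = est$rsf_volume_cm3 / truth$rsf_volume_cm3 - 1)
  }, numeric(2)))
  expect_lt(mean(biases[, "rsf"]), 0)
  expect_lt(abs(mean(biases[, "rp"])), abs(mean(biases[, "rsf"])) / 5)
})
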