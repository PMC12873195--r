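test_that("volumes convert voxel counts with the grid spacing", {
  g <- array(0L, c(20, 10, 10))
  g[1:10, 1:10, 1:10] <- 1L  # 1000 RP voxels
  vol <- label_volume(g, c(1, 1, 1))
  m <- compartment_volumes(vol)
  expect_equal(m$rp_volume_cm3, 1.0)
  expect_equal(m$rsf_volume_cm3, 0)
  expect_equal(m$rsf_rp_ratio, 0)

  # anisotropic spacing scales the volume by the voxel volume
  m2 <- compartment_volumes(label_volume(g, c(1.5, 1.5, 3)))
  expect_equal(m2$rp_volume_cm3, 1000 * 1.5 * 1.5 * 3 / 1000)

  # no RP: undefined ratio marker, not an error
  g0 <- array(0L, c(4, 4, 4)); g0[1, 1, 1] <- 3L
  m3 <- compartment_volumes(label_volume(g0, c(1, 1, 1)))
  expect_true(is.na(m3$rsf_rp_ratio))
})

test_that("a digitized ellipsoid recovers the analytic volume within 2%", {
  mask <- digitize_ellipsoid(c(20, 15, 30), c(1, 1, 1))
  grid <- array(0L, dim(mask)); grid[mask] <- 1L
  m <- compartment_volumes(label_volume(grid, c(1, 1, 1)))
  analytic <- 4 / 3 * pi * 20 * 15 * 30 / 1000
  expect_lt(abs(m$rp_volume_cm3 / analytic - 1), 0.02)
})

test_that("left and right volumes add to the both-sides volume exactly", {
  ph <- generate_phantom(small_phantom_params(seed = 13))
  both <- compartment_volumes(ph$labels)
  l <- compartment_volumes(ph$labels, "left")
  r <- compartment_volumes(ph$labels, "right")
  expect_equal(l$rp_volume_cm3 + r$rp_volume_cm3, both$rp_volume_cm3)
  expect_equal(l$rsf_volume_cm3 + r$rsf_volume_cm3, both$rsf_volume_cm3)
})

test_that("side assignment uses component centroids with satellites to the nearest kidney", {
  dims <- c(30L, 12L, 12L)
  g <- array(0L, dims)
  g[3:10, 4:9, 4:9] <- 1L    # right body (low x)
  g[20:27, 4:9, 4:9] <- 1L   # left body (high x)
  g[16, 6, 6] <- 1L          # satellite, nearer the left centroid (x 23.5 vs 6.5)
  unsided <- label_volume(g, c(1, 1, 1),
                          data.frame(code = 0:1, role = c("background", "RP"),
                                     side = NA_character_))
  sided <- split_left_right(unsided)
  expect_true(all(sided$grid[3:10, 4:9, 4:9] == 1L))
  expect_true(all(sided$grid[20:27, 4:9, 4:9] == 2L))
  expect_equal(sided$grid[16, 6, 6], 2L)

  # a single body spanning the midline falls back to a plane split
  g2 <- array(0L, dims); g2[5:26, 4:9, 4:9] <- 1L
  un2 <- label_volume(g2, c(1, 1, 1),
                      data.frame(code = 0:1, role = c("background", "RP"),
                                 side = NA_character_))
  expect_warning(s2 <- split_left_right(un2), "midline")
  expect_true(all(s2$grid[5:15, 4:9, 4:9] == 1L))
  expect_true(all(s2$grid[16:26, 4:9, 4:9] == 2L))

  expect_error(split_left_right(label_volume(array(0L, dims), c(1, 1, 1))),
               "no RP")
})

test_that("single-slice estimates match whole-kidney on homogeneous cylinders", {
  vol <- make_cylinder_pair()
  whole <- compartment_volumes(vol)
  single <- single_slice_measures(vol)
  expect_equal(single$rsf_rp_ratio, whole$rsf_rp_ratio, tolerance = 1e-12)
})

test_that("hilum-peaked fat inflates the single-slice ratio above the whole-kidney ratio", {
  ph <- generate_phantom(small_phantom_params(hilum_concentration = 4, seed = 17))
  whole <- compartment_volumes(ph$labels)
  single <- single_slice_measures(ph$labels)
  expect_gt(single$rsf_rp_ratio, whole$rsf_rp_ratio)
  expect_lt(percent_difference(whole$rsf_rp_ratio, single$rsf_rp_ratio), 0)
})

test_that("the single-slice overestimate grows with hilum concentration", {
  deltas <- vapply(c(0, 2, 6), function(conc) {
    mean(vapply(1:5, function(s) {
      ph <- generate_phantom(small_phantom_params(hilum_concentration = conc,
                                                  seed = s))
      w <- compartment_volumes(ph$labels)
      percent_difference(w$rsf_rp_ratio,
                         single_slice_measures(ph$labels)$rsf_rp_ratio)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(deltas) < 0))  # more negative = larger overestimate
})

test_that("a kidney without fat scores ratio 0 on the slice chosen by RP alone", {
  vol <- make_cylinder_pair(rsf_radius_vox = 0)
  single <- single_slice_measures(vol)
  expect_equal(single$rsf_rp_ratio, 0)
  expect_gt(single$rp_volume_cm3, 0)
})

test_that("percentage differences follow the (reference - comparison)/comparison rule", {
  expect_equal(percent_difference(0.07, 0.10), -30)
  expect_equal(percent_difference(5, 5), 0)
  expect_true(is.na(percent_difference(1, 0)))
  d <- c(-20, -40, -60)
  expect_equal(mean(d), -40)
  expect_equal(sd(d), 20)
})
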