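test_that("constant volumes have zero vesselness", {
  v <- frangi_vesselness(volume_grid(array(5, c(10, 10, 10))))
  expect_equal(max(v$data), 0)
})

test_that("the vesselness peak of a noiseless tube lies inside the truth mask", {
  ph <- gen_tube_phantom(c(40, 40, 40), radii_mm = 2, noise_sd = 0, seed = 4)
  v <- frangi_vesselness(ph$volume)
  expect_true(ph$mask[which.max(v$data)])
  expect_true(all(v$data >= 0 & v$data <= 1))
})

test_that("tubes out-score spheres at equal contrast (blob rejection)", {
  ph <- gen_tube_phantom(c(40, 40, 40), radii_mm = 2, noise_sd = 0, seed = 4)
  v_tube <- frangi_vesselness(ph$volume)
  sph <- array(0, c(40, 40, 40))
  idx <- as.matrix(expand.grid(1:40, 1:40, 1:40))
  sph[rowSums(sweep(idx, 2, c(20, 20, 20))^2) <= 16] <- 1
  v_sph <- frangi_vesselness(volume_grid(sph))
  expect_gt(max(v_tube$data), max(v_sph$data))
})

test_that("vesselness is shift-invariant and 90-degree-rotation equivariant", {
  ph <- gen_tube_phantom(c(24, 24, 24), radii_mm = 2, seed = 4)
  v1 <- frangi_vesselness(ph$volume)
  shifted <- volume_grid(ph$volume$data + 10, ph$volume$voxel_size)
  v2 <- frangi_vesselness(shifted)
  expect_lt(max(abs(v1$data - v2$data)), 1e-9)

  rot <- function(a) aperm(a[, rev(seq_len(dim(a)[2])), , drop = FALSE], c(2, 1, 3))
  v_rot <- frangi_vesselness(volume_grid(rot(ph$volume$data)))
  seg_a <- v_rot$data >= 0.5
  seg_b <- rot(v1$data >= 0.5)
  dice <- 2 * sum(seg_a & seg_b) / (sum(seg_a) + sum(seg_b))
  expect_gte(dice, 0.8)
})

test_that("radius-2 tubes are segmented with Dice >= 0.5 in a noiseless phantom", {
  ph <- gen_tube_phantom(c(40, 40, 40), radii_mm = c(2, 2), noise_sd = 0, seed = 11)
  params <- frangi_params(threshold = 0.5)
  v <- frangi_vesselness(ph$volume, params)
  labels <- volume_grid(array(1L, dim(ph$mask)))
  seg <- segment_pvs(v, params, labels, icv_mm3 = 1.5e6)
  dice <- 2 * sum(seg$mask & ph$mask) / (sum(seg$mask) + sum(ph$mask))
  expect_gte(dice, 0.5)
})

test_that("PVS segmentation gates on labels and reports the volume fraction", {
  params <- frangi_params()
  zero_v <- volume_grid(array(0, c(10, 10, 10)))
  labels <- volume_grid(array(1L, c(10, 10, 10)))
  seg0 <- segment_pvs(zero_v, params, labels, icv_mm3 = 1.5e6)
  expect_equal(seg0$pvsvf, 0)
  expect_false(any(seg0$mask))

  # 10 suprathreshold 1-mm^3 voxels inside the label region
  v <- array(0, c(10, 10, 10))
  v[1:10, 1, 1] <- 1
  seg <- segment_pvs(volume_grid(v), params, labels, icv_mm3 = 1.5e6)
  expect_equal(seg$pvsvf, 10 / 1.5e6)

  # suprathreshold voxels outside the labels contribute nothing
  bg <- array(0L, c(10, 10, 10))
  bg[5, 5, 5] <- 1L
  seg_out <- segment_pvs(volume_grid(v), params, volume_grid(bg), icv_mm3 = 1.5e6)
  expect_equal(seg_out$pvsvf, 0)

  expect_error(segment_pvs(volume_grid(v), params, labels, icv_mm3 = -1), "positive")
})

test_that("default parameters follow the published conventions", {
  p <- frangi_params()
  expect_equal(p$alpha, 0.5)
  expect_equal(p$beta, 0.5)
  expect_identical(p$c, "auto")
  expect_equal(p$threshold, 2e-5)
  expect_equal(range(p$scales_vox), c(0.1, 5))
})

test_that("anisotropic voxels trigger a scale-interpretation warning", {
  vg <- volume_grid(array(rnorm(5^3), c(5, 5, 5)), voxel_size = c(1, 1, 3))
  expect_warning(frangi_vesselness(vg), "anisotropic")
})
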