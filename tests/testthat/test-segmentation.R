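test_that("MF and FDOG kernels have the stated symmetries and zero sum", {
  for (theta in c(0, pi / 12, pi / 4, pi / 3)) {
    k <- mf_kernel(2, 9, theta)
    expect_lt(abs(sum(k)), 1e-10, label = sprintf("mf theta %.2f", theta))
    d <- fdog_kernel(2, 9, theta)
    expect_lt(abs(sum(d)), 1e-10, label = sprintf("fdog theta %.2f", theta))
  }
  k0 <- mf_kernel(1.5, 7, 0)
  expect_equal(k0, k0[, ncol(k0):1])            # even across the vessel axis
  expect_equal(mf_kernel(1.5, 7, pi / 2), t(k0))  # 90-degree rotation = transpose

  d0 <- fdog_kernel(1.5, 7, 0)
  mid <- (ncol(d0) + 1) / 2
  expect_true(all(d0[, mid] == 0))              # vanishes on the vessel axis
  expect_equal(d0, -d0[, ncol(d0):1])           # odd across the vessel axis
})

test_that("MF response peaks on the centerline; FDOG local mean flags edges", {
  # vertical vein (constant column): the kernel at theta = 0 has its
  # cross-section axis along x, matching it
  sv <- straight_vein_image(side = 48, sigma_v = 2, depth = 100, theta = pi / 2,
                            len = 60)
  k <- mf_kernel(2, 9, 0)
  resp <- veinfuse:::conv_reflect(as_pixel_matrix(sv$image), k)
  expect_true(which.max(resp[24, ]) %in% c(24, 25))

  # step edge of the same contrast: FDOG responds strongly on the edge,
  # while on the vein centerline (the MF peak) it is near zero
  step <- gray_image(cbind(matrix(100L, 48, 24), matrix(200L, 48, 24)))
  d <- fdog_kernel(2, 9, 0)
  D_edge <- abs(veinfuse:::conv_reflect(as_pixel_matrix(step), d))
  D_vein <- abs(veinfuse:::conv_reflect(as_pixel_matrix(sv$image), d))
  ctr <- which.max(resp[24, ])                 # vein centerline column
  expect_gt(mean(D_edge[10:38, 24:25]), mean(D_vein[10:38, ctr]))
})

test_that("segmentation recovers a clean matched Gaussian vein", {
  spec <- phantom_spec(n_veins = 1, width_range = c(2, 2), depth = 60,
                       noise_sd = 0, gradient_amp = 0)
  ds <- generate_dataset(3, spec, seed = 4)
  for (x in ds) {
    sc <- seg_scores(confusion(segment_veins(x$image), x$mask))
    expect_gte(sc$dice, 0.8)
    expect_gte(sc$se, 0.9)
  }
})

test_that("orientation bank covers rotated veins", {
  ax <- straight_vein_image(side = 96, theta = 0)
  diag45 <- straight_vein_image(side = 96, theta = pi / 4)
  d0 <- seg_scores(confusion(segment_veins(ax$image), ax$mask))$dice
  d45 <- seg_scores(confusion(segment_veins(diag45$image), diag45$mask))$dice
  expect_gte(d0, 0.8)
  expect_lt(abs(d0 - d45), 0.1)
})

test_that("constant images give empty masks; offsets do not change the mask", {
  expect_true(all(unclass(segment_veins(gray_image(matrix(120L, 64, 64)))) == 0L))

  sv <- straight_vein_image(side = 48, bg = 180, theta = pi / 6)
  m1 <- segment_veins(sv$image)
  m2 <- segment_veins(gray_image(unclass(sv$image) + 20L))
  expect_identical(unclass(m1)[, ], unclass(m2)[, ])

  expect_error(segment_veins(gray_image(matrix(0L, 4, 4))), "smaller than kernel")
})

test_that("refinement removes small objects using 8-connectivity, never adds", {
  m <- matrix(0L, 64, 64)
  for (i in 1:40) m[10 + i, 10 + i] <- 1L       # diagonal chain, one 8-conn object
  m[50, 5:8] <- 1L                              # 4-pixel speck
  out <- veinfuse:::remove_small_objects(m, 30L)
  expect_equal(sum(out[cbind(11:50, 11:50)]), 40L)   # diagonal chain kept
  expect_true(all(out[50, 5:8] == 0L))               # speck removed
  expect_true(all(out <= m))                         # subset of the raw mask

  sv <- straight_vein_image(side = 48)
  p_raw <- mf_fodg_params(min_object = 1L)
  p_ref <- mf_fodg_params(min_object = 30L)
  raw <- segment_veins(sv$image, p_raw)
  ref <- segment_veins(sv$image, p_ref)
  expect_true(all(unclass(ref) <= unclass(raw)))
})

test_that("isodata threshold converges to the two-class mean fixed point", {
  img <- gray_image(matrix(c(rep(50L, 100), rep(200L, 100)), 20, 10))
  expect_equal(isodata_threshold(img), 125)
  img2 <- gray_image(matrix(c(rep(0L, 50), rep(255L, 50)), 10, 10))
  expect_equal(isodata_threshold(img2), 127.5)
  expect_error(isodata_threshold(gray_image(matrix(9L, 3, 3))), "degenerate")
})
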