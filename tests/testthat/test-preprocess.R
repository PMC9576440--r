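test_that("gaussian smoothing preserves constants, mass and reduces variance", {
  expect_equal(gaussian_smooth(matrix(42, 20, 20), 3),
               matrix(42, 20, 20), tolerance = 1e-12)

  # unit impulse: center equals the squared peak of the normalized 1D kernel
  imp <- matrix(0, 41, 41); imp[21, 21] <- 1
  sm <- gaussian_smooth(imp, 3)
  r <- ceiling(3.5 * 3)
  g <- dnorm(-r:r, 0, 3); g <- g / sum(g)
  expect_equal(sm[21, 21], max(g)^2, tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-9)

  # noisy phantom slice: variance strictly drops, mean nearly preserved
  case <- small_phantom(seed = 2)
  sl <- case$image$voxels[, , 3]
  smsl <- gaussian_smooth(sl, 3)
  expect_lt(var(as.vector(smsl)), var(as.vector(sl)))
  expect_lt(abs(mean(smsl) - mean(sl)) / abs(mean(sl)), 0.005)

  expect_error(gaussian_smooth(sl, 0), "sigma")
})

test_that("locate_body finds the largest connected domain and pads it", {
  # toy: two components, the small one (table artifact) must be ignored
  toy <- matrix(-1000, 100, 100)
  toy[30:79, 20:89] <- 40      # body, 50x70 = 3500 px
  toy[95:97, 40:60] <- 300     # table, 63 px
  tf <- locate_body(toy, preprocess_config(margin = 0, opening_radius = 0))
  expect_equal(tf$bbox, c(30L, 79L, 20L, 89L))

  expect_error(locate_body(matrix(-1000, 64, 64)), "no body found")
})

test_that("the located box contains every ground-truth lung voxel", {
  cfg <- preprocess_config(out_size = 128)
  for (seed in c(4, 21)) {
    case <- small_phantom(seed = seed)
    sm <- gaussian_smooth_volume(case$image, cfg$sigma)
    tf <- locate_body(sm, cfg)
    lung <- which(case$mask$voxels == 1, arr.ind = TRUE)
    expect_true(all(lung[, 1] >= tf$bbox[1] & lung[, 1] <= tf$bbox[2]))
    expect_true(all(lung[, 2] >= tf$bbox[3] & lung[, 2] <= tf$bbox[4]))
  }
})

test_that("crop_and_zoom hits the target size and keeps masks binary", {
  case <- small_phantom(seed = 6, slice_size = 512, n_slices = 3)
  cfg <- preprocess_config()   # out_size 256
  pp <- preprocess_case(case$image, case$mask, cfg)
  expect_equal(dim(pp$image), c(256, 256, 3))
  expect_true(all(pp$mask$voxels %in% c(0, 1)))

  expect_error(crop_and_zoom(case$image,
                             transform = crop_transform(c(1, 64, 1, 64),
                                                        c(64, 64), 128)),
               "shape mismatch")
})

test_that("forward and inverse transforms round-trip masks at Dice >= 0.98", {
  cfg <- preprocess_config(out_size = 128)
  for (seed in c(8, 15)) {
    case <- small_phantom(seed = seed)
    pp <- preprocess_case(case$image, case$mask, cfg)
    back <- invert_transform(pp$mask, pp$transform)
    expect_gte(score_case(case$mask, back)$dice, 0.98)
    # support confined to the box
    outside <- back$voxels
    outside[pp$transform$bbox[1]:pp$transform$bbox[2],
            pp$transform$bbox[3]:pp$transform$bbox[4], ] <- 0
    expect_equal(sum(outside), 0)
  }
})

test_that("invert_transform handles degenerate masks exactly", {
  tf <- crop_transform(c(11, 40, 21, 60), c(100, 100), 64)
  zero <- invert_transform(array(0, c(64, 64, 2)), tf)
  expect_equal(sum(zero$voxels), 0)
  one <- invert_transform(array(1, c(64, 64, 2)), tf)
  expect_equal(sum(one$voxels), 30 * 40 * 2)
  expect_true(all(one$voxels[11:40, 21:60, ] == 1))
})
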