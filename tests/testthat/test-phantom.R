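test_that("phantom generation is deterministic and obeys its geometry contract", {
  sp <- phantom_spec(n_slices = 6, slice_size = 256, chest_fraction = 0.18,
                     seed = 11)
  a <- generate_phantom_case(sp)
  b <- generate_phantom_case(sp)
  expect_identical(a$image$voxels, b$image$voxels)
  expect_identical(a$mask$voxels, b$mask$voxels)
  expect_identical(a$defect_log, b$defect_log)

  # image and mask aligned; lungs only inside the body ellipse
  expect_identical(dim(a$image), dim(a$mask))
  mid <- dim(a$image)[3] %/% 2
  expect_lt(measure_body_fraction(a$image$voxels[, , mid]), 0.20)

  # background near air, lungs near -800, body near soft tissue
  clean <- clean_phantom(seed = 11)
  sl <- clean$image$voxels[, , 3]
  expect_equal(sl[1, 1], -1000)
  expect_equal(mean(sl[clean$mask$voxels[, , 3] == 1]), -800)
})

test_that("pristine ground truth has exactly two 3D lung components", {
  for (seed in c(1, 7, 23)) {
    case <- small_phantom(seed = seed)
    cc <- label_components_3d(case$mask, connectivity = 26)
    expect_equal(nrow(cc$components), 2)
    # both lungs span the full slice range (tapered, never absent)
    expect_true(all(cc$components$slice_min == 1))
    expect_true(all(cc$components$slice_max == dim(case$mask)[3]))
  }
})

test_that("a defect-free spec yields an empty defect log", {
  case <- clean_phantom(seed = 5)
  expect_equal(nrow(case$defect_log), 0)
  expect_identical(case$mask$voxels, case$degraded_mask$voxels)
})

test_that("streak artifacts corrupt the image linearly, never the mask", {
  case <- clean_phantom(seed = 9)
  expect_identical(add_streak_artifacts(case, 0)$image$voxels,
                   case$image$voxels)

  a <- add_streak_artifacts(case, 200, seed = 4)
  expect_identical(a$mask$voxels, case$mask$voxels)
  diffs <- abs(a$image$voxels - case$image$voxels)
  expect_gte(max(diffs), 100)
  expect_true(all(a$defect_log$kind == "streak"))

  # monotone: larger amplitude strictly increases the mean perturbation
  b <- add_streak_artifacts(case, 100, seed = 4)
  affected <- unique(a$defect_log$slice)
  pert <- function(x) mean(abs(x$image$voxels[, , affected] -
                                 case$image$voxels[, , affected]))
  expect_identical(unique(b$defect_log$slice), affected)
  expect_gt(pert(a), pert(b))

  expect_error(add_streak_artifacts(case, -5), "level")
})

test_that("breath-hold dropout removes voxels from the degraded mask only", {
  case <- clean_phantom(seed = 13, n_slices = 10)
  expect_equal(nrow(add_breath_hold_dropout(case, 0)$defect_log), 0)

  all_d <- add_breath_hold_dropout(case, 1, seed = 2)
  expect_equal(sort(unique(all_d$defect_log$slice)), 1:10)
  # pristine mask untouched; degraded is a strict voxelwise subset
  expect_identical(all_d$mask$voxels, case$mask$voxels)
  expect_true(all(all_d$degraded_mask$voxels <= all_d$mask$voxels))
  expect_lt(sum(all_d$degraded_mask$voxels), sum(all_d$mask$voxels))
  # dropped regions now look like soft tissue, not aerated lung
  dropped <- all_d$mask$voxels == 1 & all_d$degraded_mask$voxels == 0
  expect_gt(mean(all_d$image$voxels[dropped]), -200)

  expect_error(add_breath_hold_dropout(case, 1.2), "p")
})

test_that("invalid phantom parameters are rejected by field name", {
  expect_error(phantom_spec(n_slices = 0), "n_slices")
  expect_error(phantom_spec(chest_fraction = 1.2), "chest_fraction")
  expect_error(phantom_spec(dropout_probability = -0.1),
               "dropout_probability")
  expect_error(phantom_spec(noise_sigma = -1), "noise_sigma")
})
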