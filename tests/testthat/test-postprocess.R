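test_that("3D labeling matches a brute-force flood-fill oracle", {
  # three disjoint boxes of known volumes
  m <- array(0, c(12, 12, 5))
  m[2:6, 2:5, 1:5] <- 1     # 100 voxels
  m[8:11, 8:11, 1:5] <- 1   # 80 voxels
  m[1, 12, 1:5] <- 1        # 5 voxels
  cc <- label_components_3d(m, 26)
  expect_equal(cc$components$volume, c(100, 80, 5))

  set.seed(10)
  for (conn in c(6, 26)) {
    r <- array(rbinom(10 * 10 * 10, 1, 0.2), c(10, 10, 10))
    mine <- label_components_3d(r, conn)
    oracle <- oracle_label3d(r, conn)
    # same partition: number of components and identical co-membership
    expect_equal(nrow(mine$components), max(oracle))
    expect_equal(sort(mine$components$volume, decreasing = TRUE),
                 sort(tabulate(oracle[oracle > 0]), decreasing = TRUE))
    # labels agree up to renaming
    fg <- which(r == 1)
    expect_equal(length(unique(paste(mine$labels[fg], oracle[fg]))),
                 max(oracle))
  }
})

test_that("corner-touching boxes merge under 26- but not 6-connectivity", {
  m <- array(0, c(6, 6, 6))
  m[1:3, 1:3, 1:3] <- 1
  m[4:6, 4:6, 4:6] <- 1
  expect_equal(nrow(label_components_3d(m, 26)$components), 1)
  expect_equal(nrow(label_components_3d(m, 6)$components), 2)
})

test_that("labeling rejects invalid inputs", {
  expect_error(label_components_3d(array(2, c(3, 3, 3))), "binary")
  expect_error(label_components_3d(array(1, c(3, 3, 3)), connectivity = 8),
               "connectivity")
  empty <- label_components_3d(array(0, c(3, 3, 3)))
  expect_equal(nrow(empty$components), 0)
})

test_that("case filter keeps the two true lungs and removes edge blobs", {
  case <- clean_phantom(seed = 17)
  cfg <- preprocess_config(out_size = 128)
  pp <- preprocess_case(case$image, case$mask, cfg)
  m <- pp$mask$voxels
  # inject 5 small false-positive blobs near the frame edge
  withr::with_seed(1, {
    for (k in 1:5) {
      z <- sample(dim(m)[3], 1)
      corner <- sample(4, 1)
      r0 <- if (corner %in% c(1, 2)) 2 else dim(m)[1] - 4
      c0 <- if (corner %in% c(1, 3)) 2 else dim(m)[2] - 4
      m[r0:(r0 + 2), c0:(c0 + 2), z] <- 1
    }
  })
  filt <- case_filter(m, location_prior = 0.8)
  cc <- label_components_3d(filt)
  expect_equal(nrow(cc$components), 2)
  expect_identical(filt$voxels, pp$mask$voxels)  # exactly the true lungs
  # the filter only removes voxels
  expect_true(all(filt$voxels <= m))
})

test_that("case filter is idempotent and handles degenerate inputs", {
  case <- clean_phantom(seed = 19)
  pp <- preprocess_case(case$image, case$mask,
                        preprocess_config(out_size = 128))
  once <- case_filter(pp$mask$voxels)
  twice <- case_filter(once$voxels)
  expect_identical(once$voxels, twice$voxels)

  # single central component is retained as-is
  single <- array(0, c(20, 20, 3))
  single[8:12, 8:12, ] <- 1
  expect_identical(case_filter(single)$voxels, single)

  # empty input: empty output plus a warning
  expect_warning(out <- case_filter(array(0, c(10, 10, 2))), "empty")
  expect_equal(sum(out$voxels), 0)

  # peripheral-only components are all rejected, with a warning
  edge <- array(0, c(40, 40, 2))
  edge[1:2, 1:2, ] <- 1
  expect_warning(out2 <- case_filter(edge, location_prior = 0.5),
                 "centrally")
  expect_equal(sum(out2$voxels), 0)
})
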