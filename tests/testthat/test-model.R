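test_that("a residual block concatenates input with convolved channels", {
  blk <- res_block_params(in_channels = 16, channels = 16, seed = 1)
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  out <- res_block(x, blk)
  expect_equal(dim(out), c(8, 8, 32))
  # the first 16 channels are the untouched input
  expect_identical(out[, , 1:16], x)

  # spatial size is preserved for a non-square input too
  x2 <- array(rnorm(16 * 8 * 4 * 2), c(16, 8, 4, 2))
  blk2 <- res_block_params(4, 6, seed = 2)
  expect_equal(dim(res_block(x2, blk2)), c(16, 8, 10, 2))

  expect_error(res_block(x, blk2), "channels")
})

test_that("the network produces probability maps of the input size", {
  net <- build_resunet(model_config(base_channels = 4, depth = 2,
                                    dropout_rate = 0), seed = 3)
  x <- array(runif(64 * 64), c(64, 64, 1, 1))
  out <- resunet_forward(net, x)$prob
  expect_equal(dim(out), c(64, 64, 1, 1))
  expect_true(all(out >= 0 & out <= 1))

  # input not divisible by 2^depth is a configuration error
  bad <- array(runif(30 * 30), c(30, 30, 1, 1))
  expect_error(resunet_forward(net, bad), "configuration error")
})

test_that("evaluation mode is deterministic even with dropout configured", {
  net <- build_resunet(model_config(base_channels = 4, depth = 2,
                                    dropout_rate = 0.5), seed = 4)
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(resunet_forward(net, x, "eval")$prob,
                   resunet_forward(net, x, "eval")$prob)
})

test_that("concatenating blocks hold more parameters than plain blocks", {
  res <- build_resunet(model_config(base_channels = 4, depth = 2), seed = 1)
  plain <- build_resunet(model_config(base_channels = 4, depth = 2,
                                      residual = FALSE), seed = 1)
  expect_gt(count_parameters(res), count_parameters(plain))

  # channel audit of the construction plan: out = in + convolved
  for (d in seq_along(res$plan$enc)) {
    lvl <- res$plan$enc[[d]]
    expect_equal(lvl$out, lvl$cin + lvl$m)
  }
})

test_that("backpropagation matches finite differences through the whole net", {
  # linear activation removes the ReLU kink so finite differences are clean
  net <- build_resunet(model_config(base_channels = 2, depth = 1,
                                    dropout_rate = 0, leaky_slope = 1),
                       seed = 7)
  set.seed(5)
  x <- array(runif(8 * 8 * 2), c(8, 8, 1, 2))
  y <- array(rbinom(128, 1, 0.3), c(8, 8, 1, 2))
  cfg <- loss_config()
  fw <- resunet_forward(net, x, "train", want_cache = TRUE)
  df <- combined_loss_grad(y, fw$prob, cfg)
  dz <- df * fw$prob * (1 - fw$prob)
  G <- new.env()
  pedlungseg:::resunet_backward(net, dz, fw$cache, G)
  h <- 1e-5
  worst <- 0
  for (nm in ls(G)) {
    p <- net$P[[nm]]
    for (i in head(seq_along(p), 3)) {
      net$P[[nm]][i] <- p[i] + h
      lp <- combined_loss(y, resunet_forward(net, x, "train")$prob, cfg)
      net$P[[nm]][i] <- p[i] - h
      lm <- combined_loss(y, resunet_forward(net, x, "train")$prob, cfg)
      net$P[[nm]][i] <- p[i]
      num <- (lp - lm) / (2 * h)
      worst <- max(worst, abs(num - G[[nm]][i]) /
                            max(abs(num), abs(G[[nm]][i]), 1e-6))
    }
  }
  expect_lt(worst, 1e-4)
})

test_that("predict_case thresholds probability maps into stacked masks", {
  net <- build_resunet(model_config(base_channels = 2, depth = 1,
                                    dropout_rate = 0), seed = 9)
  vol <- ct_volume(array(rnorm(32 * 32 * 3, -500, 300), c(32, 32, 3)))
  # extreme thresholds give the trivial masks
  expect_equal(sum(predict_case(net, vol, threshold = 1 - 1e-12)$voxels), 0)
  expect_equal(sum(predict_case(net, vol, threshold = 1e-12)$voxels),
               32 * 32 * 3)
  m <- predict_case(net, vol, threshold = 0.5)
  expect_true(all(m$voxels %in% c(0, 1)))

  wrong <- ct_volume(array(0, c(31, 31, 2)))
  expect_error(predict_case(net, wrong), "configuration error")
})

test_that("checkpoints round-trip through save and load", {
  net <- build_resunet(model_config(base_channels = 2, depth = 1,
                                    dropout_rate = 0), seed = 11)
  x <- array(runif(16 * 16), c(16, 16, 1, 1))
  before <- resunet_forward(net, x)$prob
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(net, path)
  net2 <- load_model(path)
  expect_equal(net2$cfg, net$cfg)
  expect_identical(resunet_forward(net2, x)$prob, before)
})
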