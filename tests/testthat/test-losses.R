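test_that("dice loss matches its analytic anchors", {
  e <- matrix(0, 8, 8); e[3:4, 3:4] <- 1
  expect_equal(dice_loss(e, e, smooth = 0), 0)

  f <- matrix(0, 8, 8); f[6:7, 6:7] <- 1
  expect_equal(dice_loss(e, f, smooth = 0), 1)

  # 4 vs 4 positives with 2 shared: 1 - 2*2/(4+4) = 0.5
  e2 <- matrix(0, 4, 4); e2[1, 1:4] <- 1
  f2 <- matrix(0, 4, 4); f2[1, 3:4] <- 1; f2[2, 1:2] <- 1
  expect_equal(dice_loss(e2, f2, smooth = 0), 0.5)

  expect_error(dice_loss(e, matrix(0.5, 4, 4)), "shape mismatch")
  expect_error(dice_loss(e, matrix(2, 8, 8)), "\\[0, 1\\]")
})

test_that("dice loss is monotone in correctly predicted positives", {
  set.seed(1)
  e <- matrix(rbinom(100, 1, 0.4), 10, 10)
  f <- matrix(runif(100), 10, 10) * e    # predictions only on positives
  l0 <- dice_loss(e, f)
  wrong <- which(e == 1 & f < 1)
  for (i in head(wrong, 5)) {
    f[i] <- 1
    l1 <- dice_loss(e, f)
    expect_lte(l1, l0)
    l0 <- l1
  }
})

test_that("focal loss matches a hand-computed single-pixel oracle", {
  # one positive pixel, prediction 0.9: -0.25 * 0.1^2 * log(0.9)
  expect_equal(focal_loss(matrix(1), matrix(0.9), alpha = 0.25, gamma = 2),
               -0.25 * 0.1^2 * log(0.9))
  # vanishing loss in the confident limit
  e <- matrix(c(1, 1, 0, 0), 2, 2)
  f <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_lt(focal_loss(e, f), 1e-5)
})

test_that("focal loss with gamma 0, alpha 0.5 halves the cross-entropy", {
  set.seed(7)
  for (i in 1:100) {
    e <- matrix(rbinom(36, 1, runif(1, 0.2, 0.8)), 6, 6)
    f <- matrix(runif(36, 0.01, 0.99), 6, 6)
    bce <- -mean(e * log(f) + (1 - e) * log(1 - f))
    expect_equal(focal_loss(e, f, alpha = 0.5, gamma = 0), 0.5 * bce,
                 tolerance = 1e-6)
  }
})

test_that("combined loss arithmetic follows its definition", {
  cfg <- loss_config()
  expect_equal(cfg$alpha_combined, 0.3)

  # disjoint masks: L_Dice -> 1, log term vanishes, total equals focal part
  e <- matrix(0, 8, 8); e[1:2, 1:2] <- 1
  f <- matrix(0, 8, 8); f[7:8, 7:8] <- 1
  cfg0 <- loss_config(smooth = 0)
  expect_equal(combined_loss(e, f, cfg0), focal_loss(e, f))

  # clamped regime: perfect overlap pins the dice term at log(log_floor)
  expect_equal(combined_loss(e, e, cfg0),
               0.3 * log(1e-4) + focal_loss(e, e))
})

test_that("analytic loss gradients match finite differences within 1e-4", {
  set.seed(3)
  e <- matrix(rbinom(4, 1, 0.5), 2, 2)
  f <- matrix(runif(4, 0.15, 0.85), 2, 2)
  cfg <- loss_config()
  checks <- list(
    dice = list(function(x) dice_loss(e, x),
                dice_loss_grad(e, f)),
    focal = list(function(x) focal_loss(e, x),
                 focal_loss_grad(e, f)),
    combined = list(function(x) combined_loss(e, x, cfg),
                    combined_loss_grad(e, f, cfg)))
  for (nm in names(checks)) {
    num <- numeric_grad(checks[[nm]][[1]], f)
    an <- checks[[nm]][[2]]
    expect_lt(max(abs(num - an) / pmax(abs(num), 1e-8)), 1e-4)
  }
})
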