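test_that("confusion counts match a brute-force voxel loop", {
  set.seed(8)
  e <- array(rbinom(1000, 1, 0.3), c(10, 10, 10))
  f <- array(rbinom(1000, 1, 0.3), c(10, 10, 10))
  cc <- confusion(e, f)
  tally <- c(tp = 0, tn = 0, fp = 0, fn = 0)
  for (i in seq_along(e)) {
    key <- if (e[i] == 1 && f[i] == 1) "tp" else
           if (e[i] == 0 && f[i] == 0) "tn" else
           if (e[i] == 0) "fp" else "fn"
    tally[key] <- tally[key] + 1
  }
  expect_equal(unlist(cc[c("tp", "tn", "fp", "fn")]), tally)
  expect_equal(cc$tp + cc$tn + cc$fp + cc$fn, length(e))

  # identical masks: pure tp/tn
  cc2 <- confusion(e, e)
  expect_equal(cc2$tp, sum(e))
  expect_equal(cc2$tn, sum(e == 0))
  expect_equal(cc2$fp + cc2$fn, 0)

  expect_error(confusion(e, array(0, c(5, 5, 5))), "shape mismatch")
})

test_that("case metrics follow their defining formulas and conventions", {
  m <- case_metrics(list(tp = 9, tn = 100, fp = 1, fn = 1))
  expect_equal(m$precision, 0.9)
  expect_equal(m$recall, 0.9)
  expect_equal(m$iou, 9 / 11)
  expect_equal(m$dice, 18 / 20)

  perfect <- score_case(array(c(0, 1, 1, 0), c(2, 2, 1)),
                        array(c(0, 1, 1, 0), c(2, 2, 1)))
  expect_equal(unlist(perfect[c("iou", "dice", "precision", "recall")]),
               c(iou = 1, dice = 1, precision = 1, recall = 1))

  # empty vs empty scores 1 on all metrics; empty vs nonempty scores 0
  ee <- case_metrics(list(tp = 0, tn = 8, fp = 0, fn = 0))
  expect_true(all(unlist(ee[c("iou", "dice", "precision", "recall")]) == 1))
  en <- score_case(array(1, c(2, 2, 2)), array(0, c(2, 2, 2)))
  expect_equal(en$dice, 0)
  expect_equal(en$recall, 0)
})

test_that("dice and iou obey their algebraic identity on random cases", {
  set.seed(12)
  for (i in 1:20) {
    e <- array(rbinom(512, 1, runif(1, 0.1, 0.6)), c(8, 8, 8))
    f <- array(rbinom(512, 1, runif(1, 0.1, 0.6)), c(8, 8, 8))
    m <- score_case(e, f)
    expect_equal(m$dice, 2 * m$iou / (1 + m$iou), tolerance = 1e-9)
    # symmetry: precision(e, f) = recall(f, e)
    m2 <- score_case(f, e)
    expect_equal(m$precision, m2$recall)
    expect_equal(m$iou, m2$iou)
  }
})

test_that("aggregation is the unweighted mean over cases", {
  a <- case_metrics(list(tp = 96, tn = 0, fp = 4, fn = 4), "c1")  # dice 0.96
  b <- case_metrics(list(tp = 98, tn = 0, fp = 2, fn = 2), "c2")  # dice 0.98
  avg <- aggregate_metrics(list(a, b))
  expect_equal(avg$dice, (a$dice + b$dice) / 2)

  expect_equal(aggregate_metrics(list(a))$iou, a$iou)
  expect_error(aggregate_metrics(list()), "no cases")

  # independent second summation path on random metrics
  set.seed(4)
  ms <- lapply(1:12, function(i)
    case_metrics(list(tp = rpois(1, 50) + 1, tn = rpois(1, 50),
                      fp = rpois(1, 5), fn = rpois(1, 5)),
                 sprintf("c%d", i)))
  avg12 <- aggregate_metrics(ms)
  expect_equal(avg12$dice, sum(vapply(ms, `[[`, 0, "dice")) / 12,
               tolerance = 1e-12)

  tab <- metrics_table(ms)
  expect_equal(nrow(tab), 13)
  expect_equal(tab$case_id[13], "Average")
})
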