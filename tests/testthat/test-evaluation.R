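test_that("bounding-box IoU matches direct rectangle arithmetic", {
  a <- box_instance(0, 0, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(iou(a, box_instance(10, 10, 2)), 0)
  expect_equal(iou(a, box_instance(1, 1, 2)), 1 / 7)   # 4 + 4 - 1
  expect_equal(iou(a, box_instance(1, 1, 2)),
               iou(box_instance(1, 1, 2), a))          # symmetric
  # mask mode on identical and disjoint geometry
  expect_equal(iou(a, a, "mask"), 1)
  expect_equal(iou(a, box_instance(10, 10, 2), "mask"), 0)
  expect_lt(iou(a, box_instance(1, 1, 2), "mask"), 1)
})

test_that("greedy matching produces the specified tallies", {
  gts <- lapply(seq_len(3), function(i) box_instance(4 * i, 0, 2))
  expect_s3_class(m <- match_instances(gts, gts), "match_tally")
  expect_equal(c(m$TP, m$FP, m$FN), c(3L, 0L, 0L))
  # an extra spurious prediction is an FP and consumes no ground truth
  preds <- c(gts, list(box_instance(40, 40, 2)))
  m2 <- match_instances(preds, gts)
  expect_equal(c(m2$TP, m2$FP, m2$FN), c(3L, 1L, 0L))
  # a missed ground truth is an FN
  m3 <- match_instances(gts[1:2], gts)
  expect_equal(c(m3$TP, m3$FP, m3$FN), c(2L, 0L, 1L))
  # IoU exactly at the threshold counts as FP
  half <- instance_polygon(cbind(c(0, 2, 2, 0), c(0, 0, 1, 1)), "crown")
  m4 <- match_instances(list(half), list(box_instance(0, 0, 2)))
  expect_equal(c(m4$TP, m4$FP, m4$FN), c(0L, 1L, 1L))
  expect_error(match_instances(list(box_instance(0, 0, 2, "shadow")), gts),
               "mixed class")
})

test_that("tally conservation holds and greedy equals brute-force optimum", {
  set.seed(41)
  for (k in 1:40) {
    ng <- sample(1:5, 1)
    gts <- lapply(seq_len(ng), function(i)
      box_instance(runif(1, 0, 20), runif(1, 0, 20), 3))
    # jittered copies of a subset, plus possible spurious boxes
    keep <- which(runif(ng) < 0.8)
    preds <- lapply(keep, function(i) {
      v <- gts[[i]]$vertices + matrix(runif(2, -1, 1), 4, 2, byrow = TRUE)
      instance_polygon(v, "crown", confidence = runif(1))
    })
    if (runif(1) < 0.5)
      preds <- c(preds, list(box_instance(runif(1, 30, 40), 0, 3,
                                          confidence = runif(1))))
    m <- match_instances(preds, gts)
    expect_equal(m$TP + m$FN, ng)
    expect_equal(m$TP + m$FP, length(preds))
    M <- matrix(0, length(preds), ng)
    if (length(preds))
      for (i in seq_along(preds)) for (j in seq_len(ng))
        M[i, j] <- iou(preds[[i]], gts[[j]])
    expect_equal(m$TP, brute_force_tp(M, 0.5))
  }
})

test_that("precision, recall and F1 reproduce every reported tally row", {
  m <- precision_recall_f1(list(TP = 114L, FP = 2L, FN = 6L))
  expect_equal(m$precision, 114 / 116)
  expect_equal(m$recall, 0.95)
  expect_lte(abs(round(m$f1, 4) - 0.9660), 1e-4 + 1e-9)  # printed truncated
  p <- precision_recall_f1(list(TP = 120L, FP = 0L, FN = 0L))
  expect_equal(c(p$precision, p$recall, p$f1), c(1, 1, 1))
  s <- precision_recall_f1(list(TP = 111L, FP = 0L, FN = 9L))
  expect_equal(c(s$precision, round(s$recall, 4), round(s$f1, 4)),
               c(1, 0.9250, 0.9610))
  z <- precision_recall_f1(list(TP = 0L, FP = 0L, FN = 0L))
  expect_equal(c(z$precision, z$recall, z$f1), c(0, 0, 0))
  # f1 never exceeds the larger of precision and recall
  set.seed(13)
  for (k in 1:30) {
    t <- list(TP = sample(0:50, 1), FP = sample(0:20, 1), FN = sample(0:20, 1))
    r <- precision_recall_f1(t)
    expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
  }
})

test_that("the metrics table mirrors the report layout and writes files", {
  tallies <- list(`NDVI-13` = list(TP = 114L, FP = 2L, FN = 6L),
                  `RGB-3` = list(TP = 120L, FP = 0L, FN = 0L))
  path <- withr::local_tempfile(fileext = ".csv")
  tab <- metrics_table(tallies, path)
  expect_equal(names(tab), c("TestingSubset", "TP", "FP", "FN",
                             "Precision", "Recall", "F1"))
  expect_equal(nrow(utils::read.csv(path)), 2L)
})
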