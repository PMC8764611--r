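test_that("binarize uses an inclusive threshold and rejects bad thresholds", {
  p <- matrix(0.5, 4, 4)
  expect_equal(binarize(p, 0.5), matrix(1L, 4, 4))
  expect_equal(binarize(matrix(0.99, 4, 4), 0.999), matrix(0L, 4, 4))
  expect_error(binarize(p, 0), "in \\(0, 1\\)")
  expect_error(binarize(p, 1), "in \\(0, 1\\)")
  # mask cardinality is non-increasing in the threshold
  withr::with_seed(4, {
    for (r in 1:20) {
      pm <- matrix(runif(64), 8, 8)
      sizes <- vapply(seq(0.05, 0.95, by = 0.05),
                      function(t) sum(binarize(pm, t)), numeric(1))
      expect_true(all(diff(sizes) <= 0))
    }
  })
})

test_that("IoU applies the empty-mask conventions exactly", {
  z <- matrix(0, 8, 8)
  ee <- iou(z, z)
  expect_identical(ee$value, 1)
  expect_identical(ee$case, "empty_empty")
  spur <- z; spur[3, 3] <- 1
  so <- iou(spur, z)
  expect_identical(so$value, 0)
  expect_identical(so$case, "spurious_on_normal")
  m <- rand_mask(8, 0.5)
  m[1, 1] <- 1
  expect_equal(iou(m, m)$value, 1)
  # one predicted pixel, truth has it plus a neighbour: 1/2
  pred <- z; pred[4, 4] <- 1
  truth <- pred; truth[4, 5] <- 1
  expect_equal(iou(pred, truth)$value, 0.5)
  expect_error(iou(matrix(0, 4, 4), z), "same grid")
  expect_error(iou(matrix(2, 8, 8), z), "only 0 and 1")
})

test_that("IoU matches the exhaustive pixel-set oracle on random masks", {
  withr::with_seed(11, {
    for (r in seq_len(2000)) {
      pred <- rand_mask(8, runif(1, 0, 0.6))
      truth <- rand_mask(8, runif(1, 0, 0.6))
      expect_identical(iou(pred, truth)$value, iou_oracle(pred, truth))
    }
  })
})

test_that("mean IoU is the arithmetic mean and rejects empty input", {
  as_scores <- function(v) lapply(v, function(x) list(value = x))
  expect_equal(mean_iou(as_scores(c(1, 1))), 1)
  expect_equal(mean_iou(as_scores(c(1, 0))), 0.5)
  expect_equal(mean_iou(as_scores(c(0.5, 0.25, 0.75, 1))), 0.625)
  expect_equal(mean_iou(c(0.5, 0.25, 0.75, 1)), 0.625)
  expect_error(mean_iou(list()), "empty")
})

test_that("detection scores and slice classification follow the inclusive rule", {
  expect_equal(detection_score(matrix(0, 16, 16)), 0)
  expect_equal(detection_score(matrix(1, 16, 16)), 1)
  m <- matrix(0, 256, 256); m[seq_len(656)] <- 1
  expect_equal(detection_score(m), 656 / 65536)
  expect_identical(classify_slices(c(0.2), 0.2), "ascites")  # equal => ascites
  expect_identical(classify_slices(c(0.1, 0.5), 0), c("ascites", "ascites"))
  # declared set shrinks monotonically as the threshold rises
  withr::with_seed(5, {
    s <- runif(50)
    prev <- rep(TRUE, 50)
    for (t in sort(runif(20))) {
      cur <- classify_slices(s, t) == "ascites"
      expect_true(all(prev | !cur))
      prev <- cur
    }
  })
})

test_that("ROC endpoints, monotonicity and degenerate cases behave", {
  r <- roc_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_equal(r$auroc, 1)
  expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
  expect_equal(tail(r$fpr, 1), 1); expect_equal(tail(r$tpr, 1), 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  expect_equal(roc_curve(rep(0.4, 10), rep(c(0, 1), 5))$auroc, 0.5)
  expect_equal(roc_curve(c(0.9, 0.8, 0.85, 0.1), c(1, 1, 0, 0))$auroc, 0.75)
  expect_error(roc_curve(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("trapezoidal AUROC equals the pair-concordance statistic", {
  withr::with_seed(21, {
    for (r in seq_len(300)) {
      n <- sample(4:25, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), sample(c(1, 2, 7), 1))  # induce ties often
      expect_equal(roc_curve(scores, labels)$auroc,
                   auroc_oracle(scores, labels))
    }
  })
})

test_that("our AUROC agrees with pROC on random score sets", {
  skip_if_not_installed("pROC")
  withr::with_seed(31, {
    for (r in seq_len(25)) {
      n <- sample(10:40, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- round(runif(n), 2)
      ref <- suppressMessages(as.numeric(pROC::auc(labels, scores,
                                                   direction = "<")))
      expect_equal(roc_curve(scores, labels)$auroc, ref)
    }
  })
})

test_that("confusion counts partition the sample and invert symmetrically", {
  cm <- confusion(c(1, 1, 0, 0, 1), c(1, 0, 0, 1, 1))
  expect_equal(unclass(cm)[c("TP", "FN", "TN", "FP")],
               list(TP = 2, FN = 1, TN = 1, FP = 1))
  expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, 5)
  all_right <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(all_right$FP + all_right$FN, 0)
  truth <- c(1, 1, 0, 0, 1); pred <- c(1, 0, 0, 1, 1)
  inv <- confusion(truth, 1 - pred)
  expect_equal(inv$TP, cm$FN); expect_equal(inv$FN, cm$TP)
  expect_equal(inv$TN, cm$FP); expect_equal(inv$FP, cm$TN)
})

test_that("detection metrics follow the printed formulas and guard denominators", {
  m <- detection_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_true(all(unlist(m) == 1))
  m <- detection_metrics(list(TP = 9, FP = 1, TN = 8, FN = 2))
  expect_equal(m$sensitivity, 9 / 11)
  expect_equal(m$specificity, 8 / 9)
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(m$precision, 9 / 10)
  expect_equal(m$balanced_accuracy, (9 / 11 + 8 / 9) / 2)
  expect_equal(m$f1, 2 * (9 / 11) * (9 / 10) / (9 / 11 + 9 / 10))
  expect_error(detection_metrics(list(TP = 0, FP = 0, TN = 3, FN = 0)),
               "sensitivity undefined")
  expect_error(detection_metrics(list(TP = 2, FP = 0, TN = 0, FN = 1)),
               "specificity undefined")
  expect_error(detection_metrics(list(TP = 0, FP = 0, TN = 3, FN = 1)),
               "precision undefined")
})

test_that("balanced accuracy and F1 recomputed from rates are self-consistent", {
  withr::with_seed(41, {
    for (r in seq_len(50)) {
      cm <- list(TP = sample(1:30, 1), FP = sample(1:30, 1),
                 TN = sample(1:30, 1), FN = sample(1:30, 1))
      m <- detection_metrics(cm)
      mr <- metrics_from_rates(m$sensitivity, m$specificity, m$precision)
      expect_equal(mr$balanced_accuracy, m$balanced_accuracy)
      expect_equal(mr$f1, m$f1)
    }
  })
  # harmonic-mean fixed point: sensitivity = precision = p gives F1 = p
  expect_equal(metrics_from_rates(0.7, 0.5, 0.7)$f1, 0.7)
})

test_that("volume estimation follows spacing x thickness arithmetic", {
  m <- matrix(0, 64, 64); m[seq_len(100)] <- 1
  v <- estimate_volume(list(m), pixel_spacing_mm = 1, slice_thickness_mm = 5)
  expect_equal(v$volume_ml, 0.5)
  expect_equal(estimate_volume(list(matrix(0, 8, 8)), 1, 5)$volume_ml, 0)
  # additive over slice partitions
  m2 <- matrix(0, 64, 64); m2[200:350] <- 1
  whole <- estimate_volume(list(m, m2), c(0.7, 0.7), 5)$volume_ml
  parts <- estimate_volume(list(m), c(0.7, 0.7), 5)$volume_ml +
           estimate_volume(list(m2), c(0.7, 0.7), 5)$volume_ml
  expect_equal(whole, parts)
  # down-sampled masks: spacing rescaled by source_grid / mask grid
  v2 <- estimate_volume(list(m), 1, 5, source_grid = 128)
  expect_equal(v2$volume_ml, 0.5 * 4)
  expect_error(estimate_volume(list(m), -1, 5), "pixel_spacing_mm")
  expect_error(estimate_volume(list(m), 1, NA), "slice_thickness_mm")
})
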