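test_that("confusion metrics match the textbook formulas on fixed counts", {
  # TP = 90, FN = 10, TN = 80, FP = 20, scores encode the prediction
  labels <- c(rep(1, 100), rep(0, 100))
  scores <- c(rep(0.9, 90), rep(0.1, 10), rep(0.1, 80), rep(0.9, 20))
  cm <- confusion_metrics(labels, scores, 0.5)
  tp <- 90; fn <- 10; tn <- 80; fp <- 20
  expect_equal(cm$tp, tp); expect_equal(cm$fp, fp)
  expect_equal(cm$accuracy, (tp + tn) / 200)
  expect_equal(cm$precision, tp / (tp + fp))
  expect_equal(cm$recall, tp / (tp + fn))
  expect_equal(
    cm$mcc,
    (tp * tn - fp * fn) /
      sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  )
})

test_that("degenerate confusion matrices follow the zero conventions", {
  labels <- c(1, 1, 0, 0)
  cm <- confusion_metrics(labels, rep(0.7, 4), 0.5)  # all predicted positive
  expect_equal(cm$mcc, 0)
  expect_equal(cm$recall, 1)
  perfect <- confusion_metrics(labels, c(0.9, 0.8, 0.1, 0.2), 0.5)
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_error(confusion_metrics(integer(), numeric()), "empty")
})

test_that("ROC area equals exhaustive pairwise concordance", {
  labels <- c(1, 1, 0, 0)
  expect_equal(roc_curve(labels, labels)$auc, 1)
  expect_error(roc_curve(c(1, 1), c(0.2, 0.3)), "both classes")
  for (trial in 1:100) {
    withr::with_seed(8000 + trial, {
      n <- sample(4:20, 1)
      labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)  # duplicates force tie handling
    })
    expect_equal(roc_curve(labels, scores)$auc,
                 oracle_concordance(labels, scores))
  }
})

test_that("ROC area matches an established implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(71, {
    labels <- sample(0:1, 300, replace = TRUE)
    scores <- runif(300) + 0.3 * labels
  })
  ours <- roc_curve(labels, scores)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("random scores give chance-level ROC area", {
  withr::with_seed(72, {
    labels <- sample(0:1, 1e4, replace = TRUE)
    scores <- runif(1e4)
  })
  expect_equal(roc_curve(labels, scores)$auc, 0.5, tolerance = 0.02)
})

test_that("PR curve behaves at the extremes", {
  labels <- c(1, 1, 1, 0, 0)
  pr <- pr_curve(labels, labels)
  expect_equal(pr$auc, 1)
  expect_true(all(diff(pr$curve$recall) >= 0))
  # interpolated precision is non-increasing in recall
  withr::with_seed(73, {
    labels <- sample(0:1, 100, replace = TRUE)
    scores <- runif(100)
  })
  pr2 <- pr_curve(labels, scores)
  expect_true(all(diff(pr2$curve$precision_interp) <= 1e-12))
  expect_gte(pr2$auc, 0)
  expect_lte(pr2$auc, 1)
})

test_that("best MCC threshold equals the brute-force scan", {
  # perfectly separated groups: MCC 1 at the smallest optimal midpoint
  labels <- c(rep(0, 5), rep(1, 5))
  scores <- c(seq(0.1, 0.2, length.out = 5), seq(0.9, 1, length.out = 5))
  bt <- best_mcc_threshold(labels, scores)
  expect_equal(bt$mcc, 1)
  u <- sort(unique(scores))
  mids <- (head(u, -1) + u[-1]) / 2
  first_perfect <- min(mids[vapply(mids, function(t)
    confusion_metrics(labels, scores, t)$mcc, numeric(1)) == 1])
  expect_equal(bt$threshold, first_perfect)
  # all scores equal: single candidate, MCC 0
  bt2 <- best_mcc_threshold(c(0, 1), c(0.4, 0.4))
  expect_equal(bt2$threshold, 0.4)
  expect_equal(bt2$mcc, 0)
  # random instances vs exhaustive scan
  for (trial in 1:100) {
    withr::with_seed(9000 + trial, {
      n <- sample(5:50, 1)
      labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
      scores <- round(runif(n), 2)
    })
    bt <- best_mcc_threshold(labels, scores)
    u <- sort(unique(scores))
    cand <- if (length(u) == 1) u else (head(u, -1) + u[-1]) / 2
    mccs <- vapply(cand, function(t)
      confusion_metrics(labels, scores, t)$mcc, numeric(1))
    expect_equal(bt$mcc, max(mccs))
    expect_equal(bt$threshold, cand[which.max(mccs)])
  }
})

test_that("metrics report ties the battery together", {
  withr::with_seed(74, {
    labels <- sample(0:1, 200, replace = TRUE)
    scores <- pmin(pmax(labels * 0.6 + runif(200) * 0.5, 0), 1)
  })
  rep <- metrics_report(labels, scores)
  expect_true(all(vapply(rep, is.finite, logical(1))))
  expect_equal(rep$mcc, confusion_metrics(labels, scores,
                                          rep$threshold_at_max_mcc)$mcc)
  # a perfect report: all headline numbers 1
  rp <- metrics_report(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(rp$mcc, 1)
  expect_equal(rp$precision, 1)
  expect_equal(rp$recall, 1)
  expect_equal(rp$roc_auc, 1)
})
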