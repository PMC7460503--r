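test_that("confusion matrix counts true/predicted pairs", {
  # perfect predictions: diagonal
  y <- rep(0:3, times = c(5, 10, 15, 20))
  cm <- confusion_matrix(y, y)
  expect_equal(diag(cm), c(HS = 5L, FF = 10L, HO = 15L, SW = 20L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)

  # everything predicted FF: only column 2 populated
  cm <- confusion_matrix(y, rep(1L, length(y)))
  expect_equal(unname(colSums(cm)), c(0L, 50L, 0L, 0L))

  expect_error(confusion_matrix(c(0, 4), c(0, 1)), "0..3")
  expect_error(confusion_matrix(c(0, 1), c(0)), "equal length")
})

test_that("confusion matrix agrees with a brute-force counting loop", {
  set.seed(10)
  y <- sample(0:3, 1000, replace = TRUE)
  p <- sample(0:3, 1000, replace = TRUE)
  cm <- confusion_matrix(y, p)
  for (i in 0:3) {
    for (j in 0:3) {
      n <- 0L
      for (k in seq_along(y)) if (y[k] == i && p[k] == j) n <- n + 1L
      expect_identical(cm[i + 1, j + 1], n)
    }
  }
})

test_that("per-class precision/recall/F1 match the reported arithmetic", {
  # the skip-connected model's printed heel-strike rows
  expect_equal(gaitphase:::harmonic_f1(73.8, 56.0), 63.7, tolerance = 0.05)
  expect_equal(gaitphase:::harmonic_f1(82.3, 71.6), 76.6, tolerance = 0.05)
  expect_equal(gaitphase:::harmonic_f1(82.9, 41.0), 54.9, tolerance = 0.05)

  # a class with zero TP scores zero throughout (0/0 -> 0 convention)
  cm <- matrix(c(0L, 5L, 0L, 0L,
                 0L, 10L, 0L, 0L,
                 0L, 0L, 8L, 0L,
                 0L, 0L, 0L, 9L), 4, byrow = TRUE,
               dimnames = list(phase_levels(), phase_levels()))
  pc <- per_class_prf(cm)
  expect_equal(pc$precision[1], 0)
  expect_equal(pc$recall[1], 0)
  expect_equal(pc$f1[1], 0)

  # harmonic-mean fixed point: P = R = p gives F1 = p
  cm2 <- confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 0))
  pc2 <- per_class_prf(cm2)
  expect_equal(pc2$f1[1], 50)
  expect_equal(pc2$f1[2], 50)

  # count identities against the matrix margins
  set.seed(2)
  y <- sample(0:3, 300, replace = TRUE)
  p <- sample(0:3, 300, replace = TRUE)
  cm3 <- confusion_matrix(y, p)
  pc3 <- per_class_prf(cm3)
  expect_equal(sum(pc3$tp), sum(diag(cm3)))
  expect_equal(pc3$tp + pc3$fp, unname(colSums(cm3)))
  expect_equal(pc3$tp + pc3$fn, unname(rowSums(cm3)))
  expect_true(all(pc3$tp + pc3$fp + pc3$fn + pc3$tn == sum(cm3)))
})

test_that("accuracy is the diagonal share", {
  y <- rep(0:3, 25)
  expect_equal(accuracy(confusion_matrix(y, y)), 100)
  p <- y; p[1] <- 1L
  expect_equal(accuracy(confusion_matrix(y, p)), 99)
  expect_error(accuracy(matrix(0L, 4, 4)), "empty")
  # uniform random predictions on balanced classes sit near 25%
  set.seed(5)
  y <- rep(0:3, 2500)
  p <- sample(0:3, 10000, replace = TRUE)
  expect_lt(abs(accuracy(confusion_matrix(y, p)) - 25), 2)
})

test_that("macro metrics use the harmonic mean of the two macros", {
  pc <- data.frame(precision = rep(100, 4), recall = rep(100, 4))
  expect_equal(unname(macro_metrics(pc)), c(100, 100, 100))

  # one dead class: macros all equal 75
  pc <- data.frame(precision = c(0, 100, 100, 100),
                   recall = c(0, 100, 100, 100))
  expect_equal(unname(macro_metrics(pc)["macro_f1"]), 75)

  # random confusion matrix: matches independent recomputation from raw
  # counts, and differs in general from the mean of per-class F1
  set.seed(8)
  y <- sample(0:3, 500, replace = TRUE, prob = c(0.1, 0.4, 0.2, 0.3))
  p <- ifelse(runif(500) < 0.6, y, sample(0:3, 500, replace = TRUE))
  cm <- confusion_matrix(y, p)
  pc <- per_class_prf(cm)
  mm <- macro_metrics(pc)
  ps <- rs <- numeric(4)
  for (i in 1:4) {
    ps[i] <- if (sum(cm[, i]) == 0) 0 else 100 * cm[i, i] / sum(cm[, i])
    rs[i] <- if (sum(cm[i, ]) == 0) 0 else 100 * cm[i, i] / sum(cm[i, ])
  }
  expect_equal(unname(mm["macro_p"]), mean(ps))
  expect_equal(unname(mm["macro_r"]), mean(rs))
  expect_equal(unname(mm["macro_f1"]),
               2 * mean(ps) * mean(rs) / (mean(ps) + mean(rs)))
  # harmonic-mean bound
  expect_lte(mm["macro_f1"], max(mm["macro_p"], mm["macro_r"]))
  expect_gte(mm["macro_f1"], min(mm["macro_p"], mm["macro_r"]))
})

test_that("one-vs-rest ROC handles the degenerate score patterns", {
  y <- c(0L, 0L, 1L, 1L, 2L, 3L)
  # perfectly separating scores
  q <- diag(4)[y + 1L, ] * 0.7 + 0.075
  roc <- roc_ovr(y, q)
  expect_equal(roc$macro_auc, 1.0)
  # identical scores for everyone: AUC 0.5 per class
  q <- matrix(0.25, 6, 4)
  roc <- roc_ovr(y, q)
  for (k in 1:4) expect_equal(roc$per_class[[k]]$auc, 0.5)
  # a class absent from the truth is excluded with a warning
  expect_warning(
    r2 <- roc_ovr(c(0L, 0L, 1L, 2L), matrix(runif(16), 4, 4)),
    "absent"
  )
  expect_true(is.na(r2$per_class$SW$auc))
})

test_that("trapezoid AUC equals the exhaustive pairwise oracle", {
  set.seed(21)
  for (trial in 1:20) {
    n <- sample(4:10, 1)
    y <- sample(0:3, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    q <- matrix(runif(n * 4), n, 4)
    q <- q / rowSums(q)
    # duplicate some scores to exercise tie handling
    if (n > 5) q[2, ] <- q[1, ]
    roc <- suppressWarnings(roc_ovr(y, q))
    for (k in 0:3) {
      pos <- y == k
      if (!any(pos) || all(pos)) next
      expect_equal(roc$per_class[[k + 1]]$auc,
                   auc_pairwise(q[pos, k + 1], q[!pos, k + 1]),
                   tolerance = 1e-12)
    }
  }
})

test_that("reversing all scores maps AUC to its complement", {
  set.seed(22)
  y <- sample(0:3, 40, replace = TRUE)
  q <- matrix(runif(160), 40, 4)
  a <- roc_ovr(y, q)
  b <- roc_ovr(y, -q)
  for (k in 1:4) {
    expect_equal(a$per_class[[k]]$auc, 1 - b$per_class[[k]]$auc,
                 tolerance = 1e-12)
  }
})

test_that("our AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  y <- sample(0:3, 60, replace = TRUE)
  q <- matrix(runif(240), 60, 4)
  roc <- roc_ovr(y, q)
  for (k in 1:4) {
    ref <- pROC::auc(pROC::roc(response = as.integer(y == (k - 1)),
                               predictor = q[, k], quiet = TRUE,
                               direction = "<"))
    expect_equal(roc$per_class[[k]]$auc, as.numeric(ref),
                 tolerance = 1e-12)
  }
})

test_that("metrics report bundles and serializes consistently", {
  set.seed(9)
  y <- sample(0:3, 200, replace = TRUE)
  q <- matrix(runif(800), 200, 4)
  q <- q / rowSums(q)
  rep <- metrics_report(y, scores = q, model = "fmsnet", speed = 1.0)
  expect_s3_class(rep, "gait_metrics")
  expect_equal(rep$macro_f1,
               unname(macro_metrics(rep$per_class)["macro_f1"]))
  expect_equal(sum(rep$confusion), 200L)
  path <- withr::local_tempfile(fileext = ".json")
  write_metrics_json(rep, path, include_roc = TRUE)
  parsed <- jsonlite::read_json(path)
  expect_equal(parsed$accuracy, rep$accuracy, tolerance = 1e-12)
  expect_equal(parsed$macro_f1, rep$macro_f1, tolerance = 1e-12)
  expect_length(parsed$per_class, 4)
})
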