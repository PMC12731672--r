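test_that("confusion matrix counts true-by-predicted cells", {
  y <- c(0L, 0L, 1L, 2L)
  p <- c(0L, 1L, 1L, 2L)
  cm <- confusion_matrix(y, p)
  expect_equal(unclass(unname(cm)),
               matrix(c(1L, 1L, 0L, 0L, 1L, 0L, 0L, 0L, 1L), 3,
                      byrow = TRUE), ignore_attr = TRUE)

  perfect <- confusion_matrix(y, y)
  expect_equal(unname(diag(perfect)), c(2L, 1L, 1L))
  expect_equal(sum(perfect) - sum(diag(perfect)), 0L)

  empty <- confusion_matrix(integer(0), integer(0))
  expect_true(all(empty == 0L))

  expect_error(confusion_matrix(0:1, 0L), "lengths")
  expect_error(confusion_matrix(c(0L, 3L), c(0L, 1L)), "codes")
})

test_that("metric suite reproduces hand-computed one-vs-rest values", {
  cm <- confusion_matrix(
    y_true = rep(0:2, times = c(6, 5, 9)),
    y_pred = c(rep(0, 5), 1,            # true 0: 5 right, 1 -> class 1
               rep(1, 4), 2,            # true 1: 4 right, 1 -> class 2
               rep(2, 8), 0)            # true 2: 8 right, 1 -> class 0
  )
  expect_equal(unname(unclass(cm)),
               matrix(c(5, 1, 0, 0, 4, 1, 1, 0, 8), 3, byrow = TRUE),
               ignore_attr = TRUE)
  m <- classification_metrics(cm)
  expect_equal(m$accuracy, 17 / 20)
  expect_equal(m$recall, 17 / 20)           # support-weighted recall
  expect_equal(m$mc_rate, 3 / 20)
  # per-class OvR counts worked out by hand
  pc <- m$per_class
  expect_equal(pc$precision, c(5 / 6, 4 / 5, 8 / 9))
  expect_equal(pc$recall, c(5 / 6, 4 / 5, 8 / 9))
  expect_equal(pc$fnr, c(1 / 6, 1 / 5, 1 / 9))
  expect_equal(pc$fpr, c(1 / 14, 1 / 15, 1 / 11))
  expect_equal(m$fnr, mean(c(1 / 6, 1 / 5, 1 / 9)))  # macro
  expect_equal(m$fpr, mean(c(1 / 14, 1 / 15, 1 / 11)))
  # headline F1 is the harmonic mean of the weighted pair
  wp <- sum(c(6, 5, 9) / 20 * c(5 / 6, 4 / 5, 8 / 9))
  expect_equal(m$f1, 2 * wp * m$recall / (wp + m$recall))

  micro <- classification_metrics(cm, rate_average = "micro")
  expect_equal(micro$fnr, 3 / 20)
  expect_equal(micro$fpr, 3 / 40)
})

test_that("perfect prediction and degenerate predictors behave", {
  y <- rep(0:2, times = c(4, 3, 3))
  m <- classification_metrics(confusion_matrix(y, y))
  expect_equal(m$accuracy, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$fnr, 0)
  expect_equal(m$fpr, 0)
  expect_equal(m$mc_rate, 0)
  expect_false(m$zero_division)

  # everything predicted as one class: zero-division cells resolve to 0
  deg <- classification_metrics(confusion_matrix(y, rep(1L, 10)))
  expect_true(deg$zero_division)
  expect_true(all(is.finite(unlist(deg$per_class[, c("precision", "recall")]))))
})

test_that("mc_rate and weighted-recall identities hold on random confusion matrices", {
  for (rep in 1:30) {
    withr::with_seed(rep, {
      n <- sample(20:200, 1)
      y <- sample(0:2, n, replace = TRUE)
      p <- sample(0:2, n, replace = TRUE)
    })
    m <- classification_metrics(confusion_matrix(y, p))
    expect_identical(m$mc_rate, 1 - m$accuracy)
    expect_equal(m$recall, m$accuracy, tolerance = 1e-12)
    rates <- c(m$precision, m$recall, m$f1, m$fnr, m$fpr, m$accuracy)
    expect_true(all(rates >= 0 & rates <= 1))
  }
})

test_that("one-vs-rest AUC matches the pairwise-concordance oracle", {
  # 4-point toy: positives scored 0.9, 0.7; negatives 0.8, 0.1
  y <- c(1L, 0L, 1L, 0L)
  scores <- c(0.9, 0.8, 0.7, 0.1)
  probas <- cbind(1 - scores, scores)
  auc <- roc_auc_ovr(y, probas)
  expect_equal(unname(auc$per_class[2]), 3 / 4)
  expect_equal(unname(auc$per_class[1]), 3 / 4)  # complement scores agree

  # perfect separation and all-ties conventions
  sep <- cbind(c(0.9, 0.8, 0.1, 0.2), c(0.1, 0.2, 0.9, 0.8))
  expect_equal(unname(roc_auc_ovr(c(0, 0, 1, 1), sep)$per_class), c(1, 1))
  const <- matrix(1 / 3, 6, 3)
  expect_equal(unname(roc_auc_ovr(rep(0:2, 2), const)$per_class),
               rep(0.5, 3))

  # equality with an independent Mann-Whitney computation on random fixtures
  for (rep in 1:10) {
    withr::with_seed(100 + rep, {
      n <- 60
      y3 <- sample(0:2, n, replace = TRUE)
      pr <- matrix(runif(n * 3), n, 3)
      pr <- pr / rowSums(pr)
    })
    auc3 <- roc_auc_ovr(y3, pr)
    for (cl in 0:2) {
      expect_equal(unname(auc3$per_class[cl + 1]),
                   auc_bruteforce(pr[, cl + 1], y3 == cl),
                   tolerance = 1e-12)
    }
  }

  # a class absent from y_true is NA, not zero
  missing <- roc_auc_ovr(rep(0:1, 5), matrix(1 / 3, 10, 3))
  expect_true(is.na(missing$per_class[["ischemic"]]))
  expect_false(is.na(missing$macro))
})
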