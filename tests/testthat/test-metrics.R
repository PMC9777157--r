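# Metric engine: confusion matrices, one-vs-rest per-class metrics, macro
# averages, ROC/AUC with the Mann-Whitney oracle.

test_that("confusion matrix counts and validates", {
  cm <- confusion(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_identical(unname(cm), matrix(c(1L, 0L, 1L, 2L), 2, 2))
  # perfect predictions: diagonal with class counts
  y <- rep(0:2, times = c(3, 4, 5))
  cmp <- confusion(y, y, 3)
  expect_identical(unname(diag(cmp)), c(3L, 4L, 5L))
  expect_equal(sum(cmp) - sum(diag(cmp)), 0)
  # conservation for random labels
  set.seed(9)
  t_ <- sample(0:3, 200, replace = TRUE)
  p_ <- sample(0:3, 200, replace = TRUE)
  expect_equal(sum(confusion(t_, p_, 4)), 200)
  expect_error(confusion(c(0, 5), c(0, 1), 2), class = "kneedhl_invalid_input")
  expect_error(confusion(0:1, 0L, 2), class = "kneedhl_invalid_input")
})

test_that("per-class metrics evaluate the formulas directly", {
  # binary: TP=35 FN=5 FP=10 TN=50 for the positive class (class 1)
  cm <- matrix(c(50L, 5L, 10L, 35L), 2, 2)  # rows true, cols pred
  per <- per_class_metrics(cm)
  pos <- per[per$class == 1, ]
  expect_equal(pos$accuracy, 85.0)
  expect_equal(pos$recall, 87.5)
  expect_equal(pos$precision, 100 * 35 / 45, tolerance = 1e-10)   # 77.78
  expect_equal(pos$specificity, 100 * 50 / 60, tolerance = 1e-10) # 83.33
  expect_equal(pos$f1, 2 * pos$precision * pos$recall / (pos$precision + pos$recall),
               tolerance = 1e-10)                                 # 82.35
  expect_equal(round(pos$precision, 2), 77.78)
  expect_equal(round(pos$f1, 2), 82.35)

  # perfect diagonal: everything 100
  perfect <- per_class_metrics(diag(c(5L, 7L, 9L)))
  expect_true(all(perfect[, c("accuracy", "recall", "precision",
                              "specificity", "f1")] == 100))

  # published grade-0 row: recall 87, precision 63 -> F1 rounds to 73
  f1 <- 2 * 63 * 87 / (63 + 87)
  expect_equal(round(f1), 73)

  # one-vs-rest counts sum to the total for every class
  set.seed(3)
  cm5 <- confusion(sample(0:4, 300, TRUE), sample(0:4, 300, TRUE), 5)
  per5 <- per_class_metrics(cm5)
  expect_true(all(per5$tp + per5$fn + per5$fp + per5$tn == 300))

  # empty class yields 0 with a flag, never NaN
  cme <- matrix(c(10L, 0L, 0L, 0L), 2, 2)
  pere <- per_class_metrics(cme)
  expect_equal(pere$recall[2], 0)
  expect_true(attr(pere, "zero_division")[2])
  expect_false(any(is.nan(unlist(pere))))
  expect_error(per_class_metrics(matrix(0L, 2, 2)), class = "kneedhl_invalid_input")
})

test_that("macro averages reproduce the published column means", {
  expect_equal(round(macro_average(c(88, 27, 77, 90, 95)), 1), 75.4)
  expect_equal(round(macro_average(c(92, 89)), 1), 90.5)
  expect_equal(macro_average(42), 42)
  expect_error(macro_average(numeric(0)), class = "kneedhl_invalid_input")
})

test_that("AUC: trapezoid equals Mann-Whitney, with the expected anchors", {
  # perfect separation
  r <- roc_auc(c(0, 0, 1, 1), cbind(-c(0.1, 0.2, 0.9, 0.8), c(0.1, 0.2, 0.9, 0.8)), 2)
  expect_equal(unname(r$per_class["1"]), 1.0)
  # the worked 4-sample case: 3 of 4 pairs ordered correctly
  r4 <- roc_auc(c(0, 0, 1, 1),
                cbind(-c(0.1, 0.4, 0.35, 0.8), c(0.1, 0.4, 0.35, 0.8)), 2)
  expect_equal(unname(r4$per_class["1"]), 0.75)
  # label-independent scores: AUC near 1/2
  set.seed(17)
  tr <- sample(0:1, 4000, replace = TRUE)
  sc <- runif(4000)
  ri <- roc_auc(tr, cbind(-sc, sc), 2)
  expect_lt(abs(ri$per_class["1"] - 0.5), 0.05)

  # oracle equivalence incl. ties, across random multiclass instances
  for (s in 1:5) {
    set.seed(s)
    n <- 150
    k <- sample(2:4, 1)
    truth <- sample(0:(k - 1), n, replace = TRUE)
    scores <- matrix(sample(seq(0, 1, by = 0.05), n * k, replace = TRUE), n, k)
    r <- roc_auc(truth, scores, k)
    for (c_ in seq_len(k)) {
      expect_equal(unname(r$per_class[c_]),
                   mw_auc(as.integer(truth == c_ - 1), scores[, c_]),
                   tolerance = 1e-12)
    }
    expect_equal(r$macro, mean(r$per_class, na.rm = TRUE))
  }

  # a class absent from the truth: flagged NA, excluded from macro
  rna <- roc_auc(rep(0:1, 5), matrix(runif(30), 10, 3), 3)
  expect_true(is.na(rna$per_class["2"]))
  expect_false(anyNA(rna$per_class[c("0", "1")]))
  expect_false(is.na(rna$macro))
})

test_that("metrics_report is internally consistent and serializes", {
  set.seed(23)
  truth <- sample(0:2, 120, replace = TRUE)
  pred <- ifelse(runif(120) < 0.7, truth, sample(0:2, 120, replace = TRUE))
  scores <- matrix(runif(360), 120, 3)
  scores[cbind(1:120, pred + 1)] <- scores[cbind(1:120, pred + 1)] + 1
  rep_ <- metrics_report(truth, pred, 3, scores = scores)
  expect_equal(sum(rep_$confusion), 120)
  expect_equal(rep_$macro$recall, mean(rep_$per_class$recall))
  expect_equal(rep_$accuracy, 100 * mean(truth == pred))
  # F1 equals the harmonic-mean formula applied to its own P/R
  with(rep_$per_class, expect_equal(
    f1, ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall)), tolerance = 1e-10))
  f <- tempfile(fileext = ".json")
  write_metrics_json(rep_, f, extra = list(seed = 1))
  j <- jsonlite::read_json(f)
  expect_equal(j$n, 120)
  expect_equal(j$seed, 1)
  expect_equal(j$accuracy, rep_$accuracy, tolerance = 1e-9)
})
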