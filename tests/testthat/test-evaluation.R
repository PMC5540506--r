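# Confusion matrices, one-vs-rest statistics, folds and cross-validation.

test_that("confusion matrices tabulate true vs predicted in class order", {
  tr <- rep(c("a", "b", "c"), each = 2)
  cm <- confusionMatrix(tr, tr)
  expect_equal(unname(diag(cm)), rep(2L, 3))
  expect_equal(sum(cm), 6L)
  allA <- confusionMatrix(tr, rep("a", 6), c("a", "b", "c"))
  expect_equal(unname(allA[, "a"]), c(2L, 2L, 2L))
  expect_equal(sum(allA[, -1]), 0L)
  expect_error(confusionMatrix(character(0), character(0)), "no labels")
  expect_error(confusionMatrix("a", "z", classOrder = c("a", "b")),
               "unknown class label 'z'")
})

test_that("one-vs-rest counts reduce correctly and conserve totals", {
  cm <- diag(c(2L, 2L, 2L))
  expect_equal(binaryCounts(cm, 1), c(TP = 2L, TN = 4L, FP = 0L, FN = 0L))
  cm2 <- matrix(1L, 2, 2)
  expect_equal(binaryCounts(cm2, 1), c(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  set.seed(801)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    cm <- matrix(rpois(k * k, 3), k, k)
    for (ci in seq_len(k))
      expect_equal(sum(binaryCounts(cm, ci)), sum(cm))
  }
})

test_that("the six statistics match their defining formulas", {
  m <- classMetrics(1, 1, 1, 1)
  expect_equal(m[["accuracy"]], 0.5)
  expect_equal(m[["mcc"]], 0)
  expect_equal(unname(classMetrics(2, 2, 0, 0)), rep(1, 6))
  suppressWarnings(m3 <- classMetrics(2, 0, 1, 1))
  expect_equal(m3[["fscore"]], 4 / 6)
  # independent recomputation on random counts
  set.seed(802)
  for (rep in 1:10) {
    cnt <- rpois(4, 5) + 1
    tp <- cnt[1]; tn <- cnt[2]; fp <- cnt[3]; fn <- cnt[4]
    got <- classMetrics(tp, tn, fp, fn)
    expect_equal(got[["accuracy"]], (tp + tn) / sum(cnt))
    expect_equal(got[["sensitivity"]], tp / (tp + fn))
    expect_equal(got[["specificity"]], tn / (tn + fp))
    expect_equal(got[["precision"]], tp / (tp + fp))
    expect_equal(got[["fscore"]], 2 * tp / (2 * tp + fp + fn))
    expect_equal(got[["mcc"]],
                 (tp * tn - fp * fn) /
                   sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)))
    expect_true(all(got[1:5] >= 0 & got[1:5] <= 1))
    expect_true(got[["mcc"]] >= -1 && got[["mcc"]] <= 1)
  }
})

test_that("zero denominators yield 0 with a warning; all-zero counts error", {
  w <- capture_warnings(m <- classMetrics(0, 3, 0, 2))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(m[["precision"]], 0)
  expect_equal(m[["mcc"]], 0)
  expect_error(classMetrics(0, 0, 0, 0), "zero")
})

test_that("macro averaging is the unweighted mean; trace accuracy reported", {
  cm <- diag(c(3L, 3L))
  dimnames(cm) <- list(c("a", "b"), c("a", "b"))
  rep1 <- evalReport(cm)
  expect_equal(unname(macroMetrics(rep1)), rep(1, 6))
  expect_equal(rep1@microAccuracy, 1)
  # two classes with sensitivity 1.0 and 0.0 -> macro sensitivity 0.5
  cm2 <- matrix(c(3L, 3L, 0L, 0L), 2, 2)
  dimnames(cm2) <- list(c("a", "b"), c("a", "b"))
  suppressWarnings(rep2 <- evalReport(cm2))
  expect_equal(macroMetrics(rep2)[["sensitivity"]], 0.5)
  # identical per-class values -> macro equals them
  per <- perClassMetrics(rep1)
  expect_equal(unname(macroAverage(per)),
               unname(colMeans(as.matrix(per[, 6:11]))))
})

test_that("fold-aggregated confusion equals the pooled tabulation", {
  set.seed(803)
  labels <- sample(c("a", "b", "c"), 60, replace = TRUE)
  preds <- sample(c("a", "b", "c"), 60, replace = TRUE)
  folds <- stratifiedFolds(labels, k = 4, seed = 2)
  summed <- Reduce(`+`, lapply(folds, function(ix)
    confusionMatrix(labels[ix], preds[ix], c("a", "b", "c"))))
  expect_equal(summed, confusionMatrix(labels, preds, c("a", "b", "c")))
})

test_that("stratified folds partition records with balanced class counts", {
  labels <- rep(sprintf("c%02d", 1:13), each = 10)
  folds <- stratifiedFolds(labels, k = 10, seed = 5)
  expect_length(folds, 10L)
  for (f in folds)
    expect_equal(as.vector(table(labels[f])), rep(1L, 13))
  expect_equal(sort(unlist(folds)), seq_along(labels))
  expect_identical(folds, stratifiedFolds(labels, k = 10, seed = 5))
  expect_false(identical(folds, stratifiedFolds(labels, k = 10, seed = 6)))
  expect_error(stratifiedFolds(c("a", "b"), k = 3), "more folds")
  expect_warning(stratifiedFolds(rep(c("a", "b"), c(2, 8)), k = 4, seed = 1),
                 "fewer members")
})

test_that("cross-validation runs per-fold mining without leakage and sums folds", {
  ds <- tinyDataset(nClasses = 2L, perClass = 6L)
  rep <- crossValidate(ds, supportPct = 100, minSize = 1, maxSize = 3,
                       k = 2, seed = 4, cnn = list(hidden = 8, epochs = 5))
  expect_s4_class(rep, "EvalReport")
  expect_equal(sum(confusion(rep)), length(ds))
  expect_equal(sort(rownames(confusion(rep))), c("class1", "class2"))
  # leakage guard: mining a training subset only references its own ids
  gs <- structureGraphs(ds)
  fr <- mineClosedFragments(gs[1:8], 50, 1, 3)
  expect_true(all(unlist(supportingIds(fr)) %in% names(gs)[1:8]))
})

test_that("evaluation reports serialize to TSV", {
  cm <- matrix(c(5L, 1L, 0L, 6L), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  dir <- withr::local_tempdir()
  writeEvalReport(evalReport(cm), dir)
  expect_true(file.exists(file.path(dir, "metrics.tsv")))
  metrics <- read.delim(file.path(dir, "metrics.tsv"))
  expect_equal(metrics$class, c("a", "b", "macro", "micro"))
  conf <- read.delim(file.path(dir, "confusion.tsv"), check.names = FALSE)
  expect_equal(conf$a, c(5L, 1L))
  pct <- read.delim(file.path(dir, "confusion_pct.tsv"),
                    check.names = FALSE)
  expect_equal(pct$a[1], 100)
})
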