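# Confusion matrices, one-vs-rest statistics, stratified cross-validation.

#' Multi-class confusion matrix
#'
#' @param trueLabels,predictedLabels character vectors of equal length.
#' @param classOrder class names fixing row/column order; defaults to the
#'   sorted union of observed labels.
#' @return integer matrix, rows = true class, columns = predicted class.
#' @export
confusionMatrix <- function(trueLabels, predictedLabels,
                            classOrder = NULL) {
  if (length(trueLabels) == 0L)
    stop("no labels to tabulate", call. = FALSE)
  if (length(trueLabels) != length(predictedLabels))
    stop("true and predicted label vectors differ in length",
         call. = FALSE)
  if (is.null(classOrder))
    classOrder <- sort(unique(c(trueLabels, predictedLabels)))
  unknown <- setdiff(unique(c(trueLabels, predictedLabels)), classOrder)
  if (length(unknown))
    stop(sprintf("unknown class label '%s'", unknown[1L]), call. = FALSE)
  tt <- table(factor(trueLabels, levels = classOrder),
              factor(predictedLabels, levels = classOrder))
  m <- matrix(as.integer(tt), nrow = length(classOrder),
              dimnames = list(true = classOrder, predicted = classOrder))
  m
}

#' One-vs-rest reduction of a confusion matrix
#'
#' For the given class: TP is the diagonal cell, FN the rest of its row,
#' FP the rest of its column, TN the remainder; the four counts always sum
#' to the matrix total.
#'
#' @param confusion square integer matrix.
#' @param classIndex class position (row/column index).
#' @return named integer vector (TP, TN, FP, FN).
#' @export
binaryCounts <- function(confusion, classIndex) {
  k <- nrow(confusion)
  if (classIndex < 1L || classIndex > k)
    stop("classIndex out of range", call. = FALSE)
  tp <- confusion[classIndex, classIndex]
  fn <- sum(confusion[classIndex, ]) - tp
  fp <- sum(confusion[, classIndex]) - tp
  tn <- sum(confusion) - tp - fn - fp
  c(TP = as.integer(tp), TN = as.integer(tn), FP = as.integer(fp),
    FN = as.integer(fn))
}

#' Six binary classification statistics from (TP, TN, FP, FN)
#'
#' Accuracy (TP+TN)/(TP+TN+FP+FN), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), precision TP/(TP+FP), F-score 2TP/(2TP+FP+FN) and the
#' Matthews correlation coefficient
#' (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)). A statistic whose
#' denominator is zero is reported as 0 with a warning (degenerate folds
#' only).
#'
#' @param TP,TN,FP,FN non-negative integer counts, not all zero.
#' @return named numeric vector of the six statistics.
#' @examples
#' classMetrics(1, 1, 1, 1)  # accuracy 0.5, MCC 0
#' @export
classMetrics <- function(TP, TN, FP, FN) {
  if (any(c(TP, TN, FP, FN) < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (TP + TN + FP + FN == 0)
    stop("all counts are zero", call. = FALSE)
  TP <- as.numeric(TP); TN <- as.numeric(TN)
  FP <- as.numeric(FP); FN <- as.numeric(FN)
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("zero denominator for %s; reported as 0", what),
              call. = FALSE)
      return(0)
    }
    num / den
  }
  mccDen <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  c(accuracy = (TP + TN) / (TP + TN + FP + FN),
    sensitivity = safe(TP, TP + FN, "sensitivity"),
    specificity = safe(TN, TN + FP, "specificity"),
    precision = safe(TP, TP + FP, "precision"),
    fscore = safe(2 * TP, 2 * TP + FP + FN, "F-score"),
    mcc = safe(TP * TN - FP * FN, mccDen, "MCC"))
}

#' Unweighted macro average of per-class statistics
#'
#' @param perClass matrix or data.frame with one row per class and the six
#'   statistic columns (as produced inside [evalReport()]).
#' @return named numeric vector of column means.
#' @export
macroAverage <- function(perClass) {
  cols <- c("accuracy", "sensitivity", "specificity", "precision",
            "fscore", "mcc")
  colMeans(as.matrix(perClass[, cols, drop = FALSE]))
}

#' Full evaluation report from a confusion matrix
#'
#' Computes the one-vs-rest counts and six statistics per class, their
#' unweighted macro averages, and the overall trace/total (micro)
#' accuracy. Both accuracies are reported because macro-averaged one-vs-rest
#' accuracy and plain fraction-correct answer different questions.
#'
#' @param confusion square integer matrix with class dimnames.
#' @return An [EvalReport-class].
#' @export
evalReport <- function(confusion) {
  classes <- rownames(confusion) %||% sprintf("class%d",
                                              seq_len(nrow(confusion)))
  per <- do.call(rbind, lapply(seq_along(classes), function(ci) {
    cnt <- binaryCounts(confusion, ci)
    cbind(data.frame(class = classes[ci], TP = cnt[["TP"]],
                     TN = cnt[["TN"]], FP = cnt[["FP"]], FN = cnt[["FN"]]),
          as.data.frame(as.list(classMetrics(cnt[["TP"]], cnt[["TN"]],
                                             cnt[["FP"]], cnt[["FN"]]))))
  }))
  rownames(per) <- NULL
  new("EvalReport", confusion = confusion, perClass = per,
      macro = macroAverage(per),
      microAccuracy = sum(diag(confusion)) / sum(confusion))
}

#' Stratified k-fold partitions
#'
#' Per class, a seeded shuffle followed by round-robin allocation, so
#' per-class fold sizes differ by at most one; folds are disjoint and
#' their union covers all records.
#'
#' @param labels character vector of class labels (or an
#'   [RNAStructSet-class], whose labels are used).
#' @param k number of folds (>= 2).
#' @param seed integer RNG seed.
#' @return list of k integer vectors of record indices (the test folds).
#' @export
stratifiedFolds <- function(labels, k = 10L, seed = 1L) {
  if (is(labels, "RNAStructSet")) labels <- labels@classLabel
  n <- length(labels)
  if (k < 2L) stop("need at least 2 folds", call. = FALSE)
  if (k > n) stop("more folds than records", call. = FALSE)
  if (anyNA(labels)) stop("missing class labels", call. = FALSE)
  small <- names(which(table(labels) < k))
  if (length(small))
    warning(sprintf("class '%s' has fewer members than folds; folds will be imbalanced",
                    small[1L]), call. = FALSE)
  set.seed(seed)
  folds <- vector("list", k)
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    f <- ((seq_along(idx) - 1L) %% k) + 1L
    for (fi in seq_len(k))
      folds[[fi]] <- c(folds[[fi]], idx[f == fi])
  }
  lapply(folds, sort)
}

#' Cross-validated evaluation of the full pipeline
#'
#' For each fold, fragments are mined on the training portion ONLY, the
#' training matrix is assembled from the mining supports, a CNN is
#' trained, and the held-out records are projected into that fold's frozen
#' feature space and predicted. The final confusion matrix is the
#' elementwise sum of the per-fold confusion matrices; statistics are
#' computed from the summed matrix. Mining inside a fold never sees
#' held-out graphs, which the implementation asserts by checking fragment
#' supporting ids.
#'
#' Kernel widths are reduced automatically when a fold's mined feature
#' space is narrower than the configured kernels (small worked examples);
#' with realistic feature counts the configured values are used as given.
#'
#' @param records labelled [RNAStructSet-class] with structures attached.
#' @param supportPct,minSize,maxSize mining parameters per
#'   [mineClosedFragments()].
#' @param k number of folds. @param seed RNG seed driving fold allocation
#'   and (offset per fold) CNN training.
#' @param cnn named list of [cnnConfig()] overrides (e.g. `hidden`,
#'   `epochs`, `learningRate`).
#' @param verbose print per-fold progress.
#' @return An [EvalReport-class] over all records.
#' @export
crossValidate <- function(records, supportPct = 10, minSize = 4L,
                          maxSize = 6L, k = 10L, seed = 1L, cnn = list(),
                          verbose = FALSE) {
  labels <- records@classLabel
  if (anyNA(labels)) stop("all records must carry class labels",
                          call. = FALSE)
  graphs <- structureGraphs(records)
  ids <- seqIds(records)
  classOrder <- sort(unique(labels))
  folds <- stratifiedFolds(labels, k = k, seed = seed)
  total <- matrix(0L, length(classOrder), length(classOrder),
                  dimnames = list(true = classOrder,
                                  predicted = classOrder))
  for (f in seq_len(k)) {
    testIdx <- folds[[f]]
    trainIdx <- setdiff(seq_along(ids), testIdx)
    res <- tryCatch({
      frags <- mineClosedFragments(graphs[trainIdx], supportPct, minSize,
                                   maxSize)
      leaked <- setdiff(unique(unlist(frags@supportingIds)),
                        ids[trainIdx])
      if (length(leaked))
        stop("internal error: fragment support references held-out graphs")
      Xtr <- miningFeatureMatrix(frags, ids[trainIdx])
      cfg <- .autoCnnConfig(length(frags), length(classOrder),
                            seed = seed + f, overrides = cnn)
      model <- trainCnn(Xtr, labels[trainIdx], cfg)
      Xte <- projectGraphs(graphs[testIdx], frags)
      pred <- predict(model, Xte)
      list(conf = confusionMatrix(labels[testIdx], pred$class, classOrder),
           nFeat = length(frags))
    }, error = function(e)
      stop(sprintf("fold %d: %s", f, conditionMessage(e)), call. = FALSE))
    total <- total + res$conf
    if (verbose)
      message(sprintf("fold %d/%d: %d fragments, %d test records", f, k,
                      res$nFeat, length(testIdx)))
  }
  evalReport(total)
}

## cnnConfig with kernel widths shrunk to fit a narrow feature space.
.autoCnnConfig <- function(inputLength, nClasses, seed, overrides = list()) {
  args <- list(inputLength = inputLength, nClasses = nClasses, seed = seed)
  args[names(overrides)] <- overrides
  args$inputLength <- inputLength
  args$nClasses <- nClasses
  prefK1 <- min(args$k1 %||% 5L, inputLength)
  prefK2 <- args$k2 %||% 5L
  for (k1 in rev(seq_len(prefK1))) {
    p1 <- (inputLength - k1 + 1L) %/% 2L
    if (p1 < 1L) next
    for (k2 in rev(seq_len(min(prefK2, p1)))) {
      if ((p1 - k2 + 1L) %/% 2L >= 1L) {
        args$k1 <- k1
        args$k2 <- k2
        return(do.call(cnnConfig, args))
      }
    }
  }
  stop(sprintf("feature space of %d fragments is too small for the convolutional architecture",
               inputLength), call. = FALSE)
}

#' Write an evaluation report to TSV files
#'
#' Writes `metrics.tsv` (per-class rows, a `macro` row and a `micro`
#' accuracy row), `confusion.tsv` (counts) and `confusion_pct.tsv`
#' (row-normalized percentages).
#'
#' @param report an [EvalReport-class].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeEvalReport <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  per <- report@perClass
  macroRow <- per[1L, ]
  macroRow$class <- "macro"
  macroRow[, c("TP", "TN", "FP", "FN")] <- NA
  macroRow[, names(report@macro)] <- as.list(report@macro)
  microRow <- macroRow
  microRow$class <- "micro"
  microRow[, names(report@macro)] <- NA
  microRow$accuracy <- report@microAccuracy
  out <- rbind(per, macroRow, microRow)
  utils::write.table(out, file.path(dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cm <- data.frame(true = rownames(report@confusion), report@confusion,
                   check.names = FALSE)
  utils::write.table(cm, file.path(dir, "confusion.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pct <- report@confusion
  rs <- rowSums(pct)
  pct <- round(100 * pct / pmax(rs, 1L), 1)
  cmp <- data.frame(true = rownames(pct), pct, check.names = FALSE)
  utils::write.table(cmp, file.path(dir, "confusion_pct.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
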