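# Accessors, subsetting and show methods for the S4 containers.

#' @rdname RNAStructSet-class
#' @export
setMethod("seqIds", "RNAStructSet", function(x) x@id)

#' @rdname RNAStructSet-class
#' @export
setMethod("rnaSequences", "RNAStructSet", function(x) {
  structure(x@sequence, names = x@id)
})

#' @rdname RNAStructSet-class
#' @export
setMethod("rnaStructures", "RNAStructSet", function(x) {
  structure(x@structure, names = x@id)
})

#' @rdname RNAStructSet-class
#' @export
setMethod("classLabels", "RNAStructSet", function(x) {
  structure(x@classLabel, names = x@id)
})

#' @rdname RNAStructSet-class
#' @export
setMethod("length", "RNAStructSet", function(x) length(x@id))

#' @rdname RNAStructSet-class
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "RNAStructSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@id)
  new("RNAStructSet", id = x@id[i], sequence = x@sequence[i],
      structure = x@structure[i], classLabel = x@classLabel[i])
})

setMethod("show", "RNAStructSet", function(object) {
  n <- length(object)
  nStruct <- sum(!is.na(object@structure))
  nLab <- sum(!is.na(object@classLabel))
  cat(sprintf("RNAStructSet with %d record%s (%d with structure, %d labelled)\n",
              n, if (n == 1L) "" else "s", nStruct, nLab))
  if (n) {
    k <- min(n, 3L)
    for (p in seq_len(k))
      cat(sprintf("  %s  [%d nt]%s\n", object@id[p], nchar(object@sequence[p]),
                  if (is.na(object@classLabel[p])) "" else
                    paste0("  ", object@classLabel[p])))
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
})

#' @rdname StructureGraph-class
#' @export
setMethod("nodeLabels", "StructureGraph", function(x) x@nodeLabels)

#' @rdname StructureGraph-class
#' @export
setMethod("edgeTable", "StructureGraph", function(x) x@edges)

#' @rdname StructureGraph-class
#' @export
setMethod("length", "StructureGraph", function(x) length(x@nodeLabels))

setMethod("show", "StructureGraph", function(object) {
  nPair <- sum(object@edges$bond == "pair")
  cat(sprintf("StructureGraph '%s': %d nodes, %d backbone edges, %d pair edges\n",
              object@graphId, length(object@nodeLabels),
              sum(object@edges$bond == "backbone"), nPair))
})

#' @rdname FragmentSet-class
#' @export
setMethod("canonicalCodes", "FragmentSet", function(x) x@canonicalCode)

#' @rdname FragmentSet-class
#' @export
setMethod("supportCounts", "FragmentSet", function(x) {
  structure(x@supportCount, names = x@canonicalCode)
})

#' @rdname FragmentSet-class
#' @export
setMethod("supportingIds", "FragmentSet", function(x) {
  structure(x@supportingIds, names = x@canonicalCode)
})

#' @rdname FragmentSet-class
#' @export
setMethod("fragmentSizes", "FragmentSet", function(x) {
  structure(vapply(x@nodeLabels, length, integer(1)),
            names = x@canonicalCode)
})

#' @rdname FragmentSet-class
#' @export
setMethod("length", "FragmentSet", function(x) length(x@canonicalCode))

#' @rdname FragmentSet-class
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "FragmentSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@canonicalCode)
  new("FragmentSet", canonicalCode = x@canonicalCode[i],
      nodeLabels = x@nodeLabels[i], edges = x@edges[i],
      supportCount = x@supportCount[i], supportingIds = x@supportingIds[i],
      params = x@params)
})

setMethod("show", "FragmentSet", function(object) {
  n <- length(object)
  cat(sprintf("FragmentSet with %d fragment%s\n", n, if (n == 1L) "" else "s"))
  if (length(object@params))
    cat(sprintf("  mined at support %.3g%% (threshold %d of %d graphs), size %d..%d\n",
                object@params$supportPct, object@params$threshold,
                object@params$nGraphs, object@params$minSize,
                object@params$maxSize))
  if (n) {
    k <- min(n, 5L)
    sz <- vapply(object@nodeLabels, length, integer(1))
    for (p in seq_len(k))
      cat(sprintf("  %s  size %d, support %d\n", object@canonicalCode[p],
                  sz[p], object@supportCount[p]))
    if (n > k) cat(sprintf("  ... and %d more\n", n - k))
  }
})

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
#' @export
setMethod("featureFragments", "FeatureMatrix", function(x) x@fragments)

#' @rdname FeatureMatrix-class
#' @export
setMethod("dim", "FeatureMatrix", function(x) dim(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d graphs x %d fragments (density %.3f)\n",
              nrow(object@values), ncol(object@values),
              if (length(object@values)) mean(object@values) else NA_real_))
})

setMethod("show", "CnnModel", function(object) {
  cfg <- object@config
  cat(sprintf(paste0("CnnModel: input %d -> conv(%dx%d) -> pool -> ",
                     "conv(%dx%d) -> pool -> flatten %d -> hidden %d -> %d classes\n"),
              cfg$inputLength, cfg$n1, cfg$k1, cfg$n2, cfg$k2,
              cnnDimensions(cfg$inputLength, cfg$k1, cfg$k2, cfg$pool,
                            cfg$n2)$flatten,
              cfg$hidden, cfg$nClasses))
  cat(sprintf("  classes: %s\n", paste(object@classLabels, collapse = ", ")))
})

#' @rdname EvalReport-class
#' @export
setMethod("confusion", "EvalReport", function(x) x@confusion)

#' @rdname EvalReport-class
#' @export
setMethod("perClassMetrics", "EvalReport", function(x) x@perClass)

#' @rdname EvalReport-class
#' @export
setMethod("macroMetrics", "EvalReport", function(x) x@macro)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport over %d records, %d classes\n",
              sum(object@confusion), nrow(object@confusion)))
  cat(sprintf("  micro (trace) accuracy: %.4f\n", object@microAccuracy))
  m <- object@macro
  cat(sprintf("  macro: acc %.4f  sens %.4f  spec %.4f  prec %.4f  F %.4f  MCC %.4f\n",
              m[["accuracy"]], m[["sensitivity"]], m[["specificity"]],
              m[["precision"]], m[["fscore"]], m[["mcc"]]))
})
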