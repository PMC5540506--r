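#' @rdname RNAStructSet-class
#' @param x,object an object.
#' @export
setGeneric("seqIds", function(x) standardGeneric("seqIds"))

#' @rdname RNAStructSet-class
#' @export
setGeneric("rnaSequences", function(x) standardGeneric("rnaSequences"))

#' @rdname RNAStructSet-class
#' @export
setGeneric("rnaStructures", function(x) standardGeneric("rnaStructures"))

#' @rdname RNAStructSet-class
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))

#' @rdname StructureGraph-class
#' @param x an object.
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))

#' @rdname StructureGraph-class
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' @rdname FragmentSet-class
#' @param x an object.
#' @export
setGeneric("canonicalCodes", function(x) standardGeneric("canonicalCodes"))

#' @rdname FragmentSet-class
#' @export
setGeneric("supportCounts", function(x) standardGeneric("supportCounts"))

#' @rdname FragmentSet-class
#' @export
setGeneric("supportingIds", function(x) standardGeneric("supportingIds"))

#' @rdname FragmentSet-class
#' @export
setGeneric("fragmentSizes", function(x) standardGeneric("fragmentSizes"))

#' @rdname FeatureMatrix-class
#' @param x an object.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix-class
#' @export
setGeneric("featureFragments", function(x) standardGeneric("featureFragments"))

#' @rdname EvalReport-class
#' @param x an object.
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' @rdname EvalReport-class
#' @export
setGeneric("perClassMetrics", function(x) standardGeneric("perClassMetrics"))

#' @rdname EvalReport-class
#' @export
setGeneric("macroMetrics", function(x) standardGeneric("macroMetrics"))
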