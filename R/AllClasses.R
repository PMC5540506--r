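#' @import methods
NULL

#' RNAStructSet: a set of RNA sequences with optional structures and labels
#'
#' The unit flowing through the classification pipeline: each element is one
#' RNA sequence over the normalized alphabet \{A,C,G,U,N\}, with an optional
#' secondary structure in (extended) dot-bracket notation of equal length and
#' an optional class label. Identifiers are unique within a set.
#'
#' @slot id character, unique non-empty sequence identifiers.
#' @slot sequence character, sequences over A/C/G/U/N.
#' @slot structure character, dot-bracket strings (NA until attached).
#' @slot classLabel character, class names (NA if unlabelled).
#'
#' @seealso [readFastaRecords()], [attachStructures()], [structureGraphs()]
#' @export
setClass("RNAStructSet",
  representation(id = "character", sequence = "character",
                 structure = "character", classLabel = "character"))

setValidity("RNAStructSet", function(object) {
  n <- length(object@id)
  if (length(object@sequence) != n || length(object@structure) != n ||
      length(object@classLabel) != n)
    return("id, sequence, structure and classLabel must have equal length")
  if (any(is.na(object@id)) || any(!nzchar(object@id)))
    return("ids must be non-empty")
  if (anyDuplicated(object@id)) {
    dup <- object@id[duplicated(object@id)][1L]
    return(sprintf("duplicate id '%s'", dup))
  }
  bad <- grepl("[^ACGUN]", object@sequence)
  if (any(bad))
    return(sprintf("sequence for '%s' contains characters outside A/C/G/U/N",
                   object@id[bad][1L]))
  has <- !is.na(object@structure)
  if (any(has)) {
    mism <- has & nchar(object@structure) != nchar(object@sequence)
    if (any(mism))
      return(sprintf("structure length differs from sequence length for '%s'",
                     object@id[mism][1L]))
  }
  TRUE
})

#' Construct an RNAStructSet
#'
#' @param id character vector of unique identifiers.
#' @param sequence character vector of RNA sequences (normalized with
#'   [normalizeRnaSequence()] if `normalize = TRUE`).
#' @param structure optional character vector of dot-bracket strings.
#' @param classLabel optional character vector of class names.
#' @param normalize logical; normalize sequences (T to U, upper-case,
#'   unknown characters to N).
#' @return An [RNAStructSet-class] object.
#' @examples
#' RNAStructSet(c("a", "b"), c("GAAAC", "ACGU"),
#'              structure = c("(...)", NA))
#' @export
RNAStructSet <- function(id, sequence, structure = NA_character_,
                         classLabel = NA_character_, normalize = TRUE) {
  n <- length(id)
  if (normalize) sequence <- normalizeRnaSequence(sequence)
  new("RNAStructSet",
      id = as.character(id),
      sequence = as.character(sequence),
      structure = rep_len(as.character(structure), n),
      classLabel = rep_len(as.character(classLabel), n))
}

#' Normalize an RNA sequence string
#'
#' Upper-cases, maps T to U and any character outside \{A,C,G,U\} to N.
#' N matches only N during fragment mining (no wildcard semantics).
#'
#' @param x character vector of raw sequences.
#' @return character vector of normalized sequences.
#' @export
normalizeRnaSequence <- function(x) {
  x <- chartr("t", "u", toupper(x))
  x <- chartr("T", "U", x)
  gsub("[^ACGU]", "N", x)
}

#' StructureGraph: labelled graph of one RNA secondary structure
#'
#' Nucleotide positions are vertices (labelled by base), consecutive
#' positions are joined by `backbone` edges and base pairs by `pair` edges.
#' Positions are 1-based. Backbone edges form the simple path
#' (1,2),(2,3),...; each base pairs with at most one partner; a pair between
#' adjacent bases is rejected.
#'
#' @slot graphId character scalar, the originating record id.
#' @slot nodeLabels character vector of nucleotide labels, position order.
#' @slot edges data.frame with columns `i`, `j` (integer, i < j) and
#'   `bond` ("backbone" or "pair").
#' @seealso [buildStructureGraph()], [parseDotBracket()]
#' @export
setClass("StructureGraph",
  representation(graphId = "character", nodeLabels = "character",
                 edges = "data.frame"))

setValidity("StructureGraph", function(object) {
  e <- object@edges
  L <- length(object@nodeLabels)
  if (!all(c("i", "j", "bond") %in% names(e)))
    return("edges must have columns i, j, bond")
  if (nrow(e)) {
    if (any(e$i >= e$j)) return("edges must satisfy i < j")
    if (any(e$i < 1L) || any(e$j > L)) return("edge endpoints out of range")
    if (anyDuplicated(e[, c("i", "j")])) return("duplicate edges")
  }
  bb <- e[e$bond == "backbone", , drop = FALSE]
  want <- if (L > 1L) cbind(seq_len(L - 1L), seq(2L, L)) else
    matrix(integer(0), ncol = 2)
  if (nrow(bb) != nrow(want) ||
      (nrow(bb) && !all(bb$i == want[, 1] & bb$j == want[, 2])))
    return("backbone edges must be exactly the consecutive-position path")
  pr <- e[e$bond == "pair", , drop = FALSE]
  if (nrow(pr)) {
    if (any(pr$j - pr$i == 1L)) return("adjacent base pair")
    if (anyDuplicated(c(pr$i, pr$j)))
      return("a base pairs with more than one partner")
  }
  TRUE
})

#' FragmentSet: mined closed frequent sub-graph fragments
#'
#' Each fragment is a connected labelled graph over fragment-local 1-based
#' node ids, identified up to isomorphism by its canonical code, together
#' with the number (and ids) of graphs in the mined collection containing
#' at least one label- and bond-preserving embedding of it.
#'
#' @slot canonicalCode character vector, one code per fragment.
#' @slot nodeLabels list of character vectors.
#' @slot edges list of data.frames (i, j, bond).
#' @slot supportCount integer vector.
#' @slot supportingIds list of character vectors of graph ids (may be empty
#'   when a set is re-loaded from a fragment file).
#' @slot params list of the mining parameters used (may be empty).
#' @seealso [mineClosedFragments()], [readFragments()]
#' @export
setClass("FragmentSet",
  representation(canonicalCode = "character", nodeLabels = "list",
                 edges = "list", supportCount = "integer",
                 supportingIds = "list", params = "list"))

setValidity("FragmentSet", function(object) {
  n <- length(object@canonicalCode)
  if (length(object@nodeLabels) != n || length(object@edges) != n ||
      length(object@supportCount) != n || length(object@supportingIds) != n)
    return("slot lengths differ")
  if (anyDuplicated(object@canonicalCode))
    return("duplicate canonical codes")
  TRUE
})

#' FeatureMatrix: boolean graphs-by-fragments containment matrix
#'
#' Row i, column j is 1 when fragment j has at least one embedding in graph
#' i. Columns follow the fragment order (size ascending, canonical code
#' ascending); rows carry graph ids.
#'
#' @slot values integer matrix of 0/1 with dimnames (graph ids, codes).
#' @slot fragments the [FragmentSet-class] defining the feature space.
#' @seealso [buildFeatureMatrix()], [projectGraphs()]
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", fragments = "FragmentSet"))

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  if (ncol(v) != length(object@fragments@canonicalCode))
    return("column count differs from fragment count")
  if (length(v) && !all(v %in% c(0L, 1L)))
    return("values must be 0/1")
  if (is.null(rownames(v)) && nrow(v) > 0L)
    return("rows must carry graph ids")
  if (nrow(v) && anyDuplicated(rownames(v)))
    return("duplicate graph ids")
  TRUE
})

#' CnnModel: trained convolutional network over a frozen feature space
#'
#' Two valid (no-padding) convolutional layers with logistic activations and
#' width-2 max-pooling feed a one-hidden-layer perceptron (tanh hidden
#' units, softmax output). The model stores the fragment column order it was
#' trained on, so unseen sequences are projected into the identical feature
#' space before prediction.
#'
#' @slot config list of hyperparameters (see [cnnConfig()]).
#' @slot W1 matrix n1 x k1, first-layer kernels. @slot b1 numeric n1.
#' @slot W2 matrix n2 x (n1*k2), second-layer multi-channel kernels
#'   (column block a holds the n1 channel weights at window offset a).
#' @slot b2 numeric n2.
#' @slot M1 matrix flatten x hidden. @slot bh numeric hidden.
#' @slot M2 matrix hidden x nClasses. @slot bo numeric nClasses.
#' @slot classLabels character, output class order.
#' @slot fragmentCodes character, frozen feature-space column order.
#' @seealso [trainCnn()], [cnnConfig()]
#' @export
setClass("CnnModel",
  representation(config = "list", W1 = "matrix", b1 = "numeric",
                 W2 = "matrix", b2 = "numeric", M1 = "matrix",
                 bh = "numeric", M2 = "matrix", bo = "numeric",
                 classLabels = "character", fragmentCodes = "character"))

setValidity("CnnModel", function(object) {
  if (length(object@fragmentCodes) != object@config$inputLength)
    return("fragmentCodes length differs from config inputLength")
  if (length(object@classLabels) != object@config$nClasses)
    return("classLabels length differs from config nClasses")
  TRUE
})

#' EvalReport: confusion matrix and per-class statistics
#'
#' Holds the fold-aggregated confusion matrix (rows true class, columns
#' predicted class, in class-label order), the one-vs-rest counts and six
#' statistics (accuracy, sensitivity, specificity, precision, F-score, MCC)
#' per class, their unweighted macro averages, and the overall
#' trace/total (micro) accuracy.
#'
#' @slot confusion integer matrix with class dimnames.
#' @slot perClass data.frame, one row per class.
#' @slot macro named numeric of the six macro-averaged statistics.
#' @slot microAccuracy numeric scalar, trace(confusion)/sum(confusion).
#' @seealso [evalReport()], [crossValidate()]
#' @export
setClass("EvalReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 macro = "numeric", microAccuracy = "numeric"))

setValidity("EvalReport", function(object) {
  cm <- object@confusion
  if (nrow(cm) != ncol(cm)) return("confusion matrix must be square")
  if (nrow(object@perClass) != nrow(cm))
    return("perClass must have one row per class")
  TRUE
})
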