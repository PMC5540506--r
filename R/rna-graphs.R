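# Reading sequences/structures and turning them into labelled graphs.

#' Read a FASTA file into an RNAStructSet
#'
#' Sequences are normalized on input: upper-cased, T mapped to U, and any
#' other character outside A/C/G/U mapped to N. Wrapped sequence lines are
#' concatenated; file order is preserved. The record id is the first
#' whitespace-delimited token of the header line.
#'
#' @param path path to a FASTA file.
#' @return An [RNAStructSet-class] without structures or labels.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">x", "ACGT"), fa)
#' rnaSequences(readFastaRecords(fa))
#' @export
readFastaRecords <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[nzchar(trimws(first))]
  if (length(first) == 0L)
    stop("empty FASTA file: ", path, call. = FALSE)
  if (!startsWith(first[1L], ">"))
    stop("sequence line before any header in ", path, call. = FALSE)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate id '%s' in %s", ids[duplicated(ids)][1L], path),
         call. = FALSE)
  RNAStructSet(ids, as.character(ss))
}

#' Read dot-bracket structures
#'
#' `readViennaFile()` reads the common 3-line layout (one record = a '>' id
#' line, the sequence line, the structure line) and returns an
#' [RNAStructSet-class] with structures attached. `readStructureTable()`
#' reads a 2-column TSV (id, structure) intended to be paired with a FASTA
#' via [attachStructures()].
#'
#' @param path path to the file.
#' @return `readViennaFile()`: an RNAStructSet; `readStructureTable()`:
#'   a named character vector of structures.
#' @export
readViennaFile <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) == 0L) stop("empty structure file: ", path, call. = FALSE)
  if (!startsWith(ln[1L], ">"))
    stop("expected '>' header as first line of ", path, call. = FALSE)
  if (length(ln) %% 3L != 0L)
    stop("malformed 3-line structure file (line count not a multiple of 3): ",
         path, call. = FALSE)
  hd <- seq(1L, length(ln), by = 3L)
  if (!all(startsWith(ln[hd], ">")))
    stop("malformed 3-line structure file: headers out of register in ",
         path, call. = FALSE)
  ids <- sub("\\s.*$", "", sub("^>", "", ln[hd]))
  RNAStructSet(ids, ln[hd + 1L], structure = trimws(ln[hd + 2L]))
}

#' @rdname readViennaFile
#' @export
readStructureTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2L)
    stop("structure table must have two columns (id, structure)",
         call. = FALSE)
  structure(tab[[2L]], names = tab[[1L]])
}

#' Attach structures to sequence records
#'
#' @param records an [RNAStructSet-class].
#' @param structures a named character vector (id to dot-bracket string),
#'   e.g. from [readStructureTable()], or an RNAStructSet with structures.
#' @return the records with structure strings filled in; every record must
#'   receive a structure of matching length.
#' @export
attachStructures <- function(records, structures) {
  if (is(structures, "RNAStructSet"))
    structures <- rnaStructures(structures)
  idx <- match(seqIds(records), names(structures))
  if (anyNA(idx))
    stop(sprintf("no structure for id '%s'",
                 seqIds(records)[is.na(idx)][1L]), call. = FALSE)
  new("RNAStructSet", id = records@id, sequence = records@sequence,
      structure = unname(structures[idx]), classLabel = records@classLabel)
}

#' Read a class-label manifest (TSV id, class) and attach labels
#'
#' @param path 2-column TSV mapping sequence id to class name.
#' @param records optionally, an [RNAStructSet-class] to attach labels to.
#' @return With `records`: the labelled set; otherwise a named character
#'   vector id -> class.
#' @export
readLabelManifest <- function(path, records = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 2L)
    stop("label manifest must have two columns (id, class)", call. = FALSE)
  labels <- structure(tab[[2L]], names = tab[[1L]])
  if (is.null(records)) return(labels)
  idx <- match(seqIds(records), names(labels))
  if (anyNA(idx))
    stop(sprintf("no class label for id '%s'",
                 seqIds(records)[is.na(idx)][1L]), call. = FALSE)
  new("RNAStructSet", id = records@id, sequence = records@sequence,
      structure = records@structure, classLabel = unname(labels[idx]))
}

## Bracket families of the extended dot-bracket alphabet. Each family is
## independently balanced; families may cross (pseudoknots).
.bracketFamilies <- local({
  open <- c("(", "[", "{", "<", LETTERS)
  close <- c(")", "]", "}", ">", letters)
  list(open = open, close = close)
})

#' Parse extended dot-bracket notation into base pairs
#'
#' Supports the bracket families `()`, `[]`, `{}`, `<>` and `A-Z` paired
#' with `a-z` (pseudoknot notation as emitted by structure predictors).
#' Matching is per-family by stack; pairs from different families may cross.
#'
#' @param structure a dot-bracket string.
#' @return data.frame with integer columns `i`, `j` (1-based positions,
#'   i < j), one row per base pair, ordered by `i`.
#' @examples
#' parseDotBracket("((..))")
#' parseDotBracket("([)]")  # two crossing families
#' @export
parseDotBracket <- function(structure) {
  .assertScalarString(structure, "structure")
  ch <- strsplit(structure, "", fixed = TRUE)[[1L]]
  fam <- .bracketFamilies
  openIdx <- match(ch, fam$open)
  closeIdx <- match(ch, fam$close)
  bad <- which(ch != "." & is.na(openIdx) & is.na(closeIdx))
  if (length(bad))
    stop(sprintf("illegal character '%s' at position %d", ch[bad[1L]],
                 bad[1L]), call. = FALSE)
  stacks <- vector("list", length(fam$open))
  iOut <- integer(0); jOut <- integer(0)
  for (p in seq_along(ch)) {
    f <- openIdx[p]
    if (!is.na(f)) {
      stacks[[f]] <- c(stacks[[f]], p)
      next
    }
    f <- closeIdx[p]
    if (!is.na(f)) {
      s <- stacks[[f]]
      if (length(s) == 0L)
        stop(sprintf("unbalanced '%s' at position %d: no matching '%s'",
                     ch[p], p, fam$open[f]), call. = FALSE)
      iOut <- c(iOut, s[length(s)])
      jOut <- c(jOut, p)
      stacks[[f]] <- s[-length(s)]
    }
  }
  left <- which(lengths(stacks) > 0L)
  if (length(left))
    stop(sprintf("unbalanced '%s' at end: %d unmatched",
                 fam$open[left[1L]], length(stacks[[left[1L]]])),
         call. = FALSE)
  ord <- order(iOut)
  data.frame(i = iOut[ord], j = jOut[ord])
}

#' Build the labelled structure graph of one (sequence, structure) pair
#'
#' Vertices are nucleotide positions labelled by base; consecutive positions
#' are joined by `backbone` edges and each parsed base pair contributes one
#' `pair` edge. A pair between adjacent positions is geometrically
#' impossible and rejected.
#'
#' @param sequence normalized RNA sequence string.
#' @param structure dot-bracket string of equal length.
#' @param graphId identifier for the graph.
#' @return A [StructureGraph-class].
#' @examples
#' buildStructureGraph("GAAAC", "(...)", "hairpin")
#' @export
buildStructureGraph <- function(sequence, structure, graphId = "g1") {
  .assertScalarString(sequence, "sequence")
  .assertScalarString(structure, "structure")
  L <- nchar(sequence)
  if (nchar(structure) != L)
    stop(sprintf("structure length %d differs from sequence length %d for '%s'",
                 nchar(structure), L, graphId), call. = FALSE)
  pairs <- parseDotBracket(structure)
  if (nrow(pairs) && any(pairs$j - pairs$i == 1L))
    stop(sprintf("adjacent base pair (%d,%d) in '%s'",
                 pairs$i[which(pairs$j - pairs$i == 1L)[1L]],
                 pairs$j[which(pairs$j - pairs$i == 1L)[1L]], graphId),
         call. = FALSE)
  labels <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bb <- if (L > 1L)
    .makeEdges(seq_len(L - 1L), seq(2L, L), "backbone") else .emptyEdges()
  pe <- if (nrow(pairs)) .makeEdges(pairs$i, pairs$j, "pair") else
    .emptyEdges()
  new("StructureGraph", graphId = graphId, nodeLabels = labels,
      edges = rbind(bb, pe))
}

#' Build structure graphs for every record of a set
#'
#' @param records an [RNAStructSet-class] with structures attached.
#' @return named list of [StructureGraph-class] objects, in record order.
#' @export
structureGraphs <- function(records) {
  if (any(is.na(records@structure)))
    stop(sprintf("record '%s' has no structure attached",
                 records@id[is.na(records@structure)][1L]), call. = FALSE)
  out <- lapply(seq_along(records@id), function(p)
    buildStructureGraph(records@sequence[p], records@structure[p],
                        records@id[p]))
  names(out) <- records@id
  out
}
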