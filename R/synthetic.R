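# Synthetic labelled ncRNA-like datasets: each class is defined by a
# characteristic hairpin motif (class-specific stem length, innermost pair
# and loop trinucleotide) embedded at a random offset in unpaired random
# flanking sequence. Structures are emitted with the ground-truth pairing;
# substitution noise perturbs the sequence only, modelling the mismatch
# between a predicted structure and the underlying sequence.

.basePairs <- list(c("G", "C"), c("C", "G"), c("A", "U"), c("U", "A"),
                   c("G", "U"))
.loopTable <- c("GAA", "UUC", "CGC", "AAG", "UCU", "ACA", "GGU", "CAC")

## Deterministic class signature: stem of length 3 + classIndex whose pairs
## cycle through the pair table with a class-specific phase, plus a
## class-specific loop trinucleotide.
.classMotif <- function(classIndex) {
  stemLen <- 3L + classIndex
  pairs <- lapply(seq_len(stemLen), function(d)
    .basePairs[[((classIndex + d - 1L) %% length(.basePairs)) + 1L]])
  left <- vapply(pairs, `[`, character(1), 1L)
  right <- rev(vapply(pairs, `[`, character(1), 2L))
  loop <- .loopTable[((classIndex - 1L) %% length(.loopTable)) + 1L]
  seq <- paste0(paste(left, collapse = ""), loop,
                paste(right, collapse = ""))
  struct <- paste0(strrep("(", stemLen), "...", strrep(")", stemLen))
  list(sequence = seq, structure = struct, length = nchar(seq))
}

#' Specification of a synthetic dataset
#'
#' @param nClasses number of classes (>= 2); class c carries a hairpin
#'   motif with a stem of 3 + c base pairs and a class-specific loop.
#' @param perClass records per class.
#' @param lengthRange integer pair, min/max record length in nucleotides;
#'   the minimum must accommodate the largest motif.
#' @param mutationRate per-position probability of nucleotide substitution
#'   applied after motif embedding (sequence only; the structure string is
#'   kept).
#' @param seed integer RNG seed; generation is fully deterministic given
#'   the spec.
#' @return validated spec list.
#' @export
syntheticSpec <- function(nClasses = 5L, perClass = 40L,
                          lengthRange = c(25L, 40L), mutationRate = 0,
                          seed = 1L) {
  spec <- list(nClasses = as.integer(nClasses),
               perClass = as.integer(perClass),
               lengthRange = as.integer(lengthRange),
               mutationRate = mutationRate, seed = as.integer(seed))
  if (spec$nClasses < 2L) stop("need at least 2 classes", call. = FALSE)
  if (spec$perClass < 1L) stop("need at least 1 record per class",
                               call. = FALSE)
  if (spec$mutationRate < 0 || spec$mutationRate > 1)
    stop("mutationRate must be in [0, 1]", call. = FALSE)
  if (length(spec$lengthRange) != 2L ||
      spec$lengthRange[1L] > spec$lengthRange[2L])
    stop("lengthRange must be c(min, max)", call. = FALSE)
  maxMotif <- .classMotif(spec$nClasses)$length
  if (spec$lengthRange[1L] < maxMotif)
    stop(sprintf("minimum length %d is shorter than the largest class motif (%d nt)",
                 spec$lengthRange[1L], maxMotif), call. = FALSE)
  spec
}

#' Generate a labelled synthetic dataset
#'
#' @param spec a [syntheticSpec()].
#' @return An [RNAStructSet-class] with structures and class labels;
#'   exactly `nClasses * perClass` records, `perClass` per label, ids
#'   `class<k>_r<i>`.
#' @examples
#' ds <- generateDataset(syntheticSpec(nClasses = 3, perClass = 5))
#' table(classLabels(ds))
#' @export
generateDataset <- function(spec) {
  spec <- do.call(syntheticSpec, spec)   # re-validate
  set.seed(spec$seed)
  alphabet <- c("A", "C", "G", "U")
  ids <- character(0); seqs <- character(0); structs <- character(0)
  labs <- character(0)
  for (cls in seq_len(spec$nClasses)) {
    motif <- .classMotif(cls)
    for (r in seq_len(spec$perClass)) {
      len <- sample(spec$lengthRange[1L]:spec$lengthRange[2L], 1L)
      offset <- sample.int(len - motif$length + 1L, 1L) - 1L
      flankL <- paste(sample(alphabet, offset, replace = TRUE),
                      collapse = "")
      nR <- len - offset - motif$length
      flankR <- paste(sample(alphabet, nR, replace = TRUE), collapse = "")
      seq <- paste0(flankL, motif$sequence, flankR)
      struct <- paste0(strrep(".", offset), motif$structure,
                       strrep(".", nR))
      if (spec$mutationRate > 0) {
        ch <- strsplit(seq, "")[[1L]]
        hit <- which(stats::runif(len) < spec$mutationRate)
        for (p in hit)
          ch[p] <- sample(setdiff(alphabet, ch[p]), 1L)
        seq <- paste(ch, collapse = "")
      }
      ids <- c(ids, sprintf("class%d_r%03d", cls, r))
      seqs <- c(seqs, seq)
      structs <- c(structs, struct)
      labs <- c(labs, sprintf("class%d", cls))
    }
  }
  RNAStructSet(ids, seqs, structure = structs, classLabel = labs,
               normalize = FALSE)
}

#' Toy secondary-structure folder (base-pair maximization)
#'
#' Nussinov-style dynamic programming over Watson-Crick and GU wobble
#' pairs with a minimum hairpin loop of 3 unpaired bases; the traceback is
#' deterministic (prefers pairing the left end with the smallest admissible
#' partner). Emits nested structures only (no pseudoknots). A test
#' stand-in for an external structure predictor, exercising the
#' FASTA-only input path.
#'
#' @param sequence RNA string over A/C/G/U.
#' @return dot-bracket string of equal length.
#' @examples
#' toyFold("GAAAC")      # "(...)"
#' toyFold("GGGAAACCC")  # "(((...)))"
#' @export
toyFold <- function(sequence) {
  .assertScalarString(sequence, "sequence")
  ch <- strsplit(toupper(sequence), "")[[1L]]
  if (any(!ch %in% c("A", "C", "G", "U")))
    stop("sequence must be over A/C/G/U", call. = FALSE)
  n <- length(ch)
  canPair <- function(a, b)
    paste0(a, b) %in% c("GC", "CG", "AU", "UA", "GU", "UG")
  N <- matrix(0L, n, n)
  if (n >= 5L)
    for (span in 4L:(n - 1L))
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- N[i + 1L, j]
        for (k in (i + 4L):j) {
          if (!canPair(ch[i], ch[k])) next
          inner <- if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L
          outer <- if (k + 1L <= j) N[k + 1L, j] else 0L
          best <- max(best, 1L + inner + outer)
        }
        N[i, j] <- best
      }
  out <- rep(".", n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- iv[1L]; j <- iv[2L]
    if (i >= j || j - i < 4L) next
    paired <- FALSE
    for (k in (i + 4L):j) {
      if (!canPair(ch[i], ch[k])) next
      inner <- if (k - 1L >= i + 1L) N[i + 1L, k - 1L] else 0L
      outer <- if (k + 1L <= j) N[k + 1L, j] else 0L
      if (1L + inner + outer == N[i, j]) {
        out[i] <- "("; out[k] <- ")"
        if (k - 1L >= i + 1L) stack[[length(stack) + 1L]] <- c(i + 1L, k - 1L)
        if (k + 1L <= j) stack[[length(stack) + 1L]] <- c(k + 1L, j)
        paired <- TRUE
        break
      }
    }
    if (!paired) stack[[length(stack) + 1L]] <- c(i + 1L, j)
  }
  paste(out, collapse = "")
}

#' Write a dataset to the pipeline's file formats
#'
#' Writes `sequences.fasta`, `structures.db` (3-line dot-bracket records)
#' and `labels.tsv` (id, class), the same formats the command-line
#' interface consumes; the files round-trip through [readFastaRecords()],
#' [readViennaFile()] and [readLabelManifest()].
#'
#' @param records labelled [RNAStructSet-class] with structures.
#' @param outDir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
writeDataset <- function(records, outDir) {
  if (length(records) == 0L) stop("no records to write", call. = FALSE)
  if (any(is.na(records@structure)))
    stop("records must have structures attached", call. = FALSE)
  if (any(is.na(records@classLabel)))
    stop("records must carry class labels", call. = FALSE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  paths <- c(fasta = file.path(outDir, "sequences.fasta"),
             structures = file.path(outDir, "structures.db"),
             labels = file.path(outDir, "labels.tsv"))
  writeLines(paste0(">", records@id, "\n", records@sequence),
             paths[["fasta"]])
  writeLines(paste0(">", records@id, "\n", records@sequence, "\n",
                    records@structure), paths[["structures"]])
  utils::write.table(data.frame(id = records@id,
                                class = records@classLabel),
                     paths[["labels"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}
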