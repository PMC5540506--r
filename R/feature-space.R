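# Boolean containment features over a mined (or frozen) fragment space.

## Host-graph view used by the backtracking matcher.
.hostView <- function(graph) {
  p <- .asPlain(graph)
  n <- length(p$labels)
  bond <- matrix(NA_character_, n, n)
  if (nrow(p$edges))
    for (r in seq_len(nrow(p$edges))) {
      bond[p$edges$i[r], p$edges$j[r]] <- p$edges$bond[r]
      bond[p$edges$j[r], p$edges$i[r]] <- p$edges$bond[r]
    }
  adj <- .adjacency(p$labels, p$edges)
  list(labels = p$labels, bond = bond, nb = adj$nb, deg = lengths(adj$nb))
}

## Matching order: most-constrained-first, every later node anchored to an
## earlier one (fragments are connected), with the anchor edges to check.
.matchPlan <- function(labels, edges) {
  s <- length(labels)
  adj <- .adjacency(labels, edges)
  deg <- lengths(adj$nb)
  ord <- integer(s)
  placed <- logical(s)
  ord[1L] <- which.max(deg)
  placed[ord[1L]] <- TRUE
  if (s > 1L)
    for (k in 2L:s) {
      links <- vapply(seq_len(s), function(v)
        if (placed[v]) -1L else sum(placed[adj$nb[[v]]]), integer(1))
      pick <- which(links == max(links))[1L]
      ord[k] <- pick
      placed[pick] <- TRUE
    }
  anchors <- vector("list", s)
  pos <- match(seq_len(s), ord)
  if (nrow(edges))
    for (r in seq_len(nrow(edges))) {
      i <- edges$i[r]; j <- edges$j[r]
      late <- if (pos[i] > pos[j]) i else j
      early <- if (late == i) j else i
      anchors[[pos[late]]] <-
        rbind(anchors[[pos[late]]],
              data.frame(earlierPos = pos[early], bond = edges$bond[r],
                         stringsAsFactors = FALSE))
    }
  list(ord = ord, labels = labels[ord], anchors = anchors, deg = deg[ord])
}

## TRUE iff the planned fragment embeds in the host view.
.embedExists <- function(host, plan) {
  s <- length(plan$labels)
  assign <- integer(s)
  found <- FALSE
  recurse <- function(k) {
    if (found) return()
    if (k > s) { found <<- TRUE; return() }
    anc <- plan$anchors[[k]]
    cand <- if (is.null(anc)) {
      which(host$labels == plan$labels[k] & host$deg >= plan$deg[k])
    } else {
      first <- host$nb[[assign[anc$earlierPos[1L]]]]
      first[host$labels[first] == plan$labels[k]]
    }
    for (v in cand) {
      if (v %in% assign[seq_len(k - 1L)]) next
      if (host$deg[v] < plan$deg[k]) next
      ok <- TRUE
      if (!is.null(anc))
        for (r in seq_len(nrow(anc))) {
          b <- host$bond[v, assign[anc$earlierPos[r]]]
          if (is.na(b) || b != anc$bond[r]) { ok <- FALSE; break }
        }
      if (ok) {
        assign[k] <<- v
        recurse(k + 1L)
        assign[k] <<- 0L
        if (found) return()
      }
    }
  }
  recurse(1L)
  found
}

#' Test fragment containment in a structure graph
#'
#' A fragment is contained when a label- and bond-preserving sub-graph
#' isomorphic embedding exists (sub-graph, not induced: the host may have
#' extra edges among the matched nodes). Matching is exact backtracking
#' with label/degree pruning.
#'
#' @param graph a [StructureGraph-class].
#' @param fragments a [FragmentSet-class].
#' @return logical vector, one entry per fragment.
#' @export
containsFragment <- function(graph, fragments) {
  host <- .hostView(graph)
  vapply(seq_along(fragments@canonicalCode), function(f) {
    plan <- .matchPlan(fragments@nodeLabels[[f]], fragments@edges[[f]])
    .embedExists(host, plan)
  }, logical(1))
}

.containmentValues <- function(graphs, fragments) {
  ids <- .graphIdsOf(graphs)
  nF <- length(fragments)
  vals <- matrix(0L, nrow = length(graphs), ncol = nF,
                 dimnames = list(ids, fragments@canonicalCode))
  if (length(graphs) == 0L || nF == 0L) return(vals)
  plans <- lapply(seq_len(nF), function(f)
    .matchPlan(fragments@nodeLabels[[f]], fragments@edges[[f]]))
  for (g in seq_along(graphs)) {
    host <- .hostView(graphs[[g]])
    vals[g, ] <- vapply(plans, function(pl)
      as.integer(.embedExists(host, pl)), integer(1))
  }
  vals
}

#' Build the boolean graphs-by-fragments feature matrix
#'
#' Entry (i, j) is 1 when fragment j is contained in graph i, recomputed by
#' sub-graph isomorphism. When the fragments were mined over these same
#' graphs the column sums equal the mined support counts (a property the
#' test suite checks).
#'
#' @param graphs non-empty list of [StructureGraph-class] objects.
#' @param fragments a non-empty [FragmentSet-class].
#' @return A [FeatureMatrix-class].
#' @export
buildFeatureMatrix <- function(graphs, fragments) {
  if (length(graphs) == 0L) stop("empty graph list", call. = FALSE)
  if (length(fragments) == 0L) stop("empty feature space", call. = FALSE)
  new("FeatureMatrix", values = .containmentValues(graphs, fragments),
      fragments = fragments)
}

#' Project graphs into a frozen feature space
#'
#' Containment is recomputed against a fixed fragment list (e.g. loaded
#' with [readFragments()] from a training run); there is no re-mining, so
#' fragments absent from a new graph simply yield 0 and the column order is
#' identical to the frozen space. Projecting the training graphs themselves
#' reproduces the training matrix exactly.
#'
#' @param graphs list of [StructureGraph-class] objects (may be empty: the
#'   result then has zero rows and the frozen column count).
#' @param fragments the frozen [FragmentSet-class].
#' @return A [FeatureMatrix-class].
#' @export
projectGraphs <- function(graphs, fragments) {
  if (length(fragments) == 0L) stop("empty feature space", call. = FALSE)
  new("FeatureMatrix", values = .containmentValues(graphs, fragments),
      fragments = fragments)
}

#' Feature matrix straight from a mining run
#'
#' Uses the supporting graph ids carried by a [mineClosedFragments()] result
#' instead of re-running the sub-graph matcher; equal to
#' [buildFeatureMatrix()] over the mined graphs (a tested invariant) and
#' much faster, so cross-validation uses it for the training portion.
#'
#' @param fragments a [FragmentSet-class] carrying supporting ids.
#' @param graphIds the mined graph ids, in the desired row order.
#' @return A [FeatureMatrix-class].
#' @export
miningFeatureMatrix <- function(fragments, graphIds) {
  if (length(fragments) == 0L) stop("empty feature space", call. = FALSE)
  if (anyDuplicated(graphIds))
    stop(sprintf("duplicate graph id '%s'",
                 graphIds[duplicated(graphIds)][1L]), call. = FALSE)
  vals <- matrix(0L, nrow = length(graphIds), ncol = length(fragments),
                 dimnames = list(graphIds, fragments@canonicalCode))
  for (f in seq_along(fragments@supportingIds))
    vals[graphIds %in% fragments@supportingIds[[f]], f] <- 1L
  new("FeatureMatrix", values = vals, fragments = fragments)
}

# ---- serialization --------------------------------------------------------

.fragmentFileVersion <- "# rnaFragNet fragments v1 (positions 1-based)"
.matrixFileVersion <- "# rnaFragNet feature-matrix v1"

.edgesToText <- function(e) {
  if (nrow(e) == 0L) return("")
  paste(paste0(e$i, "-", e$j, ":", e$bond), collapse = ";")
}

.edgesFromText <- function(txt) {
  if (is.na(txt) || !nzchar(txt)) return(.emptyEdges())
  parts <- strsplit(strsplit(txt, ";", fixed = TRUE)[[1L]], "[-:]")
  .makeEdges(vapply(parts, function(p) as.integer(p[1L]), integer(1)),
             vapply(parts, function(p) as.integer(p[2L]), integer(1)),
             vapply(parts, `[`, character(1), 3L))
}

#' Read and write fragment files
#'
#' Tab-separated with a version comment line and columns `canonical_code`,
#' `size`, `support_count`, `node_labels` (comma-joined) and `edges`
#' (semicolon-joined `i-j:bond`, 1-based fragment-local positions). Row
#' order is the deterministic mining order, so identical mining runs give
#' byte-identical files. Supporting graph ids are not serialized; a
#' re-loaded set is a frozen feature space for [projectGraphs()].
#'
#' @param fragments a [FragmentSet-class].
#' @param path file path.
#' @return `writeFragments()`: the path, invisibly. `readFragments()`: a
#'   [FragmentSet-class].
#' @export
writeFragments <- function(fragments, path) {
  sz <- vapply(fragments@nodeLabels, length, integer(1))
  df <- data.frame(
    canonical_code = fragments@canonicalCode,
    size = sz,
    support_count = fragments@supportCount,
    node_labels = vapply(fragments@nodeLabels, paste, character(1),
                         collapse = ","),
    edges = vapply(fragments@edges, .edgesToText, character(1)),
    stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.fragmentFileVersion, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFragments
#' @export
readFragments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", comment.char = "#",
                          quote = "")
  need <- c("canonical_code", "size", "support_count", "node_labels",
            "edges")
  if (!all(need %in% names(df)))
    stop("not a fragment file (missing columns): ", path, call. = FALSE)
  n <- nrow(df)
  new("FragmentSet",
      canonicalCode = df$canonical_code,
      nodeLabels = strsplit(df$node_labels, ",", fixed = TRUE),
      edges = lapply(df$edges, .edgesFromText),
      supportCount = as.integer(df$support_count),
      supportingIds = rep(list(character(0)), n),
      params = list())
}

#' Read and write feature-matrix files
#'
#' Tab-separated 0/1 matrix with a version comment line, a `graph_id`
#' column and one column per fragment canonical code.
#'
#' @param x a [FeatureMatrix-class].
#' @param path file path.
#' @param fragments optionally, the [FragmentSet-class] the matrix columns
#'   refer to (checked against the column header); otherwise the returned
#'   object carries codes only.
#' @return `writeFeatureMatrix()`: the path, invisibly.
#'   `readFeatureMatrix()`: a [FeatureMatrix-class].
#' @export
writeFeatureMatrix <- function(x, path) {
  df <- data.frame(graph_id = rownames(x@values), x@values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.matrixFileVersion, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path, fragments = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", quote = "",
                          check.names = FALSE)
  if (names(df)[1L] != "graph_id")
    stop("not a feature-matrix file: ", path, call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(vals) <- "integer"
  rownames(vals) <- df$graph_id
  codes <- colnames(vals)
  if (is.null(fragments)) {
    fragments <- new("FragmentSet", canonicalCode = codes,
                     nodeLabels = rep(list(character(0)), length(codes)),
                     edges = rep(list(.emptyEdges()), length(codes)),
                     supportCount = rep(NA_integer_, length(codes)),
                     supportingIds = rep(list(character(0)), length(codes)),
                     params = list())
  } else if (!identical(codes, fragments@canonicalCode)) {
    stop("feature space mismatch between matrix columns and fragment file",
         call. = FALSE)
  }
  new("FeatureMatrix", values = vals, fragments = fragments)
}
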