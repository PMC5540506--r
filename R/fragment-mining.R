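# Closed frequent connected sub-graph mining over labelled structure graphs.
#
# Fragments are connected labelled graphs matched by sub-graph (not induced
# sub-graph) isomorphism: a fragment may omit edges that exist between its
# nodes in a host graph. Fragment "size" is the NODE count (nucleotides).
# Support is the number of graphs containing at least one embedding;
# embedding multiplicity within one graph is irrelevant.

.permutationsOf <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in .permutationsOf(k - 1L))
    for (pos in seq_len(k))
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

## Iterated neighbourhood refinement: isomorphism-invariant ordered node
## classes, used to restrict the permutations tried by canonicalCode().
.refineClasses <- function(labels, edges) {
  n <- length(labels)
  adj <- .adjacency(labels, edges)
  inv <- vapply(seq_len(n), function(v) {
    inc <- sort(paste0(adj$bond[[v]], "~", labels[adj$nb[[v]]]))
    paste0(labels[v], "/", length(inc), "/", paste(inc, collapse = ";"))
  }, character(1))
  rank <- match(inv, sort(unique(inv)))
  repeat {
    key <- vapply(seq_len(n), function(v) {
      paste0(rank[v], "|", paste(sort(rank[adj$nb[[v]]]), collapse = ","))
    }, character(1))
    newRank <- match(key, sort(unique(key)))
    if (length(unique(newRank)) == length(unique(rank))) break
    rank <- newRank
  }
  rank
}

#' Canonical code of a connected labelled fragment graph
#'
#' A deterministic string equal for isomorphic fragments (respecting node
#' and bond labels) and distinct for non-isomorphic ones. Nodes are first
#' partitioned into isomorphism-invariant classes by iterated neighbourhood
#' refinement; the code is the lexicographic minimum of a
#' labels-plus-sorted-edge-list serialization over all class-respecting
#' node orderings.
#'
#' @param labels character vector of node labels, or a
#'   [StructureGraph-class] (in which case `edges` is taken from it).
#' @param edges data.frame with columns `i`, `j`, `bond` over 1-based
#'   node positions.
#' @return character scalar.
#' @examples
#' canonicalCode(c("A", "C"), data.frame(i = 1, j = 2, bond = "backbone"))
#' # identical to the reversed listing:
#' canonicalCode(c("C", "A"), data.frame(i = 1, j = 2, bond = "backbone"))
#' @export
canonicalCode <- function(labels, edges = NULL) {
  if (is(labels, "StructureGraph")) {
    edges <- labels@edges
    labels <- labels@nodeLabels
  }
  n <- length(labels)
  if (n == 0L) stop("empty fragment", call. = FALSE)
  if (is.null(edges)) edges <- .emptyEdges()
  if (!.isConnected(n, edges))
    stop("disconnected fragment has no canonical code", call. = FALSE)
  if (n == 1L) return(paste0(labels, "||"))
  rank <- .refineClasses(labels, edges)
  classes <- split(seq_len(n), rank)     # ordered by rank
  sizes <- lengths(classes)
  if (prod(factorial(sizes)) > 40320)
    stop("fragment too symmetric to canonicalise", call. = FALSE)
  perClass <- lapply(classes, function(nodes) {
    lapply(.permutationsOf(length(nodes)), function(p) nodes[p])
  })
  grid <- expand.grid(lapply(perClass, seq_along))
  best <- NULL
  ei <- edges$i; ej <- edges$j; eb <- edges$bond
  for (r in seq_len(nrow(grid))) {
    ord <- unlist(lapply(seq_along(perClass),
                         function(ci) perClass[[ci]][[grid[r, ci]]]),
                  use.names = FALSE)
    pos <- integer(n)
    pos[ord] <- seq_len(n)
    a <- pmin(pos[ei], pos[ej])
    b <- pmax(pos[ei], pos[ej])
    code <- paste0(paste(labels[ord], collapse = ","), "||",
                   paste(sort(paste0(a, "-", b, ":", eb)), collapse = ";"))
    if (is.null(best) || code < best) best <- code
  }
  best
}

## Build a FragmentSet from a list of entries
## list(code, labels, edges, support, ids), sorted (size asc, code asc).
.fragmentSetFrom <- function(entries, params) {
  sz <- vapply(entries, function(e) length(e$labels), integer(1))
  cd <- vapply(entries, function(e) e$code, character(1))
  ord <- order(sz, cd)
  entries <- entries[ord]
  new("FragmentSet",
      canonicalCode = cd[ord],
      nodeLabels = lapply(entries, function(e) e$labels),
      edges = lapply(entries, function(e) e$edges),
      supportCount = vapply(entries, function(e) as.integer(e$support),
                            integer(1)),
      supportingIds = lapply(entries, function(e) sort(e$ids)),
      params = params)
}

.checkMiningParams <- function(graphs, supportPct, minSize, maxSize) {
  if (length(graphs) == 0L) stop("empty graph list", call. = FALSE)
  if (!is.numeric(supportPct) || supportPct <= 0 || supportPct > 100)
    stop("supportPct must be in (0, 100]", call. = FALSE)
  if (minSize < 1L || minSize > maxSize)
    stop("need 1 <= minSize <= maxSize", call. = FALSE)
  thr <- as.integer(ceiling(supportPct / 100 * length(graphs)))
  if (thr < 1L)
    stop("support threshold computes to 0 graphs", call. = FALSE)
  thr
}

.graphIdsOf <- function(graphs) {
  ids <- vapply(seq_along(graphs), function(g) {
    gr <- graphs[[g]]
    if (is(gr, "StructureGraph")) gr@graphId
    else names(graphs)[g] %||% paste0("g", g)
  }, character(1))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate graph id '%s'", ids[duplicated(ids)][1L]),
         call. = FALSE)
  ids
}

#' Mine closed frequent connected sub-graphs
#'
#' Depth-first growth from single-node seeds: every one-edge extension of a
#' fragment (a new node reached by an edge, or an additional edge between
#' two fragment nodes) is generated from the fragment's complete embedding
#' lists; duplicates are pruned by canonical code. A fragment is reported
#' when its node count lies in `[minSize, maxSize]`, its support reaches
#' `ceiling(supportPct/100 * length(graphs))` graphs, and it is CLOSED
#' within the size window: no one-edge extension with at most `maxSize`
#' nodes has equal support. Output order is (size ascending, canonical code
#' ascending), so identical inputs give identical fragment files.
#'
#' @param graphs list of [StructureGraph-class] objects.
#' @param supportPct minimum support as a percentage of the graph count,
#'   in (0, 100].
#' @param minSize,maxSize minimum/maximum fragment size in nodes.
#' @return A [FragmentSet-class] with support counts and supporting graph
#'   ids.
#' @seealso [oracleMineFragments()] for the brute-force reference used in
#'   tests, [buildFeatureMatrix()] for the boolean containment matrix.
#' @export
mineClosedFragments <- function(graphs, supportPct, minSize, maxSize) {
  thr <- .checkMiningParams(graphs, supportPct, minSize, maxSize)
  ids <- .graphIdsOf(graphs)
  plain <- lapply(graphs, .asPlain)
  nG <- length(plain)

  ## Disjoint union of all host graphs: global node ids let every
  ## embedding of a fragment across the whole collection live in ONE
  ## matrix (rows = embeddings, columns = fragment nodes), so candidate
  ## extensions are generated with vectorised operations and no per-graph
  ## loop. gOfNode maps a global node back to its graph.
  sizes <- vapply(plain, function(p) length(p$labels), integer(1))
  off <- c(0L, cumsum(sizes))
  labAll <- unlist(lapply(plain, `[[`, "labels"), use.names = FALSE)
  gOfNode <- rep.int(seq_len(nG), sizes)
  nbAll <- vector("list", length(labAll))
  bdAll <- vector("list", length(labAll))
  for (g in seq_len(nG)) {
    adj <- .adjacency(plain[[g]]$labels, plain[[g]]$edges)
    for (v in seq_along(adj$nb)) {
      nbAll[[off[g] + v]] <- adj$nb[[v]] + off[g]
      bdAll[[off[g] + v]] <- adj$bond[[v]]
    }
  }

  seen <- new.env(parent = emptyenv())
  results <- list()

  supportOf <- function(gvec) length(unique(gvec))

  ## All one-edge extensions of a fragment, with their embedding lists.
  ## All one-edge extensions of a fragment, with their embedding matrices.
  ## M holds one embedding per row over global node ids.
  collectCandidates <- function(frag, M) {
    s <- length(frag$labels)
    hasEdge <- matrix(FALSE, s, s)
    if (nrow(frag$edges))
      for (r in seq_len(nrow(frag$edges))) {
        hasEdge[frag$edges$i[r], frag$edges$j[r]] <- TRUE
        hasEdge[frag$edges$j[r], frag$edges$i[r]] <- TRUE
      }
    fK <- list(); fR <- list()
    bK <- list(); bR <- list()
    cols <- seq_len(s)
    for (u in seq_len(s)) {
      hosts <- M[, u]
      cnt <- lengths(nbAll[hosts])
      if (sum(cnt) == 0L) next
      rowidx <- rep.int(seq_len(nrow(M)), cnt)
      nbf <- unlist(nbAll[hosts], use.names = FALSE)
      bdf <- unlist(bdAll[hosts], use.names = FALSE)
      Msub <- M[rowidx, , drop = FALSE]
      ## an embedding uses distinct host nodes, so each neighbour matches
      ## at most one fragment column: ucol is 0 (new node) or the column
      ucol <- as.integer((Msub == nbf) %*% cols)
      fsel <- which(ucol == 0L)
      if (length(fsel)) {
        fK[[length(fK) + 1L]] <-
          paste0("F|", u, "|", bdf[fsel], "|", labAll[nbf[fsel]])
        fR[[length(fR) + 1L]] <-
          cbind(Msub[fsel, , drop = FALSE], nbf[fsel])
      }
      bsel <- which(ucol > u)
      if (length(bsel)) {
        bsel <- bsel[!hasEdge[cbind(u, ucol[bsel])]]
        if (length(bsel)) {
          bK[[length(bK) + 1L]] <-
            paste0("B|", u, "|", ucol[bsel], "|", bdf[bsel])
          bR[[length(bR) + 1L]] <- Msub[bsel, , drop = FALSE]
        }
      }
    }
    finalize <- function(kChunks, rChunks) {
      if (!length(kChunks)) return(list())
      keys <- unlist(kChunks, use.names = FALSE)
      rows <- do.call(rbind, rChunks)
      lapply(split(seq_along(keys), keys), function(ix)
        rows[ix, , drop = FALSE])
    }
    c(finalize(fK, fR), finalize(bK, bR))
  }

  explore <- function(frag, M, code) {
    s <- length(frag$labels)
    gvec <- gOfNode[M[, 1L]]
    supp <- supportOf(gvec)
    cands <- collectCandidates(frag, M)
    keys <- sort(as.character(names(cands)))
    parsed <- strsplit(keys, "|", fixed = TRUE)
    cSupps <- vapply(keys, function(kk)
      supportOf(gOfNode[cands[[kk]][, 1L]]), integer(1))
    inWindow <- vapply(parsed, function(p) p[1L] == "B" || s < maxSize,
                       logical(1))
    closed <- !any(cSupps[inWindow] == supp)
    if (closed && s >= minSize && s <= maxSize && supp >= thr) {
      results[[length(results) + 1L]] <<-
        list(code = code, labels = frag$labels, edges = frag$edges,
             support = supp, ids = ids[sort(unique(gvec))])
    }
    for (ki in seq_along(keys)) {
      parts <- parsed[[ki]]
      forward <- parts[1L] == "F"
      if (forward && s >= maxSize) next
      if (cSupps[ki] < thr) next
      u <- as.integer(parts[2L])
      if (forward) {
        frag2 <- list(labels = c(frag$labels, parts[4L]),
                      edges = rbind(frag$edges,
                                    .makeEdges(u, s + 1L, parts[3L])))
      } else {
        u2 <- as.integer(parts[3L])
        frag2 <- list(labels = frag$labels,
                      edges = rbind(frag$edges,
                                    .makeEdges(u, u2, parts[4L])))
      }
      code2 <- canonicalCode(frag2$labels, frag2$edges)
      if (!is.null(seen[[code2]])) next
      seen[[code2]] <- TRUE
      explore(frag2, cands[[keys[ki]]], code2)
    }
  }

  allLabels <- sort(unique(labAll))
  for (lab in allLabels) {
    w <- which(labAll == lab)
    if (length(w) == 0L || supportOf(gOfNode[w]) < thr) next
    frag <- list(labels = lab, edges = .emptyEdges())
    code <- canonicalCode(frag$labels, frag$edges)
    if (!is.null(seen[[code]])) next
    seen[[code]] <- TRUE
    explore(frag, matrix(w, ncol = 1L), code)
  }

  .fragmentSetFrom(results,
                   list(supportPct = supportPct, minSize = minSize,
                        maxSize = maxSize, nGraphs = nG, threshold = thr))
}

#' Support of fragments over a graph collection
#'
#' Counts, for each fragment, the number of graphs containing at least one
#' label- and bond-preserving sub-graph isomorphic embedding of it.
#' Embedding multiplicity within one graph does not matter.
#'
#' @param fragments a [FragmentSet-class].
#' @param graphs list of [StructureGraph-class] objects.
#' @return named integer vector of per-fragment support counts.
#' @export
fragmentSupport <- function(fragments, graphs) {
  .graphIdsOf(graphs)
  hits <- vapply(graphs, containsFragment,
                 logical(length(fragments)), fragments = fragments)
  hits <- matrix(hits, nrow = length(fragments))  # fragments x graphs
  structure(as.integer(rowSums(hits)), names = fragments@canonicalCode)
}

## Brute-force sub-graph isomorphism for tiny graphs (oracle only):
## tries every injective assignment of fragment nodes to host nodes.
.bruteSubIso <- function(fl, fe, gl, ge) {
  nf <- length(fl); ng <- length(gl)
  if (nf > ng) return(FALSE)
  adjBond <- matrix(NA_character_, ng, ng)
  if (nrow(ge))
    for (r in seq_len(nrow(ge))) {
      adjBond[ge$i[r], ge$j[r]] <- ge$bond[r]
      adjBond[ge$j[r], ge$i[r]] <- ge$bond[r]
    }
  assign <- integer(nf)
  ok <- FALSE
  recurse <- function(k) {
    if (ok) return()
    if (k > nf) { ok <<- TRUE; return() }
    for (v in seq_len(ng)) {
      if (gl[v] != fl[k] || v %in% assign[seq_len(k - 1L)]) next
      good <- TRUE
      if (nrow(fe)) {
        rel <- fe[(fe$i == k & fe$j < k) | (fe$j == k & fe$i < k), ,
                  drop = FALSE]
        if (nrow(rel))
          for (r in seq_len(nrow(rel))) {
            other <- if (rel$i[r] == k) rel$j[r] else rel$i[r]
            b <- adjBond[v, assign[other]]
            if (is.na(b) || b != rel$bond[r]) { good <- FALSE; break }
          }
      }
      if (good) {
        assign[k] <<- v
        recurse(k + 1L)
        assign[k] <<- 0L
        if (ok) return()
      }
    }
  }
  recurse(1L)
  ok
}

#' Brute-force reference miner for tiny graphs
#'
#' Enumerates every connected fragment of every graph explicitly (all edge
#' subsets plus single nodes), counts supports, and keeps the closed
#' frequent ones under the same contract as [mineClosedFragments()]. Meant
#' as an independent test oracle; refuses graphs above 10 nodes.
#'
#' @inheritParams mineClosedFragments
#' @return A [FragmentSet-class].
#' @export
oracleMineFragments <- function(graphs, supportPct, minSize, maxSize) {
  thr <- .checkMiningParams(graphs, supportPct, minSize, maxSize)
  ids <- .graphIdsOf(graphs)
  plain <- lapply(graphs, .asPlain)
  tooBig <- vapply(plain, function(p) length(p$labels) > 10L, logical(1))
  if (any(tooBig))
    stop("graph too large for exhaustive enumeration (> 10 nodes)",
         call. = FALSE)
  reps <- new.env(parent = emptyenv())    # code -> fragment
  supp <- new.env(parent = emptyenv())    # code -> graph index set
  note <- function(code, frag, g) {
    if (is.null(reps[[code]])) reps[[code]] <- frag
    supp[[code]] <- union(supp[[code]], g)
  }
  for (g in seq_along(plain)) {
    p <- plain[[g]]
    for (lab in unique(p$labels))
      note(paste0(lab, "||"),
           list(labels = lab, edges = .emptyEdges()), g)
    E <- nrow(p$edges)
    if (E == 0L) next
    bits <- 2^(seq_len(E) - 1L)
    for (mask in seq_len(2^E - 1L)) {
      sel <- bitwAnd(mask, bits) > 0
      sub <- p$edges[sel, , drop = FALSE]
      nodes <- sort(unique(c(sub$i, sub$j)))
      if (length(nodes) > maxSize) next
      local <- .makeEdges(match(sub$i, nodes), match(sub$j, nodes),
                          sub$bond)
      if (!.isConnected(length(nodes), local)) next
      frag <- list(labels = p$labels[nodes], edges = local)
      note(canonicalCode(frag$labels, frag$edges), frag, g)
    }
  }
  codes <- ls(supp)
  nEdges <- vapply(codes, function(cd) nrow(reps[[cd]]$edges), integer(1))
  nNodes <- vapply(codes, function(cd) length(reps[[cd]]$labels), integer(1))
  suppN <- vapply(codes, function(cd) length(supp[[cd]]), integer(1))
  keep <- which(suppN >= thr & nNodes >= minSize & nNodes <= maxSize)
  results <- list()
  for (kf in keep) {
    f <- reps[[codes[kf]]]
    exts <- which(nEdges == nEdges[kf] + 1L & nNodes <= maxSize &
                    suppN == suppN[kf])
    isClosed <- TRUE
    for (ke in exts) {
      gfrag <- reps[[codes[ke]]]
      if (.bruteSubIso(f$labels, f$edges, gfrag$labels, gfrag$edges)) {
        isClosed <- FALSE
        break
      }
    }
    if (isClosed)
      results[[length(results) + 1L]] <-
        list(code = codes[kf], labels = f$labels, edges = f$edges,
             support = suppN[kf], ids = ids[supp[[codes[kf]]]])
  }
  .fragmentSetFrom(results,
                   list(supportPct = supportPct, minSize = minSize,
                        maxSize = maxSize, nGraphs = length(plain),
                        threshold = thr))
}
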