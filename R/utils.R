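# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertScalarString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x))
    stop(what, " must be a non-empty string", call. = FALSE)
  invisible(x)
}

## Plain-graph representation used internally by the miner and matcher:
## list(labels = character vector, edges = data.frame(i, j, bond)) with
## 1-based node positions and i < j.
.emptyEdges <- function() {
  data.frame(i = integer(0), j = integer(0), bond = character(0),
             stringsAsFactors = FALSE)
}

.makeEdges <- function(i, j, bond) {
  if (length(i) == 0L) return(.emptyEdges())
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  data.frame(i = as.integer(i), j = as.integer(j),
             bond = as.character(bond), stringsAsFactors = FALSE)
}

.plainGraph <- function(labels, edges) {
  list(labels = as.character(labels), edges = edges)
}

.asPlain <- function(g) {
  if (is(g, "StructureGraph"))
    .plainGraph(g@nodeLabels, g@edges)
  else
    g
}

## Adjacency list: for each node, integer neighbours and their bond labels.
.adjacency <- function(labels, edges) {
  n <- length(labels)
  nb <- vector("list", n)
  bd <- vector("list", n)
  for (v in seq_len(n)) {
    nb[[v]] <- integer(0)
    bd[[v]] <- character(0)
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      i <- edges$i[r]; j <- edges$j[r]; b <- edges$bond[r]
      nb[[i]] <- c(nb[[i]], j); bd[[i]] <- c(bd[[i]], b)
      nb[[j]] <- c(nb[[j]], i); bd[[j]] <- c(bd[[j]], b)
    }
  }
  list(nb = nb, bond = bd)
}

## Connectivity of (labels, edges) over all nodes.
.isConnected <- function(nNodes, edges) {
  if (nNodes <= 1L) return(TRUE)
  seen <- logical(nNodes)
  adj <- .adjacency(character(nNodes), edges)$nb
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  all(seen)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))
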