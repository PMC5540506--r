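# Shared fixtures: all test graphs are built in code.

# Backbone-only path graph from a sequence string.
pathGraph <- function(seqStr, id = seqStr) {
  buildStructureGraph(seqStr, strrep(".", nchar(seqStr)), id)
}

# Random RNA-like structure graph: random sequence with up to two
# non-adjacent base pairs encoded in separate bracket families (so pair
# sets may cross), giving mixed backbone/pair bond labels.
randomRnaGraph <- function(id, lenRange = 4:8, maxPairs = 2L) {
  L <- sample(lenRange, 1L)
  seqStr <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                  collapse = "")
  st <- rep(".", L)
  families <- list(c("(", ")"), c("[", "]"))
  free <- seq_len(L)
  nPairs <- sample(0:maxPairs, 1L)
  made <- 0L
  while (made < nPairs && length(free) >= 2L) {
    cand <- free[free <= L - 2L]
    if (!length(cand)) break
    i <- sample(rep(cand, 2L), 1L)   # rep() guards length-1 sample()
    partners <- free[free >= i + 2L]
    if (!length(partners)) { free <- setdiff(free, i); next }
    j <- sample(rep(partners, 2L), 1L)
    made <- made + 1L
    fam <- families[[(made - 1L) %% 2L + 1L]]
    st[i] <- fam[1L]; st[j] <- fam[2L]
    free <- setdiff(free, c(i, j))
  }
  buildStructureGraph(seqStr, paste(st, collapse = ""), id)
}

randomGraphSet <- function(n = NULL, lenRange = 4:8) {
  if (is.null(n)) n <- sample(2:6, 1L)
  lapply(seq_len(n), function(i)
    randomRnaGraph(paste0("g", i), lenRange = lenRange))
}

# FragmentSet with a single hand-built fragment.
singleFragment <- function(labels, edges = NULL) {
  if (is.null(edges))
    edges <- data.frame(i = integer(0), j = integer(0),
                        bond = character(0))
  new("FragmentSet",
      canonicalCode = canonicalCode(labels, edges),
      nodeLabels = list(labels), edges = list(edges),
      supportCount = NA_integer_, supportingIds = list(character(0)),
      params = list())
}

edgesDf <- function(i, j, bond) data.frame(i = i, j = j, bond = bond,
                                           stringsAsFactors = FALSE)

# Small labelled synthetic dataset for pipeline smoke tests.
tinyDataset <- function(nClasses = 2L, perClass = 6L, seed = 11L) {
  generateDataset(syntheticSpec(nClasses = nClasses, perClass = perClass,
                                lengthRange = c(25L, 30L),
                                mutationRate = 0, seed = seed))
}
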