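# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Full-matrix affine-gap Smith-Waterman score (Gotoh, dense, loop-based).
swScoreOracle <- function(a, b, go = 11, ge = 1) {
  S <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)
  Iy <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      Ix[i, j] <- max(M[i - 1, j] - go - ge, Ix[i - 1, j] - ge)
      Iy[i, j] <- max(M[i, j - 1] - go - ge, Iy[i, j - 1] - ge)
      M[i, j] <- max(0,
                     max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                         Iy[i - 1, j - 1]) + S[A[i - 1], B[j - 1]])
      best <- max(best, M[i, j], Ix[i, j], Iy[i, j])
    }
  }
  best
}

# Global affine-gap alignment score of an already-aligned pair of rows,
# scored from the alignment itself (terminal gaps penalized).
alignedPairScore <- function(rowA, rowB, go = 11, ge = 1) {
  S <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    get("BLOSUM62", envir = e)
  })
  A <- strsplit(rowA, "")[[1]]
  B <- strsplit(rowB, "")[[1]]
  sub <- sum(ifelse(A != "-" & B != "-",
                    S[cbind(match(A, rownames(S)), match(B, rownames(S)))],
                    0))
  gapcost <- function(x) {
    r <- rle(x == "-")
    sum((go + ge * r$lengths)[r$values])
  }
  sub - gapcost(A) - gapcost(B)
}

# Dense, loop-based Markov clustering on a weighted adjacency matrix,
# returning the partition as a list of index vectors. Follows the stated
# algorithm directly: unit self-loops, column normalization, expansion,
# entrywise inflation, pruning, components of the limit.
mclOracle <- function(A, inflation = 1.5, maxIter = 100, tol = 1e-6,
                      prune = 1e-12) {
  n <- nrow(A)
  for (i in seq_len(n)) A[i, i] <- max(A[i, i], 1)
  for (j in seq_len(n)) A[, j] <- A[, j] / sum(A[, j])
  for (it in seq_len(maxIter)) {
    old <- A
    A <- A %*% A
    A <- A^inflation
    A[A < prune] <- 0
    for (j in seq_len(n)) A[, j] <- A[, j] / sum(A[, j])
    if (max(abs(A - old)) < tol) break
  }
  # connected components of the nonzero pattern, by BFS
  adj <- (A + t(A)) > 0
  diag(adj) <- TRUE
  comp <- rep(NA_integer_, n)
  cc <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cc <- cc + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cc
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  unname(split(seq_len(n), comp))
}

# Canonical representation of a partition for comparison.
partitionKey <- function(sets) {
  sets <- lapply(sets, sort)
  paste(sort(vapply(sets, paste, character(1), collapse = ",")),
        collapse = "|")
}

# Evolve protein sequences down a given tree: each edge applies a fixed
# number of substitutions at uniformly chosen positions.
simulateAlongTree <- function(tree, seqLen = 2000, mutPerEdge = 60) {
  aa <- arsenome:::AA_ALPHABET20
  root <- sample(aa, seqLen, replace = TRUE)
  nTip <- length(tree$tip.label)
  seqs <- vector("list", nTip + tree$Nnode)
  rootNode <- nTip + 1L
  seqs[[rootNode]] <- root
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]
    child <- ord$edge[k, 2]
    s <- seqs[[par]]
    pos <- sample(seqLen, mutPerEdge)
    for (p in pos) s[p] <- sample(setdiff(aa, s[p]), 1)
    seqs[[child]] <- s
  }
  rows <- vapply(seq_len(nTip), function(i) paste(seqs[[i]], collapse = ""),
                 character(1))
  names(rows) <- tree$tip.label
  rows
}
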