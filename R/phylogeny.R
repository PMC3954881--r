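#' @importFrom ape nj ladderize Ntip prop.clades
#' @importFrom stats hclust as.dist
NULL

#' Single-copy core gene detection
#'
#' Keeps ortholog groups that have exactly one member in every genome of
#' the cohort and whose member lengths are all within \code{lengthTol} of
#' the group median length ("nearly identical" lengths).
#'
#' @param groups Ortholog groups from \code{\link{clusterOrthologs}} run on
#'   the high-stringency (identity >= 50\%) all-vs-all graph.
#' @param cohort The \code{\link{GenomeCohort}} (>= 2 genomes).
#' @param lengthTol Allowed fractional deviation from the group median
#'   length (default 0.1).
#' @return A \code{CoreGeneSet}: list with \code{groups} (each carrying a
#'   members data frame and length stats) and \code{n_genomes}.
#' @export
findSingleCopyCore <- function(groups, cohort, lengthTol = 0.1) {
  n <- length(genomes(cohort))
  if (n < 2L) stop("core-gene detection needs >= 2 genomes")
  lens <- unlist(lapply(genomes(cohort),
                        function(g) setNames(width(proteins(g)),
                                             names(proteins(g)))))
  names(lens) <- sub("^[^.]*\\.", "", names(lens))  # strip list-name prefix
  keep <- list()
  for (gr in groups) {
    m <- gr$members
    if (nrow(m) != n) next
    if (length(unique(m$genome)) != n) next
    L <- unname(lens[m$protein_id])
    med <- median(L)
    if (any(abs(L - med) > lengthTol * med)) next
    gr$median_length <- med
    gr$lengths <- L
    keep[[length(keep) + 1L]] <- gr
  }
  structure(list(groups = keep, n_genomes = n), class = "CoreGeneSet")
}

#' @export
print.CoreGeneSet <- function(x, ...) {
  cat("CoreGeneSet:", length(x$groups), "single-copy core gene group(s) in",
      x$n_genomes, "genomes\n")
  invisible(x)
}

# Extended substitution matrix with a zero-scoring gap symbol appended.
.profileScoreMatrix <- function(scheme) {
  S <- .substitutionMatrix(scheme$matrix)
  S <- rbind(cbind(S, `-` = 0), `-` = 0)
  S
}

# Column frequency matrix (symbols x columns) of an alignment block.
.profileFreqs <- function(block, symbols) {
  apply(block, 2L, function(col) {
    tabulate(factor(col, levels = symbols), nbins = length(symbols))
  }) / nrow(block)
}

# Global (Needleman-Wunsch/Gotoh) affine-gap alignment of two profiles.
# Three-state DP, row-vectorized: the match and vertical-gap states depend
# only on the previous row; the horizontal-gap state within a row is a
# running maximum over the current row's match state (cummax trick), which
# is exactly the standard open-from-match Gotoh recurrence. A gap of
# length L costs gapOpen + L * gapExtend, matching the local aligner.
.alignProfiles <- function(A, B, scheme) {
  S <- .profileScoreMatrix(scheme)
  syms <- rownames(S)
  go <- scheme$gapOpen
  ge <- scheme$gapExtend
  fa <- .profileFreqs(A, syms)
  fb <- .profileFreqs(B, syms)
  sub <- t(fa) %*% S %*% fb          # la x lb column-pair scores
  la <- ncol(A)
  lb <- ncol(B)
  NEG <- -1e18
  M <- matrix(NEG, la + 1L, lb + 1L)   # this column pair aligned
  Ix <- matrix(NEG, la + 1L, lb + 1L)  # gap in B (consumes A columns)
  Iy <- matrix(NEG, la + 1L, lb + 1L)  # gap in A (consumes B columns)
  M[1L, 1L] <- 0
  Iy[1L, -1L] <- -go - ge * seq_len(lb)
  for (i in seq_len(la) + 1L) {
    prevH <- pmax(M[i - 1L, ], Ix[i - 1L, ], Iy[i - 1L, ])
    M[i, -1L] <- prevH[-(lb + 1L)] + sub[i - 1L, ]
    Ix[i, ] <- pmax(M[i - 1L, ] - go - ge, Ix[i - 1L, ] - ge)
    a <- M[i, seq_len(lb)] + ge * (0:(lb - 1L))
    Iy[i, -1L] <- cummax(a) - go - ge * seq_len(lb)
  }
  scoreEnd <- max(M[la + 1L, lb + 1L], Ix[la + 1L, lb + 1L],
                  Iy[la + 1L, lb + 1L])
  # traceback mirrors the forward recurrences exactly
  eq <- function(x, y) abs(x - y) < 1e-6
  path <- character(la + lb)
  np <- 0L
  i <- la + 1L
  j <- lb + 1L
  state <- c("M", "Ix", "Iy")[which.max(c(M[i, j], Ix[i, j], Iy[i, j]))]
  while (i > 1L || j > 1L) {
    np <- np + 1L
    if (state == "M") {
      path[np] <- "D"
      prev <- c(M[i - 1L, j - 1L], Ix[i - 1L, j - 1L], Iy[i - 1L, j - 1L])
      state <- c("M", "Ix", "Iy")[which(eq(prev,
                                           M[i, j] - sub[i - 1L, j - 1L]))[1L]]
      i <- i - 1L
      j <- j - 1L
    } else if (state == "Ix") {
      path[np] <- "A"
      state <- if (eq(Ix[i, j], M[i - 1L, j] - go - ge)) "M" else "Ix"
      i <- i - 1L
    } else {
      path[np] <- "B"
      state <- if (eq(Iy[i, j], M[i, j - 1L] - go - ge)) "M" else "Iy"
      j <- j - 1L
    }
  }
  path <- rev(path[seq_len(np)])
  # build merged block
  na <- nrow(A)
  nb <- nrow(B)
  out <- matrix("-", na + nb, length(path))
  ai <- 0L
  bi <- 0L
  for (k in seq_along(path)) {
    p <- path[k]
    if (p == "D") {
      ai <- ai + 1L
      bi <- bi + 1L
      out[seq_len(na), k] <- A[, ai]
      out[na + seq_len(nb), k] <- B[, bi]
    } else if (p == "A") {
      ai <- ai + 1L
      out[seq_len(na), k] <- A[, ai]
    } else {
      bi <- bi + 1L
      out[na + seq_len(nb), k] <- B[, bi]
    }
  }
  rownames(out) <- c(rownames(A), rownames(B))
  list(block = out, score = scoreEnd)
}

# Fractional shared k-mer distance used for the guide tree.
.kmerDistance <- function(seqs, k = 3L) {
  km <- lapply(seqs, proteinKmers, k = k)
  n <- length(seqs)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- length(intersect(km[[i]], km[[j]]))
      D[i, j] <- D[j, i] <-
        1 - shared / max(1L, min(length(km[[i]]), length(km[[j]])))
    }
  }
  D
}

#' Progressive multiple alignment of one protein per genome
#'
#' Guide-tree progressive profile alignment: a shared 3-mer distance matrix
#' and average-linkage clustering fix the merge order; profiles are merged
#' by global affine-gap profile-profile alignment under the scoring scheme
#' (sum-of-pairs column scores, existing gaps scoring zero). For two
#' sequences this reduces to an optimal global pairwise alignment.
#'
#' @param seqs Named character vector (or \code{AAStringSet}), one protein
#'   per genome; >= 2 sequences (a single sequence is returned unchanged
#'   with a warning).
#' @param scheme \code{\link{scoringScheme}}.
#' @return Named character vector of aligned rows (equal lengths, gaps as
#'   \code{"-"}), in the input order.
#' @export
progressiveAlign <- function(seqs, scheme = scoringScheme()) {
  if (is(seqs, "AAStringSet")) seqs <- setNames(as.character(seqs),
                                                names(seqs))
  if (length(seqs) == 1L) {
    warning("single sequence; returned unaligned")
    return(seqs)
  }
  toBlock <- function(s, nm) {
    m <- matrix(strsplit(s, "", fixed = TRUE)[[1L]], nrow = 1L)
    rownames(m) <- nm
    m
  }
  if (length(seqs) == 2L) {
    merged <- .alignProfiles(toBlock(seqs[1L], names(seqs)[1L]),
                             toBlock(seqs[2L], names(seqs)[2L]), scheme)
    block <- merged$block
  } else {
    D <- .kmerDistance(seqs)
    hc <- hclust(as.dist(D), method = "average")
    nodes <- vector("list", nrow(hc$merge))
    getBlock <- function(id) {
      if (id < 0L) toBlock(seqs[-id], names(seqs)[-id]) else nodes[[id]]
    }
    for (m in seq_len(nrow(hc$merge))) {
      nodes[[m]] <- .alignProfiles(getBlock(hc$merge[m, 1L]),
                                   getBlock(hc$merge[m, 2L]),
                                   scheme)$block
    }
    block <- nodes[[length(nodes)]]
  }
  rows <- apply(block, 1L, paste, collapse = "")
  rows[names(seqs)]
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param alignments List of alignments (named character vectors from
#'   \code{\link{progressiveAlign}}), all over the identical genome set.
#' @return A \code{SuperMatrix}: list with \code{rows} (per-genome
#'   concatenated aligned sequence) and \code{partitions} (data frame:
#'   partition, start, end; boundaries tile each row exactly).
#' @export
concatenateAlignments <- function(alignments) {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  genomesSet <- names(alignments[[1L]])
  for (k in seq_along(alignments)) {
    missing <- setdiff(genomesSet, names(alignments[[k]]))
    extra <- setdiff(names(alignments[[k]]), genomesSet)
    if (length(missing) || length(extra)) {
      stop("genome set mismatch in partition ", k, ": missing ",
           paste(missing, collapse = ","), " extra ",
           paste(extra, collapse = ","))
    }
  }
  widths <- vapply(alignments, function(a) nchar(a[[1L]]), numeric(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  rows <- vapply(genomesSet, function(g) {
    paste(vapply(alignments, `[[`, character(1), g), collapse = "")
  }, character(1))
  nm <- names(alignments)
  if (is.null(nm)) nm <- paste0("partition", seq_along(alignments))
  structure(list(rows = rows,
                 partitions = data.frame(partition = nm,
                                         start = as.integer(starts),
                                         end = as.integer(ends))),
            class = "SuperMatrix")
}

#' @export
print.SuperMatrix <- function(x, ...) {
  cat("SuperMatrix:", length(x$rows), "genomes x", nchar(x$rows[[1L]]),
      "aligned columns in", nrow(x$partitions), "partition(s)\n")
  invisible(x)
}

# Poisson-corrected distance matrix from aligned rows; columns with a gap
# in either member of a pair are excluded pairwise.
.poissonDist <- function(chmat, cap = NULL) {
  n <- nrow(chmat)
  D <- matrix(0, n, n, dimnames = list(rownames(chmat), rownames(chmat)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- chmat[i, ] != "-" & chmat[j, ] != "-"
      p <- if (any(ok)) mean(chmat[i, ok] != chmat[j, ok]) else 1
      if (p >= 1) {
        if (is.null(cap)) {
          stop("saturated pair (p >= 1) between ", rownames(chmat)[i],
               " and ", rownames(chmat)[j],
               "; use more conservative input sequences")
        }
        p <- cap
      }
      D[i, j] <- D[j, i] <- -log(1 - p)
    }
  }
  D
}

.superMatrixChars <- function(sm) {
  t(vapply(sm$rows, function(r) strsplit(r, "", fixed = TRUE)[[1L]],
           character(nchar(sm$rows[[1L]]))))
}

#' Neighbor-joining tree with partition-aware bootstrap
#'
#' Pairwise distances are Poisson-corrected p-distances
#' (\eqn{d = -\ln(1-p)}, gapped columns excluded pairwise); the topology is
#' estimated by neighbor joining (negative branch lengths clamped to zero).
#' Bootstrap replicates resample alignment columns with replacement within
#' each partition; support values (percent of replicates containing each
#' bipartition) are stored as internal node labels.
#'
#' @param sm A \code{\link{concatenateAlignments}} supermatrix (>= 3
#'   genomes).
#' @param nBootstrap Number of bootstrap replicates (default 100; 1000 for
#'   publication-grade support values).
#' @param seed Integer seed; supports are exactly reproducible.
#' @return An \code{ape} \code{phylo} tree with bootstrap percentages in
#'   \code{node.label}.
#' @export
buildTree <- function(sm, nBootstrap = 100L, seed = 1L) {
  chmat <- .superMatrixChars(sm)
  if (nrow(chmat) < 3L) stop("tree building needs >= 3 genomes")
  D <- .poissonDist(chmat)
  tree <- ape::nj(as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  if (nBootstrap > 0L) {
    parts <- sm$partitions
    boots <- withSeed(deriveSeed(seed, 401L), {
      lapply(seq_len(nBootstrap), function(b) {
        cols <- unlist(lapply(seq_len(nrow(parts)), function(pi) {
          rng <- parts$start[pi]:parts$end[pi]
          sample(rng, length(rng), replace = TRUE)
        }))
        Db <- .poissonDist(chmat[, cols, drop = FALSE], cap = 0.95)
        ape::nj(as.dist(Db))
      })
    })
    supp <- ape::prop.clades(tree, boots, rooted = FALSE)
    supp[is.na(supp)] <- 0
    tree$node.label <- round(100 * supp / nBootstrap)
  }
  tree
}
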