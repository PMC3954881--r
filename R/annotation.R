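#' Screen one genome's proteome against the curated reference database
#'
#' Every protein is aligned (Smith-Waterman, after a shared k-mer
#' prefilter) against the reference exemplars; proteins with at least one
#' hit passing the thresholds become candidates, labelled with the family
#' of their best passing hit (highest raw score; ties broken by subject id).
#' Mirroring a functional-classification filter, a candidate whose best
#' family score is not at least \code{ambiguityMargin} times the best score
#' of any other family is marked \code{rejected} as cross-family noise.
#'
#' @param genome An \code{\link{AnnotatedGenome}}.
#' @param db A \code{\link{ReferenceDB}}.
#' @param t \code{\link{similarityThresholds}} (default: E <= 1e-10,
#'   coverage >= 70, identity >= 35).
#' @param scheme \code{\link{scoringScheme}}.
#' @param ambiguityMargin Required best-family score advantage (default
#'   1.1).
#' @return Data frame with one row per protein with a passing hit:
#'   genome_id, protein_id, contig, start, end, strand, family, pathway,
#'   status (\code{candidate} or \code{rejected}), best_hit_subject,
#'   identity_pct, coverage_pct, evalue, raw_score, ambiguous.
#' @export
screenCandidates <- function(genome, db, t = similarityThresholds(),
                             scheme = scoringScheme(),
                             ambiguityMargin = 1.1) {
  if (length(db) == 0L) stop("reference database is empty")
  qs <- proteins(genome)
  ss <- proteins(db)
  dbLen <- sum(width(ss))
  # prefilter: query-subject pairs sharing a 4-mer
  skm <- lapply(as.character(ss), proteinKmers, k = 4L)
  sidx <- split(rep.int(seq_along(ss), lengths(skm)),
                unlist(skm, use.names = FALSE))
  qi <- integer(0); si <- integer(0)
  qchars <- as.character(qs)
  for (i in seq_along(qs)) {
    kk <- proteinKmers(qchars[i], 4L)
    subj <- unique(unlist(sidx[kk], use.names = FALSE))
    if (length(subj) > 0L) {
      qi <- c(qi, rep.int(i, length(subj)))
      si <- c(si, subj)
    }
  }
  hits <- .alignPairs(qs, ss, qi, si, scheme)
  empty <- data.frame(
    genome_id = character(0), protein_id = character(0),
    contig = character(0), start = integer(0), end = integer(0),
    strand = character(0), family = character(0), pathway = character(0),
    status = character(0), best_hit_subject = character(0),
    identity_pct = numeric(0), coverage_pct = numeric(0),
    evalue = numeric(0), raw_score = numeric(0), ambiguous = logical(0))
  if (nrow(hits) == 0L) return(empty)
  hits$evalue <- karlinEvalue(hits$raw_score, width(qs)[hits$q], dbLen,
                              scheme)
  hits$coverage_pct <- hits$qcov_pct
  hits <- hits[passesThresholds(hits, t), , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  hits$family <- refFamily(db)[hits$s]
  hits$subject_id <- names(ss)[hits$s]
  feats <- genomeFeatures(genome)
  fmeta <- data.frame(protein_id = mcols(feats)$protein_id,
                      contig = as.character(seqnames(feats)),
                      start = start(feats), end = end(feats),
                      strand = as.character(strand(feats)))
  rows <- lapply(split(hits, hits$q), function(h) {
    # best hit: highest raw score, ties by lexicographic subject id
    h <- h[order(-h$raw_score, h$subject_id), , drop = FALSE]
    best <- h[1L, ]
    famBest <- vapply(split(h$raw_score, h$family), max, numeric(1))
    famBest <- sort(famBest, decreasing = TRUE)
    ambiguous <- length(famBest) > 1L &&
      famBest[1L] < ambiguityMargin * famBest[2L]
    pid <- names(qs)[best$q]
    fm <- fmeta[match(pid, fmeta$protein_id), ]
    data.frame(genome_id = strainId(genome), protein_id = pid,
               contig = fm$contig, start = fm$start, end = fm$end,
               strand = fm$strand, family = best$family,
               pathway = familyPathway(best$family),
               status = if (ambiguous) "rejected" else "candidate",
               best_hit_subject = best$subject_id,
               identity_pct = best$identity_pct,
               coverage_pct = best$coverage_pct,
               evalue = best$evalue, raw_score = best$raw_score,
               ambiguous = ambiguous)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Markov clustering of one dense stochastic matrix. Self-loops (weight 1)
# are added before column normalization, the standard regularization that
# prevents period-2 oscillation on bipartite-like graphs.
.mclIterate <- function(M, inflation, maxIter, tol, prune) {
  diag(M) <- pmax(diag(M), 1)
  normalize <- function(X) sweep(X, 2L, pmax(colSums(X), .Machine$double.xmin),
                                 "/")
  M <- normalize(M)
  for (it in seq_len(maxIter)) {
    prev <- M
    M <- M %*% M              # expansion
    M <- M^inflation          # inflation
    M[M < prune] <- 0
    M <- normalize(M)
    if (max(abs(M - prev)) < tol) return(M)
  }
  stop("MCL did not converge after ", maxIter, " iterations")
}

#' Markov (MCL) ortholog clustering of a similarity graph
#'
#' Runs Markov clustering on the weighted homology graph: the column-
#' normalized transition matrix is alternately expanded (matrix square) and
#' inflated (entrywise power \code{inflation}, then renormalized) until the
#' matrix is stable; connected components of the limit matrix are the
#' ortholog groups. Clustering is performed per connected component of the
#' input graph, which leaves the result unchanged but bounds the matrix
#' sizes. Singleton groups are allowed.
#'
#' @param graph Similarity graph from \code{\link{allVsAll}} (igraph;
#'   vertices need \code{name} and \code{genome} attributes).
#' @param inflation Granularity parameter > 1 (default 1.5).
#' @param maxIter Iteration cap (default 100).
#' @param tol Max-norm convergence tolerance (default 1e-6).
#' @param prune Entries below this are zeroed each iteration (1e-12).
#' @return List of ortholog groups, each a list with \code{group_id} and
#'   \code{members} (data frame: protein_id, genome), ordered by decreasing
#'   size then first member id; the output is invariant to vertex order.
#' @export
clusterOrthologs <- function(graph, inflation = 1.5, maxIter = 100L,
                             tol = 1e-6, prune = 1e-12) {
  if (inflation <= 1) stop("inflation must be > 1")
  comp <- igraph::components(graph)
  memberSets <- list()
  for (ci in seq_len(comp$no)) {
    vids <- which(comp$membership == ci)
    if (length(vids) == 1L) {
      memberSets[[length(memberSets) + 1L]] <-
        igraph::V(graph)$name[vids]
      next
    }
    sub <- igraph::induced_subgraph(graph, vids)
    # deterministic vertex order within the component
    ord <- order(igraph::V(sub)$name)
    sub <- igraph::permute(sub, order(ord))
    A <- igraph::as_adjacency_matrix(sub, attr = "weight", sparse = FALSE)
    M <- .mclIterate(A, inflation, maxIter, tol, prune)
    lim <- igraph::graph_from_adjacency_matrix(
      (M + t(M)) > 0, mode = "undirected", diag = FALSE)
    cl <- igraph::components(lim)$membership
    nms <- igraph::V(sub)$name
    for (g in split(nms, cl)) {
      memberSets[[length(memberSets) + 1L]] <- sort(g)
    }
  }
  genome_of <- setNames(igraph::V(graph)$genome, igraph::V(graph)$name)
  memberSets <- memberSets[order(-lengths(memberSets),
                                 vapply(memberSets, `[`, character(1), 1L))]
  lapply(seq_along(memberSets), function(i) {
    m <- memberSets[[i]]
    list(group_id = sprintf("OG%04d", i),
         members = data.frame(protein_id = m,
                              genome = unname(genome_of[m])))
  })
}

#' Partition candidates into clustered and scattered genes
#'
#' A candidate is clustered iff it is a member of some detected gene
#' cluster; the two sets partition the candidate set.
#'
#' @param candidates Candidate table (rows with status \code{candidate}).
#' @param clusters Cluster list from \code{\link{detectClusters}} over the
#'   same candidates.
#' @return List with character vectors \code{clustered} and
#'   \code{scattered} of protein ids.
#' @export
partitionByPosition <- function(candidates, clusters) {
  inCluster <- unique(unlist(lapply(clusters,
                                    function(cl) cl$members$protein_id)))
  ids <- candidates$protein_id
  list(clustered = ids[ids %in% inCluster],
       scattered = ids[!ids %in% inCluster])
}

#' Confirm scattered genes against the clustered gene set
#'
#' Clustered genes are taken as the trusted arsenic-related genes; each
#' scattered candidate is re-searched against the clustered genes of its
#' own family (cohort-wide) and confirmed iff some hit passes the same
#' thresholds as the screen. Scattered candidates that fail are rejected.
#' If the cohort has no clustered genes at all, a warning is issued and all
#' scattered candidates fall back to their (already passing) reference-
#' database best hit, i.e. are confirmed.
#'
#' @param scattered Candidate rows for scattered genes.
#' @param clustered Candidate rows for clustered genes.
#' @param cohort The \code{\link{GenomeCohort}} (for sequences).
#' @param t \code{\link{similarityThresholds}}.
#' @param scheme \code{\link{scoringScheme}}.
#' @return \code{scattered} with \code{status} set to
#'   \code{scattered_confirmed} or \code{rejected}.
#' @export
confirmScattered <- function(scattered, clustered, cohort,
                             t = similarityThresholds(),
                             scheme = scoringScheme()) {
  if (nrow(scattered) == 0L) {
    scattered$status <- character(0)
    return(scattered)
  }
  if (nrow(clustered) == 0L) {
    warning("no clustered genes in cohort; ",
            "falling back to reference-database confirmation")
    scattered$status <- "scattered_confirmed"
    return(scattered)
  }
  seqs <- do.call(c, unname(lapply(genomes(cohort), proteins)))
  status <- character(nrow(scattered))
  for (i in seq_len(nrow(scattered))) {
    fam <- scattered$family[i]
    targets <- clustered$protein_id[clustered$family == fam]
    if (length(targets) == 0L) {
      status[i] <- "rejected"
      next
    }
    q <- seqs[scattered$protein_id[i]]
    ss <- seqs[targets]
    hits <- .alignPairs(q, ss, rep(1L, length(ss)), seq_along(ss), scheme)
    hits$evalue <- karlinEvalue(hits$raw_score, width(q), sum(width(ss)),
                                scheme)
    hits$coverage_pct <- hits$qcov_pct
    status[i] <- if (any(passesThresholds(hits, t))) "scattered_confirmed"
                 else "rejected"
  }
  scattered$status <- status
  scattered
}

#' Full annotation of a cohort
#'
#' Runs the three-step re-annotation over all genomes: candidate screening
#' against the reference database, genomic-neighborhood cluster detection,
#' clustered/scattered partition, and scattered-gene confirmation.
#'
#' @param cohort A \code{\link{GenomeCohort}}.
#' @param db A \code{\link{ReferenceDB}}.
#' @param t \code{\link{similarityThresholds}} for the screen.
#' @param scheme \code{\link{scoringScheme}}.
#' @param p \code{\link{neighborhoodParams}}.
#' @return List: \code{annotations} (all screened rows with final status
#'   \code{clustered}, \code{scattered_confirmed} or \code{rejected}),
#'   \code{clusters} (cohort-wide cluster list).
#' @export
annotateCohort <- function(cohort, db, t = similarityThresholds(),
                           scheme = scoringScheme(),
                           p = neighborhoodParams()) {
  screened <- lapply(genomes(cohort), screenCandidates, db = db, t = t,
                     scheme = scheme)
  clusters <- list()
  for (g in genomes(cohort)) {
    cand <- screened[[strainId(g)]]
    cand <- cand[cand$status == "candidate", , drop = FALSE]
    clusters <- c(clusters, detectClusters(cand, g))
  }
  ann <- do.call(rbind, screened)
  rownames(ann) <- NULL
  cand <- ann[ann$status == "candidate", , drop = FALSE]
  part <- partitionByPosition(cand, clusters)
  ann$status[ann$protein_id %in% part$clustered] <- "clustered"
  sc <- cand[cand$protein_id %in% part$scattered, , drop = FALSE]
  cl <- cand[cand$protein_id %in% part$clustered, , drop = FALSE]
  scConf <- confirmScattered(sc, cl, cohort, t, scheme)
  ann$status[match(scConf$protein_id, ann$protein_id)] <- scConf$status
  list(annotations = ann, clusters = clusters)
}

#' Pathway tally of confirmed annotations
#'
#' Aggregates confirmed gene calls into the summary the pipeline reports:
#' per-pathway and per-family totals, grand total, per-genome counts, and
#' the clustered-gene fraction. Construct directly from counts via
#' \code{\link{pathwayTally}} for desk arithmetic.
#'
#' @param annotations Annotation table (confirmed rows are those with
#'   status \code{clustered} or \code{scattered_confirmed}).
#' @param cohort The \code{\link{GenomeCohort}} (fixes the genome
#'   denominator, including zero-gene strains).
#' @return A \code{PathwayTally}; see \code{\link{pathwayTally}}.
#' @export
countByPathway <- function(annotations, cohort) {
  conf <- annotations[annotations$status %in%
                        c("clustered", "scattered_confirmed"), ,
                      drop = FALSE]
  bad <- setdiff(conf$family, names(arsenicFamilies()))
  if (length(bad)) stop("unknown family: ", paste(bad, collapse = ", "))
  sids <- vapply(genomes(cohort), strainId, character(1))
  pwCounts <- table(factor(familyPathway(conf$family),
                           levels = c("ars", "aio", "arr", "arsM")))
  famCounts <- table(factor(conf$family, levels = names(arsenicFamilies())))
  perGenome <- table(factor(conf$genome_id, levels = sids))
  pathwayTally(
    pathwayCounts = setNames(as.integer(pwCounts), names(pwCounts)),
    nGenomes = length(sids),
    nClustered = sum(conf$status == "clustered"),
    familyCounts = setNames(as.integer(famCounts), names(famCounts)),
    perGenome = setNames(as.integer(perGenome), names(perGenome)))
}

#' Construct a pathway tally from raw counts
#'
#' @param pathwayCounts Named integer vector over \code{ars}, \code{aio},
#'   \code{arr}, \code{arsM}.
#' @param nGenomes Number of genomes in the cohort.
#' @param nClustered Number of confirmed genes inside clusters.
#' @param familyCounts,perGenome Optional finer-grained counts.
#' @return A \code{PathwayTally} list with fields \code{pathway_counts},
#'   \code{grand_total}, \code{n_genomes}, \code{n_clustered},
#'   \code{family_counts}, \code{per_genome}.
#' @examples
#' # the cohort-scale worked example: 1051 + 60 + 2 + 4 = 1117 genes
#' t <- pathwayTally(c(ars = 1051, aio = 60, arr = 2, arsM = 4),
#'                   nGenomes = 188, nClustered = 795)
#' grandTotal(t)        # 1117
#' clusteredPct(t)      # 71.2
#' perGenomeMean(t, "ars")  # 5.6
#' pathwayPct(t, "ars")     # 94.1
#' @export
pathwayTally <- function(pathwayCounts, nGenomes, nClustered = NA_integer_,
                         familyCounts = NULL, perGenome = NULL) {
  bad <- setdiff(names(pathwayCounts), c("ars", "aio", "arr", "arsM"))
  if (length(bad)) stop("unknown pathway: ", paste(bad, collapse = ", "))
  structure(list(pathway_counts = pathwayCounts,
                 grand_total = sum(pathwayCounts),
                 n_genomes = nGenomes,
                 n_clustered = nClustered,
                 family_counts = familyCounts,
                 per_genome = perGenome),
            class = "PathwayTally")
}

#' @export
print.PathwayTally <- function(x, ...) {
  cat("PathwayTally:", x$grand_total, "genes over", x$n_genomes,
      "genomes (", paste(names(x$pathway_counts), x$pathway_counts,
                         sep = "=", collapse = ", "), ")\n")
  invisible(x)
}

#' @rdname pathwayTally
#' @param t A \code{PathwayTally}.
#' @export
grandTotal <- function(t) unname(t$grand_total)

#' @rdname pathwayTally
#' @export
clusteredPct <- function(t) {
  roundHalfUp(100 * t$n_clustered / t$grand_total, 1)
}

#' @rdname pathwayTally
#' @param pathway Pathway name.
#' @export
pathwayPct <- function(t, pathway) {
  roundHalfUp(100 * t$pathway_counts[[pathway]] / t$grand_total, 1)
}

#' @rdname pathwayTally
#' @export
perGenomeMean <- function(t, pathway) {
  roundHalfUp(t$pathway_counts[[pathway]] / t$n_genomes, 1)
}

#' Write an annotation table as TSV
#'
#' @param annotations Annotation table from \code{\link{annotateCohort}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeAnnotationTsv <- function(annotations, path) {
  write.table(annotations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
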