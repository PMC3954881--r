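#' @importFrom Biostrings pairwiseAlignment nmatch nmismatch nindel nchar
#'   insertion deletion aligned pattern subject AAString
#' @importFrom BiocGenerics score start end
NULL

# Substitution matrices shipped with Biostrings, loaded lazily by name.
.substitutionMatrix <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Scoring scheme for protein alignment and E-value statistics
#'
#' Defaults reproduce the conventional gapped BLOSUM62 protein search
#' (gap open 11, gap extend 1) with the standard Karlin-Altschul parameters
#' for that scheme (lambda = 0.267, K = 0.041).
#'
#' @param matrix Substitution matrix name (a matrix shipped with Biostrings).
#' @param gapOpen,gapExtend Positive affine gap penalties;
#'   \code{gapExtend <= gapOpen} required.
#' @param lambda,K Positive Karlin-Altschul statistical parameters.
#' @return A \code{ScoringScheme} (list).
#' @examples
#' scoringScheme()
#' @export
scoringScheme <- function(matrix = "BLOSUM62", gapOpen = 11, gapExtend = 1,
                          lambda = 0.267, K = 0.041) {
  stopifnot(gapOpen > 0, gapExtend > 0)
  if (gapExtend > gapOpen) stop("gapExtend must be <= gapOpen")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend,
                 lambda = lambda, K = K),
            class = "ScoringScheme")
}

#' Homology-screen thresholds
#'
#' The annotation screen uses E-value <= 1e-10, coverage >= 70% and
#' identity >= 35%; the core-gene screen raises identity to >= 50%.
#' All comparisons are inclusive. Coverage is computed on the query
#' sequence by default; the denominator side is configurable.
#'
#' @param maxEvalue Maximum E-value (inclusive).
#' @param minCoverage Minimum percent coverage (inclusive).
#' @param minIdentity Minimum percent identity (inclusive).
#' @param coverageOn Which sequence the coverage denominator uses:
#'   \code{"query"}, \code{"subject"} or \code{"both"} (both must pass).
#' @return A \code{Thresholds} (list).
#' @examples
#' similarityThresholds()                     # annotation screen
#' similarityThresholds(minIdentity = 50)     # core-gene screen
#' @export
similarityThresholds <- function(maxEvalue = 1e-10, minCoverage = 70,
                                 minIdentity = 35,
                                 coverageOn = c("query", "subject", "both")) {
  stopifnot(maxEvalue >= 0,
            minCoverage >= 0, minCoverage <= 100,
            minIdentity >= 0, minIdentity <= 100)
  structure(list(maxEvalue = maxEvalue, minCoverage = minCoverage,
                 minIdentity = minIdentity,
                 coverageOn = match.arg(coverageOn)),
            class = "Thresholds")
}

#' Karlin-Altschul E-value
#'
#' \eqn{E = K m n e^{-\lambda S}} for raw score \eqn{S}, query length
#' \eqn{m} and database length \eqn{n}.
#'
#' @param rawScore Raw alignment score.
#' @param queryLen,dbLen Positive sequence/database lengths (residues).
#' @param scheme A \code{\link{scoringScheme}}.
#' @return The expected number of chance hits at least this good.
#' @examples
#' karlinEvalue(0, 100, 100)  # K * 100 * 100 = 410
#' @export
karlinEvalue <- function(rawScore, queryLen, dbLen, scheme = scoringScheme()) {
  if (any(queryLen <= 0) || any(dbLen <= 0)) {
    stop("queryLen and dbLen must be positive")
  }
  scheme$K * queryLen * dbLen * exp(-scheme$lambda * rawScore)
}

# log10 of the E-value, stable for scores whose E underflows double range.
.log10Evalue <- function(rawScore, queryLen, dbLen, scheme) {
  log10(scheme$K) + log10(queryLen) + log10(dbLen) -
    scheme$lambda * rawScore / log(10)
}

# Align a set of (query index, subject index) pairs with Smith-Waterman
# (local) or Needleman-Wunsch (global), batched per subject for speed.
# Returns one row per pair with raw metrics; identity is over aligned
# columns (gaps included in the denominator, as in BLAST), coverage is the
# aligned-residue fraction of each side.
.alignPairs <- function(queries, subjects, qi, si, scheme,
                        type = "local") {
  stopifnot(length(qi) == length(si))
  if (length(qi) == 0L) {
    return(data.frame(q = integer(0), s = integer(0), raw_score = numeric(0),
                      aln_len = integer(0), n_match = integer(0),
                      n_mismatch = integer(0), gap_opens = integer(0),
                      qstart = integer(0), qend = integer(0),
                      sstart = integer(0), send = integer(0),
                      identity_pct = numeric(0), qcov_pct = numeric(0),
                      scov_pct = numeric(0)))
  }
  mat <- .substitutionMatrix(scheme$matrix)
  groups <- split(seq_along(qi), si)
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    idx <- groups[[g]]
    sj <- si[idx[1L]]
    pa <- pairwiseAlignment(queries[qi[idx]], subjects[[sj]],
                            type = type, substitutionMatrix = mat,
                            gapOpening = scheme$gapOpen,
                            gapExtension = scheme$gapExtend)
    ni <- nindel(pa)
    out[[g]] <- data.frame(
      q = qi[idx], s = sj,
      raw_score = score(pa),
      aln_len = nchar(pa),
      n_match = nmatch(pa),
      n_mismatch = nmismatch(pa),
      gap_opens = insertion(ni)[, "Length"] + deletion(ni)[, "Length"],
      qstart = start(pattern(pa)), qend = end(pattern(pa)),
      sstart = start(subject(pa)), send = end(subject(pa)))
  }
  res <- do.call(rbind, out)
  qlen <- width(queries)[res$q]
  slen <- width(subjects)[res$s]
  res$identity_pct <- 100 * res$n_match / res$aln_len
  res$qcov_pct <- 100 * (res$qend - res$qstart + 1L) / qlen
  res$scov_pct <- 100 * (res$send - res$sstart + 1L) / slen
  res
}

#' Optimal local (Smith-Waterman) alignment of two proteins
#'
#' Computes the optimal affine-gap local alignment under the scheme's
#' substitution matrix and reports the screening metrics used throughout the
#' pipeline: raw score, Karlin-Altschul E-value, percent identity over
#' aligned columns, and percent coverage of the query.
#'
#' @param query,subject Protein strings (20 amino acids plus X).
#' @param scheme A \code{\link{scoringScheme}}.
#' @param queryId,subjectId Identifiers carried into the result.
#' @param dbLen Database length (residues) for the E-value; defaults to the
#'   subject length (single-sequence search).
#' @return One-row \code{data.frame} (a homology hit) with columns
#'   \code{query_id}, \code{subject_id}, \code{raw_score}, \code{evalue},
#'   \code{identity_pct}, \code{coverage_pct}, \code{scov_pct},
#'   \code{aln_len}, \code{n_match}, \code{n_mismatch}, \code{gap_opens},
#'   \code{qstart}, \code{qend}, \code{sstart}, \code{send}.
#' @examples
#' alignLocal("HEAGAWGHEE", "PAWHEAE")
#' @export
alignLocal <- function(query, subject, scheme = scoringScheme(),
                       queryId = "query", subjectId = "subject",
                       dbLen = nchar(subject)) {
  checkProtein(query, "query")
  checkProtein(subject, "subject")
  qs <- AAStringSet(query)
  ss <- AAStringSet(subject)
  h <- .alignPairs(qs, ss, 1L, 1L, scheme, type = "local")
  data.frame(query_id = queryId, subject_id = subjectId,
             raw_score = h$raw_score,
             evalue = karlinEvalue(h$raw_score, nchar(query), dbLen, scheme),
             identity_pct = h$identity_pct,
             coverage_pct = h$qcov_pct,
             scov_pct = h$scov_pct,
             aln_len = h$aln_len, n_match = h$n_match,
             n_mismatch = h$n_mismatch, gap_opens = h$gap_opens,
             qstart = h$qstart, qend = h$qend,
             sstart = h$sstart, send = h$send)
}

#' Apply screen thresholds to homology hits
#'
#' A hit passes iff \code{evalue <= maxEvalue} AND
#' \code{coverage >= minCoverage} AND \code{identity >= minIdentity},
#' all inclusive. Coverage is taken from the side(s) configured in the
#' thresholds (\code{coverage_pct} is query-side; \code{scov_pct}
#' subject-side).
#'
#' @param hit Data frame of hits (as from \code{\link{alignLocal}}).
#' @param t A \code{\link{similarityThresholds}}.
#' @return Logical vector, one per hit row.
#' @export
passesThresholds <- function(hit, t = similarityThresholds()) {
  cov <- switch(t$coverageOn,
    query = hit$coverage_pct,
    subject = hit$scov_pct,
    both = pmin(hit$coverage_pct, hit$scov_pct))
  hit$evalue <= t$maxEvalue & cov >= t$minCoverage &
    hit$identity_pct >= t$minIdentity
}

# Candidate pairs sharing >= minShared k-mers, from an inverted k-mer index.
# Returns a 2-column matrix of (i, j) with i < j.
.kmerCandidatePairs <- function(seqs, k = 4L, minShared = 1L) {
  n <- length(seqs)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  km <- lapply(as.character(seqs), proteinKmers, k = k)
  idx <- split(rep.int(seq_len(n), lengths(km)), unlist(km, use.names = FALSE))
  keys <- unlist(lapply(idx, function(v) {
    if (length(v) < 2L) return(numeric(0))
    v <- sort.int(unique(v))
    if (length(v) < 2L) return(numeric(0))
    cb <- utils::combn(v, 2L)
    cb[1L, ] * (n + 1) + cb[2L, ]
  }), use.names = FALSE)
  if (length(keys) == 0L) return(matrix(integer(0), ncol = 2L))
  if (minShared > 1L) {
    tab <- table(keys)
    keys <- as.numeric(names(tab)[tab >= minShared])
  } else {
    keys <- unique(keys)
  }
  cbind(as.integer(keys %/% (n + 1)), as.integer(keys %% (n + 1)))
}

#' All-vs-all homology graph over a cohort's proteomes
#'
#' Aligns every cross-checked protein pair (a shared k-mer prefilter skips
#' pairs that cannot be homologous) and builds the undirected similarity
#' graph used for ortholog clustering: an edge is present iff the hit passes
#' the thresholds in at least one query direction; edge weight is
#' \code{min(-log10(evalue), 200)}. Self-hits are excluded.
#'
#' @param cohort A \code{\link{GenomeCohort}} (or list of
#'   \code{AnnotatedGenome}).
#' @param t \code{\link{similarityThresholds}} for edge admission.
#' @param scheme \code{\link{scoringScheme}}.
#' @param proteinIds Optional restriction to a subset of protein ids.
#' @param kmerK,minSharedKmers Prefilter: candidate pairs must share at
#'   least \code{minSharedKmers} k-mers of length \code{kmerK}.
#' @return An \code{igraph} undirected graph; vertices carry \code{name}
#'   (protein id), \code{genome} and \code{nres} (length) attributes, edges
#'   carry \code{weight} plus the hit metrics.
#' @export
allVsAll <- function(cohort, t = similarityThresholds(),
                     scheme = scoringScheme(), proteinIds = NULL,
                     kmerK = 4L, minSharedKmers = 1L) {
  gl <- if (is(cohort, "GenomeCohort")) genomes(cohort) else cohort
  if (length(gl) < 2L) stop("all-vs-all needs at least 2 genomes")
  seqs <- do.call(c, unname(lapply(gl, proteins)))
  genome_of <- rep(vapply(gl, strainId, character(1)),
                   vapply(gl, function(g) length(proteins(g)), integer(1)))
  if (anyDuplicated(names(seqs))) {
    stop("duplicate protein ids across cohort: ",
         paste(head(unique(names(seqs)[duplicated(names(seqs))]), 5),
               collapse = ", "))
  }
  if (!is.null(proteinIds)) {
    keep <- names(seqs) %in% proteinIds
    seqs <- seqs[keep]
    genome_of <- genome_of[keep]
  }
  n <- length(seqs)
  dbLen <- sum(width(seqs))
  pairs <- .kmerCandidatePairs(seqs, k = kmerK, minShared = minSharedKmers)
  # drop within-genome self pairs? No: paralogs within a genome are real
  # edges; only identical protein (i == j) is excluded, which the i < j
  # pairing already guarantees.
  hits <- .alignPairs(seqs, seqs, pairs[, 1L], pairs[, 2L], scheme)
  if (nrow(hits) > 0L) {
    ev_q <- karlinEvalue(hits$raw_score, width(seqs)[hits$q], dbLen, scheme)
    ev_s <- karlinEvalue(hits$raw_score, width(seqs)[hits$s], dbLen, scheme)
    pass_q <- passesThresholds(data.frame(
      evalue = ev_q, coverage_pct = hits$qcov_pct, scov_pct = hits$scov_pct,
      identity_pct = hits$identity_pct), t)
    pass_s <- passesThresholds(data.frame(
      evalue = ev_s, coverage_pct = hits$scov_pct, scov_pct = hits$qcov_pct,
      identity_pct = hits$identity_pct), t)
    keep <- pass_q | pass_s
    hits <- hits[keep, , drop = FALSE]
    if (nrow(hits) > 0L) {
      lg <- pmin(.log10Evalue(hits$raw_score, width(seqs)[hits$q], dbLen,
                              scheme),
                 .log10Evalue(hits$raw_score, width(seqs)[hits$s], dbLen,
                              scheme))
      hits$weight <- pmin(-lg, 200)
      hits$evalue <- 10^lg
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = names(seqs))
  g <- igraph::set_vertex_attr(g, "genome", value = genome_of)
  g <- igraph::set_vertex_attr(g, "nres", value = width(seqs))
  if (nrow(hits) > 0L) {
    g <- igraph::add_edges(
      g, rbind(hits$q, hits$s),
      weight = hits$weight, identity_pct = hits$identity_pct,
      raw_score = hits$raw_score, evalue = hits$evalue,
      qcov_pct = hits$qcov_pct, scov_pct = hits$scov_pct)
  }
  g
}

#' Write homology hits as BLAST outfmt-6 style TSV
#'
#' Columns: query, subject, identity, alignment length, mismatches, gap
#' opens, qstart, qend, sstart, send, evalue, raw score.
#'
#' @param hits Data frame of hits (from \code{\link{alignLocal}} or
#'   screening).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
writeHitsTsv <- function(hits, path) {
  out <- data.frame(query = hits$query_id, subject = hits$subject_id,
                    identity = sprintf("%.2f", hits$identity_pct),
                    aln_len = hits$aln_len, mismatches = hits$n_mismatch,
                    gapopens = hits$gap_opens,
                    qstart = hits$qstart, qend = hits$qend,
                    sstart = hits$sstart, send = hits$send,
                    evalue = format(hits$evalue, digits = 3),
                    score = hits$raw_score)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
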