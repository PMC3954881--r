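#' Neighborhood parameters for cluster detection
#'
#' Two arsenic-related genes are neighbors iff they lie on the same contig,
#' have at most \code{maxIntervening} non-arsenic genes between them, and
#' their intergenic gap is at most \code{maxGapBp}. The defaults (one
#' tolerated insertion, 5 kb) capture operonic adjacency while tolerating a
#' single inserted ORF.
#'
#' @param maxIntervening Non-negative integer (default 1).
#' @param maxGapBp Positive integer (default 5000).
#' @return A \code{NeighborhoodParams} (list).
#' @export
neighborhoodParams <- function(maxIntervening = 1L, maxGapBp = 5000L) {
  stopifnot(maxIntervening >= 0L, maxGapBp > 0L)
  structure(list(maxIntervening = as.integer(maxIntervening),
                 maxGapBp = as.integer(maxGapBp)),
            class = "NeighborhoodParams")
}

#' Canonical name of a gene cluster's organization
#'
#' Joins the member family names with \code{"-"}, read in the transcription
#' direction of the majority strand: a cluster whose members mostly lie on
#' the minus strand is read right-to-left, so mirrored copies of the same
#' operon receive the same form name (e.g. arsR-arsC-acr3 regardless of
#' which strand carries it). Strand ties are broken by taking the
#' lexicographically smaller of the two readings.
#'
#' @param families Family names in ascending coordinate order.
#' @param strands Per-gene strand (\code{"+"}/\code{"-"}), same length.
#' @return Canonical form string.
#' @examples
#' canonicalForm(c("arsR", "arsC", "acr3"), c("+", "+", "+"))
#' canonicalForm(c("acr3", "arsC", "arsR"), c("-", "-", "-"))  # same form
#' @export
canonicalForm <- function(families, strands = rep("+", length(families))) {
  stopifnot(length(families) == length(strands))
  fwd <- paste(families, collapse = "-")
  rev_ <- paste(rev(families), collapse = "-")
  nplus <- sum(strands == "+")
  nminus <- sum(strands == "-")
  if (nplus > nminus) fwd
  else if (nminus > nplus) rev_
  else min(fwd, rev_)
}

#' Detect gene-neighborhood clusters of arsenic-related genes
#'
#' Clusters are maximal runs of neighboring candidate genes (see
#' \code{\link{neighborhoodParams}}); a single isolated candidate is not a
#' cluster. Clusters never span contigs.
#'
#' @param candidates Data frame of this genome's candidates with a
#'   \code{protein_id} and \code{family} column (from
#'   \code{\link{screenCandidates}}).
#' @param genome The \code{\link{AnnotatedGenome}}.
#' @param p \code{\link{neighborhoodParams}}.
#' @return List of gene clusters; each has \code{genome_id}, \code{contig},
#'   \code{members} (data frame: protein_id, family, strand, start, end, in
#'   coordinate order) and \code{form} (canonical organization name).
#' @export
detectClusters <- function(candidates, genome, p = neighborhoodParams()) {
  feats <- genomeFeatures(genome)
  ids <- mcols(feats)$protein_id
  unknown <- setdiff(candidates$protein_id, ids)
  if (length(unknown) > 0L) {
    stop("candidate references unknown gene id(s): ",
         paste(head(unknown, 5), collapse = ", "))
  }
  if (nrow(candidates) == 0L) return(list())
  fam_of <- setNames(candidates$family, candidates$protein_id)
  clusters <- list()
  for (ctg in unique(as.character(seqnames(feats)))) {
    sel <- as.character(seqnames(feats)) == ctg
    fsub <- feats[sel]
    idsub <- mcols(fsub)$protein_id
    cand_idx <- which(idsub %in% candidates$protein_id)
    if (length(cand_idx) < 2L) next
    # neighbor test between consecutive candidates along the contig
    run <- list(cand_idx[1L])
    for (k in seq_len(length(cand_idx) - 1L)) {
      a <- cand_idx[k]
      b <- cand_idx[k + 1L]
      intervening <- b - a - 1L
      gap <- start(fsub)[b] - end(fsub)[a] - 1L
      joined <- intervening <= p$maxIntervening && gap <= p$maxGapBp
      if (joined) {
        run[[length(run)]] <- c(run[[length(run)]], b)
      } else {
        run[[length(run) + 1L]] <- b
      }
    }
    for (r in run) {
      if (length(r) < 2L) next
      members <- data.frame(
        protein_id = idsub[r],
        family = unname(fam_of[idsub[r]]),
        strand = as.character(strand(fsub))[r],
        start = start(fsub)[r],
        end = end(fsub)[r])
      clusters[[length(clusters) + 1L]] <- list(
        genome_id = strainId(genome), contig = ctg, members = members,
        form = canonicalForm(members$family, members$strand))
    }
  }
  clusters
}

# Dominant pathway of a cluster; ties broken in fixed pathway order.
.clusterPathway <- function(cluster) {
  pw <- familyPathway(cluster$members$family)
  tab <- table(factor(pw, levels = c("ars", "aio", "arr", "arsM")))
  names(tab)[which.max(tab)]
}

#' Census of operon organization forms across a cohort
#'
#' Counts detected clusters per canonical form, optionally restricted to
#' clusters whose dominant member pathway matches \code{pathway}. Forms
#' whose share of the counted operons exceeds \code{mainThreshold} are
#' flagged as main forms.
#'
#' @param clusters Cohort-wide list of clusters from
#'   \code{\link{detectClusters}}.
#' @param pathway Optional pathway filter (\code{"ars"}, \code{"aio"},
#'   \code{"arr"}, \code{"arsM"}); \code{NULL} counts all clusters.
#' @param mainThreshold Main-form frequency fraction (default 0.045, i.e.
#'   forms above 4.5\% of operons).
#' @return A \code{FormCensus}: list with \code{counts} (named, decreasing),
#'   \code{total}, \code{n_forms}, \code{main_forms}.
#' @export
censusForms <- function(clusters, pathway = NULL, mainThreshold = 0.045) {
  if (!is.null(pathway)) {
    keep <- vapply(clusters, .clusterPathway, character(1)) == pathway
    clusters <- clusters[keep]
  }
  forms <- vapply(clusters, `[[`, character(1), "form")
  counts <- sort(table(forms), decreasing = TRUE)
  counts <- setNames(as.integer(counts), names(counts))
  total <- length(forms)
  main <- if (total > 0L) names(counts)[counts / total > mainThreshold]
          else character(0)
  structure(list(counts = counts, total = total,
                 n_forms = length(counts), main_forms = main),
            class = "FormCensus")
}

#' @export
print.FormCensus <- function(x, ...) {
  cat("FormCensus:", x$total, "operons,", x$n_forms, "distinct forms;",
      length(x$main_forms), "main form(s)\n")
  invisible(x)
}

#' Write a form census as TSV (form, count, share)
#'
#' @param census A \code{\link{censusForms}} result.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeCensusTsv <- function(census, path) {
  df <- data.frame(form = names(census$counts),
                   count = unname(census$counts),
                   share = if (census$total > 0)
                     unname(census$counts) / census$total else numeric(0))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flanking-gene report for a cluster
#'
#' Lists up to \code{window} annotated genes upstream and downstream of a
#' cluster on its contig, preserving order and strand. Genes are labelled
#' with their arsenic family (if annotated or planted), their pst phosphate
#' transporter label if planted, else \code{"other"}. Lists are truncated at
#' contig edges.
#'
#' @param cluster One cluster from \code{\link{detectClusters}}.
#' @param genome The \code{\link{AnnotatedGenome}}.
#' @param window Positive number of genes on each side.
#' @param annotations Optional cohort annotation table used for labels.
#' @return Data frame: side (upstream/downstream), protein_id, label,
#'   strand, start, end.
#' @export
flankingReport <- function(cluster, genome, window = 5L,
                           annotations = NULL) {
  if (window < 1L) stop("window must be >= 1")
  feats <- genomeFeatures(genome)
  sel <- as.character(seqnames(feats)) == cluster$contig
  fsub <- feats[sel]
  idsub <- mcols(fsub)$protein_id
  pos <- match(cluster$members$protein_id, idsub)
  lo <- min(pos)
  hi <- max(pos)
  up <- seq(max(1L, lo - window), lo - 1L)
  down <- seq(hi + 1L, min(length(fsub), hi + window))
  if (lo == 1L) up <- integer(0)
  if (hi == length(fsub)) down <- integer(0)
  lab <- function(i) {
    pid <- idsub[i]
    if (!is.null(annotations) && pid %in% annotations$protein_id) {
      return(annotations$family[match(pid, annotations$protein_id)])
    }
    l <- mcols(fsub)$label[i]
    if (!is.null(l) && !is.na(l) &&
        l %in% c(names(arsenicFamilies()), "pstS", "pstC", "pstA", "pstB")) {
      return(l)
    }
    "other"
  }
  idx <- c(up, down)
  if (length(idx) == 0L) {
    return(data.frame(side = character(0), protein_id = character(0),
                      label = character(0), strand = character(0),
                      start = integer(0), end = integer(0)))
  }
  data.frame(
    side = rep(c("upstream", "downstream"), c(length(up), length(down))),
    protein_id = idsub[idx],
    label = vapply(idx, lab, character(1)),
    strand = as.character(strand(fsub))[idx],
    start = start(fsub)[idx],
    end = end(fsub)[idx])
}

#' Write detected clusters as TSV
#'
#' Columns: genome_id, contig, start, end, n_members, form, member_ids.
#'
#' @param clusters List of clusters from \code{\link{detectClusters}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeClustersTsv <- function(clusters, path) {
  df <- do.call(rbind, lapply(clusters, function(cl) {
    data.frame(genome_id = cl$genome_id, contig = cl$contig,
               start = min(cl$members$start), end = max(cl$members$end),
               n_members = nrow(cl$members), form = cl$form,
               member_ids = paste(cl$members$protein_id, collapse = ","))
  }))
  if (is.null(df)) {
    df <- data.frame(genome_id = character(0), contig = character(0),
                     start = integer(0), end = integer(0),
                     n_members = integer(0), form = character(0),
                     member_ids = character(0))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
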