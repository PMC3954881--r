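#' @importFrom grDevices png dev.off
NULL

#' Build the strains x gene-family distribution matrix
#'
#' One row per cohort strain (all-zero rows retained for strains without
#' arsenic genes), one column per configured gene family plus a final
#' \code{ars_clusters} column counting the ars-like clusters (clusters
#' whose dominant member pathway is \code{ars}) of each strain. With the
#' default 20 families this gives 21 columns.
#'
#' @param annotations Annotation table from \code{\link{annotateCohort}}
#'   (confirmed rows are counted).
#' @param clusters Cohort-wide cluster list.
#' @param cohort The \code{\link{GenomeCohort}}.
#' @param families Family columns (default: all 20).
#' @return A \code{\link{DistributionMatrix}} (flags unset; see
#'   \code{\link{flagOutliers}}).
#' @export
buildMatrix <- function(annotations, clusters, cohort,
                        families = names(arsenicFamilies())) {
  sids <- unname(vapply(genomes(cohort), strainId, character(1)))
  conf <- annotations[annotations$status %in%
                        c("clustered", "scattered_confirmed"), ,
                      drop = FALSE]
  orphan <- setdiff(conf$genome_id, sids)
  if (length(orphan) > 0L) {
    stop("annotated strain(s) absent from cohort metadata: ",
         paste(orphan, collapse = ", "))
  }
  counts <- matrix(0L, nrow = length(sids), ncol = length(families) + 1L,
                   dimnames = list(sids, c(families, "ars_clusters")))
  if (nrow(conf) > 0L) {
    tab <- table(factor(conf$genome_id, levels = sids),
                 factor(conf$family, levels = families))
    counts[, families] <- as.integer(tab)
  }
  for (cl in clusters) {
    if (.clusterPathway(cl) == "ars" && cl$genome_id %in% sids) {
      counts[cl$genome_id, "ars_clusters"] <-
        counts[cl$genome_id, "ars_clusters"] + 1L
    }
  }
  new("DistributionMatrix", counts = counts,
      flags = rep("none", length(sids)))
}

#' Flag strains with outlying arsenic gene totals
#'
#' The cohort mean is the grand total of gene-family counts divided by the
#' number of strains. A strain is flagged \code{2x} if its gene total is at
#' least twice (but under four times) the mean, \code{4x} if at least four
#' times (both inclusive) -- the single/double asterisk annotation of the
#' distribution heatmap.
#'
#' @param m A \code{\link{DistributionMatrix}}.
#' @return The matrix with flags set.
#' @export
flagOutliers <- function(m) {
  counts <- distCounts(m)
  if (nrow(counts) == 0L) stop("empty distribution matrix")
  geneCols <- setdiff(colnames(counts), "ars_clusters")
  totals <- rowSums(counts[, geneCols, drop = FALSE])
  mu <- sum(totals) / nrow(counts)
  flags <- rep("none", nrow(counts))
  if (mu > 0) {
    flags[totals >= 2 * mu] <- "2x"
    flags[totals >= 4 * mu] <- "4x"
  }
  new("DistributionMatrix", counts = counts, flags = flags)
}

# Tip order of a ladderized tree (ascending clade size, larger clade last),
# as plotted top to bottom.
.treeTipOrder <- function(tree) {
  lt <- ape::ladderize(tree, right = FALSE)
  lt$tip.label[lt$edge[lt$edge[, 2L] <= ape::Ntip(lt), 2L]]
}

#' Order matrix rows by the core-gene phylogeny
#'
#' Rows are permuted to the leaf order of the (ladderized) tree; contents
#' are unchanged. Reordering twice is idempotent.
#'
#' @param m A \code{\link{DistributionMatrix}}.
#' @param tree \code{phylo} tree whose tips are exactly the matrix rows.
#' @return The reordered matrix.
#' @export
orderByTree <- function(m, tree) {
  counts <- distCounts(m)
  missing <- setdiff(rownames(counts), tree$tip.label)
  extra <- setdiff(tree$tip.label, rownames(counts))
  if (length(missing) || length(extra)) {
    stop("tree leaves and matrix rows differ; missing from tree: ",
         paste(missing, collapse = ","), "; extra in tree: ",
         paste(extra, collapse = ","))
  }
  ord <- .treeTipOrder(tree)
  new("DistributionMatrix", counts = counts[ord, , drop = FALSE],
      flags = strainFlags(m)[match(ord, rownames(counts))])
}

#' Write a distribution matrix as TSV
#'
#' Columns: strain, the gene families, \code{ars_clusters}, \code{total}
#' (gene columns only) and \code{flag}.
#'
#' @param m A \code{\link{DistributionMatrix}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeDistributionTsv <- function(m, path) {
  counts <- distCounts(m)
  geneCols <- setdiff(colnames(counts), "ars_clusters")
  df <- data.frame(strain = rownames(counts), counts,
                   total = rowSums(counts[, geneCols, drop = FALSE]),
                   flag = strainFlags(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a distribution matrix TSV back
#'
#' @param path A file written by \code{\link{writeDistributionTsv}}.
#' @return A \code{\link{DistributionMatrix}}.
#' @export
readDistributionTsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  counts <- as.matrix(df[, setdiff(colnames(df),
                                   c("strain", "total", "flag")),
                         drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$strain
  new("DistributionMatrix", counts = counts, flags = df$flag)
}

#' Render the distribution heatmap
#'
#' Writes a PNG heatmap (rows in matrix order, i.e. tree order after
#' \code{\link{orderByTree}}; color by count; strain labels annotated with
#' \code{*} / \code{**} for 2x/4x flags) and the matrix as TSV alongside.
#'
#' @param m A \code{\link{DistributionMatrix}}.
#' @param path PNG output path; the TSV is written to the same path with a
#'   \code{.tsv} extension.
#' @return \code{path}, invisibly.
#' @export
renderHeatmap <- function(m, path) {
  counts <- distCounts(m)
  flags <- strainFlags(m)
  mark <- c(none = "", `2x` = " *", `4x` = " **")[flags]
  labs <- paste0(rownames(counts), mark)
  maxv <- max(counts, 1L)
  pheatmap::pheatmap(
    counts, cluster_rows = FALSE, cluster_cols = FALSE,
    labels_row = labs, breaks = seq(0, maxv, length.out = 101),
    color = grDevices::colorRampPalette(c("white", "orange", "red"))(100),
    filename = path, silent = TRUE)
  writeDistributionTsv(m, sub("\\.[A-Za-z]+$", ".tsv", path))
  invisible(path)
}
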