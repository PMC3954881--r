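#' @importFrom graphics axis plot points text
NULL

#' Habitat-group summary of arsenic gene counts
#'
#' Per-habitat statistics of arsenic-related genes per genome, plus the two
#' comparisons of interest: host-associated strains (codes H, P, Z) versus
#' environmental strains (S, W, D, R), and arsenic-rich strains versus the
#' rest. Strains coded E, U or NA appear in the per-group table but are
#' excluded from the host/environment comparison.
#'
#' @param tally A \code{\link{countByPathway}} tally carrying per-genome
#'   counts.
#' @param metadata Strain metadata (\code{data.frame}/\code{DataFrame} with
#'   strain_id, habitat_code, genome_size_bp, arsenic_rich).
#' @param hostCodes,envCodes Habitat-code sets for the comparison.
#' @return A \code{GroupSummary}: list with \code{groups} (data frame:
#'   habitat_code, n, mean, median, min, max), \code{host_mean},
#'   \code{env_mean}, \code{env_host_ratio} (NA when undefined),
#'   \code{rich_mean}, \code{other_mean}.
#' @export
summarizeByGroup <- function(tally, metadata,
                             hostCodes = c("H", "P", "Z"),
                             envCodes = c("S", "W", "D", "R")) {
  metadata <- as.data.frame(metadata)
  perGenome <- tally$per_genome
  if (is.null(perGenome)) stop("tally carries no per-genome counts")
  missing <- setdiff(names(perGenome), metadata$strain_id)
  if (length(missing) > 0L) {
    stop("strain(s) missing metadata: ", paste(missing, collapse = ", "))
  }
  md <- metadata[match(names(perGenome), metadata$strain_id), ]
  codes <- md$habitat_code
  groups <- do.call(rbind, lapply(unique(codes), function(cc) {
    v <- perGenome[codes == cc]
    data.frame(habitat_code = cc, n = length(v), mean = mean(v),
               median = median(v), min = min(v), max = max(v))
  }))
  groups <- groups[order(groups$habitat_code), , drop = FALSE]
  rownames(groups) <- NULL
  hostv <- perGenome[codes %in% hostCodes]
  envv <- perGenome[codes %in% envCodes]
  hostMean <- if (length(hostv)) mean(hostv) else NA_real_
  envMean <- if (length(envv)) mean(envv) else NA_real_
  ratio <- if (!is.na(hostMean) && !is.na(envMean) && hostMean > 0) {
    envMean / hostMean
  } else NA_real_
  richv <- perGenome[md$arsenic_rich]
  otherv <- perGenome[!md$arsenic_rich]
  structure(list(groups = groups,
                 host_mean = hostMean, env_mean = envMean,
                 env_host_ratio = ratio,
                 rich_mean = if (length(richv)) mean(richv) else NA_real_,
                 other_mean = if (length(otherv)) mean(otherv)
                              else NA_real_),
            class = "GroupSummary")
}

#' @export
print.GroupSummary <- function(x, ...) {
  cat("GroupSummary over", sum(x$groups$n), "strains in",
      nrow(x$groups), "habitat groups\n")
  print(x$groups)
  cat(sprintf("host mean %.2f | env mean %.2f | rich mean %.2f vs %.2f\n",
              x$host_mean, x$env_mean, x$rich_mean, x$other_mean))
  invisible(x)
}

#' Pearson correlation with two-sided t-test p-value
#'
#' Sample Pearson correlation of two vectors and the two-sided p-value from
#' the t transform \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of
#' freedom (as in \code{stats::cor.test}).
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return List with \code{r} and \code{p}.
#' @examples
#' pearsonR(1:10, (1:10) * 2 + 1)  # r = 1
#' @export
pearsonR <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Scatter plot of gene counts per genome by habitat group
#'
#' One jittered column per habitat code present in the cohort (empty codes
#' are omitted with a message); a TSV of the plotted points is written
#' alongside the PNG.
#'
#' @param tally A \code{\link{countByPathway}} tally.
#' @param metadata Strain metadata table.
#' @param path PNG output path (TSV written with \code{.tsv} extension).
#' @param seed Seed for the horizontal jitter.
#' @return \code{path}, invisibly.
#' @export
scatterByGroup <- function(tally, metadata, path, seed = 1L) {
  metadata <- as.data.frame(metadata)
  perGenome <- tally$per_genome
  md <- metadata[match(names(perGenome), metadata$strain_id), ]
  present <- intersect(HABITAT_CODES, unique(md$habitat_code))
  absent <- setdiff(HABITAT_CODES, present)
  if (length(absent) > 0L) {
    message("habitat group(s) with no strains omitted: ",
            paste(absent, collapse = ", "))
  }
  gi <- match(md$habitat_code, present)
  pts <- data.frame(strain_id = names(perGenome),
                    habitat_code = md$habitat_code,
                    genes = unname(perGenome))
  withSeed(deriveSeed(seed, 501L), {
    grDevices::png(path, width = 900, height = 600)
    plot(gi + runif(length(gi), -0.15, 0.15), pts$genes,
         xlim = c(0.5, length(present) + 0.5), xaxt = "n",
         xlab = "Isolation source", ylab = "Arsenic-related genes per genome",
         pch = 19, col = "steelblue",
         main = "Arsenic-related gene count by habitat")
    axis(1, at = seq_along(present), labels = present)
    dev.off()
  })
  write.table(pts, sub("\\.[A-Za-z]+$", ".tsv", path), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
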