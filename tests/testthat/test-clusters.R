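# Hand-built genome: 10 genes on contig A, 2 on contig B, candidates at
# chosen indices, ~1 kb genes with small gaps.
.toyGenome <- function(candIdx = c(5, 6), bigGapAfter = NULL,
                       nA = 10L, strands = NULL) {
  starts <- seq(1, by = 1500, length.out = nA)
  if (!is.null(bigGapAfter)) {
    starts[(bigGapAfter + 1):nA] <- starts[(bigGapAfter + 1):nA] + 10000
  }
  set.seed(31)
  seqsA <- vapply(seq_len(nA), function(i) randomPeptide(100), character(1))
  seqsB <- vapply(1:2, function(i) randomPeptide(100), character(1))
  gr <- GenomicRanges::GRanges(
    seqnames = rep(c("cA", "cB"), c(nA, 2)),
    ranges = IRanges::IRanges(start = c(starts, 1, 1500),
                              width = 303),
    strand = if (is.null(strands)) "+" else strands)
  S4Vectors::mcols(gr)$protein_id <- paste0("toy|g", seq_len(nA + 2))
  AnnotatedGenome("toy", gr, Biostrings::AAStringSet(
    setNames(c(seqsA, seqsB), paste0("toy|g", seq_len(nA + 2)))))
}

test_that("adjacent candidates cluster; distant or cross-contig do not", {
  g <- .toyGenome()
  cand <- data.frame(protein_id = c("toy|g5", "toy|g6"),
                     family = c("arsR", "arsC"))
  cl <- detectClusters(cand, g)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$members$protein_id, c("toy|g5", "toy|g6"))
  # three intervening genes break the neighborhood
  cand2 <- data.frame(protein_id = c("toy|g5", "toy|g9"),
                      family = c("arsR", "arsC"))
  expect_length(detectClusters(cand2, g), 0L)
  # contig boundary breaks the neighborhood
  cand3 <- data.frame(protein_id = c("toy|g10", "toy|g11"),
                      family = c("arsR", "arsC"))
  expect_length(detectClusters(cand3, g), 0L)
  # unknown id errors
  expect_error(detectClusters(data.frame(protein_id = "nope",
                                         family = "arsC"), g),
               "unknown gene id")
})

test_that("one intervening gene is tolerated but a >5kb gap is not", {
  g <- .toyGenome()
  cand <- data.frame(protein_id = c("toy|g5", "toy|g7"),
                     family = c("arsR", "arsC"))
  expect_length(detectClusters(cand, g), 1L)
  g2 <- .toyGenome(bigGapAfter = 5)
  cand2 <- data.frame(protein_id = c("toy|g5", "toy|g6"),
                      family = c("arsR", "arsC"))
  expect_length(detectClusters(cand2, g2), 0L)
})

test_that("canonical form reads along the majority strand", {
  expect_equal(canonicalForm(c("arsR", "arsC", "acr3"), c("+", "+", "+")),
               "arsR-arsC-acr3")
  # mirrored copy on the minus strand canonicalizes identically
  expect_equal(canonicalForm(c("acr3", "arsC", "arsR"), c("-", "-", "-")),
               "arsR-arsC-acr3")
  # two-member palindrome is orientation-free
  expect_equal(canonicalForm(c("arsC", "arsC"), c("+", "+")), "arsC-arsC")
  expect_equal(canonicalForm(c("arsC", "arsC"), c("-", "-")), "arsC-arsC")
})

test_that("canonical form is invariant under coordinate mirroring", {
  ann <- fixtureAnnotation()
  flip <- c("+" = "-", "-" = "+")
  for (cl in ann$clusters) {
    mirrored <- list(members = data.frame(
      family = rev(cl$members$family),
      strand = unname(flip[rev(cl$members$strand)])))
    expect_equal(canonicalForm(mirrored$members$family,
                               mirrored$members$strand),
                 cl$form)
  }
})

test_that("form census counts, conserves and flags main forms", {
  ann <- fixtureAnnotation()
  census <- censusForms(ann$clusters, pathway = "ars")
  expect_equal(sum(census$counts), census$total)
  expect_equal(census$n_forms, length(census$counts))
  # counts sum to the number of ars-dominant input clusters
  nArs <- sum(vapply(ann$clusters, arsenome:::.clusterPathway,
                     character(1)) == "ars")
  expect_equal(census$total, nArs)
  # single-cluster census: one form at 100% share, flagged main
  one <- censusForms(ann$clusters[1])
  expect_equal(one$n_forms, 1L)
  expect_equal(one$main_forms, ann$clusters[[1]]$form)
})

test_that("aio operons report pstSCAB in their flanks", {
  ann <- fixtureAnnotation()
  co <- fixtureCohort()
  aio <- Filter(function(cl) all(cl$members$family %in% c("aioB", "aioA")),
                ann$clusters)
  expect_gte(length(aio), 2L)
  found <- FALSE
  for (cl in aio) {
    rep <- flankingReport(cl, genomes(co)[[cl$genome_id]], window = 5,
                          annotations = ann$annotations)
    down <- rep$label[rep$side == "downstream"]
    if (all(c("pstS", "pstC", "pstA", "pstB") %in% down)) found <- TRUE
  }
  expect_true(found)
})

test_that("flanking report truncates at contig edges and checks window", {
  g <- .toyGenome()
  cand <- data.frame(protein_id = c("toy|g1", "toy|g2"),
                     family = c("arsR", "arsC"))
  cl <- detectClusters(cand, g)[[1]]
  rep <- flankingReport(cl, g, window = 5)
  expect_equal(sum(rep$side == "upstream"), 0L)
  expect_lte(sum(rep$side == "downstream"), 5L)
  expect_true(all(rep$label == "other"))
  expect_error(flankingReport(cl, g, window = 0), ">= 1")
})

test_that("clustered count from detection is consistent with partition", {
  ann <- fixtureAnnotation()
  cand <- ann$annotations
  part <- partitionByPosition(cand, ann$clusters)
  nClusterMembers <- length(unique(unlist(
    lapply(ann$clusters, function(cl) cl$members$protein_id))))
  expect_equal(length(part$clustered), nClusterMembers)
  expect_equal(length(part$clustered),
               nrow(cand) - length(part$scattered))
})
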