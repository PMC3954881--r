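test_that("reference database has the requested size and determinism", {
  db <- generateReferenceDB(nPerFamily = 3, seed = 11)
  expect_equal(length(db), 60L)
  expect_equal(length(unique(refFamily(db))), 20L)
  db2 <- generateReferenceDB(nPerFamily = 3, seed = 11)
  f1 <- tempfile()
  f2 <- tempfile()
  Biostrings::writeXStringSet(proteins(db), f1)
  Biostrings::writeXStringSet(proteins(db2), f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(generateReferenceDB(families = c("arsC", "xyzzy")),
               "xyzzy")
})

test_that("reference exemplars separate within- from cross-family identity", {
  db <- generateReferenceDB(nPerFamily = 2, seed = 12)
  seqs <- as.character(proteins(db))
  fam <- refFamily(db)
  # within-family pairs well above the 35% screen
  for (f in c("arsC", "acr3", "aioA")) {
    idx <- which(fam == f)
    h <- alignLocal(seqs[idx[1]], seqs[idx[2]])
    expect_gt(h$identity_pct, 35)
    expect_gt(h$coverage_pct, 70)
  }
  # cross-family pairs fail the screen (identity+coverage jointly)
  set.seed(13)
  fams <- sample(unique(fam), 6)
  for (k in seq(1, 5, by = 2)) {
    i <- which(fam == fams[k])[1]
    j <- which(fam == fams[k + 1])[1]
    h <- alignLocal(seqs[i], seqs[j])
    h$scov_pct <- h$coverage_pct
    expect_false(passesThresholds(h, similarityThresholds()))
  }
})

test_that("mutateProtein hits its identity target and validates input", {
  set.seed(2)
  s <- randomPeptide(100)
  expect_identical(mutateProtein(s, 1.0, seed = 1), s)
  m <- mutateProtein(s, 0.5, seed = 1)
  expect_equal(nchar(m), 100L)
  ident <- mean(strsplit(s, "")[[1]] == strsplit(m, "")[[1]])
  expect_gte(ident, 0.45)
  expect_lte(ident, 0.55)
  expect_error(mutateProtein(randomPeptide(5), 0.5), "too short")
  expect_error(mutateProtein(s, 0), "\\(0, 1\\]")
})

test_that("planted clusters are consecutive genes on one contig", {
  co <- fixtureMini()
  truth <- truthTable(co)
  for (tr in truth) {
    g <- genomes(co)[[tr$strain_id]]
    feats <- genomeFeatures(g)
    ids <- S4Vectors::mcols(feats)$protein_id
    for (cl in tr$clusters) {
      pos <- match(cl$member_ids, ids)
      expect_equal(pos, seq(min(pos), max(pos)))
      expect_equal(unique(as.character(
        GenomicRanges::seqnames(feats)[pos])), cl$contig)
    }
  }
})

test_that("scattered genes have >= 2 non-arsenic genes on each side", {
  co <- fixtureCohort()
  fams <- names(arsenicFamilies())
  for (tr in truthTable(co)) {
    if (length(tr$scattered) == 0) next
    g <- genomes(co)[[tr$strain_id]]
    feats <- genomeFeatures(g)
    lab <- S4Vectors::mcols(feats)$label
    ids <- S4Vectors::mcols(feats)$protein_id
    ctg <- as.character(GenomicRanges::seqnames(feats))
    for (sc in tr$scattered) {
      i <- match(sc$protein_id, ids)
      near <- which(ctg == ctg[i] & abs(seq_along(ids) - i) <= 2 &
                    seq_along(ids) != i)
      expect_false(any(lab[near] %in% fams),
                   label = paste("isolation of", sc$protein_id))
    }
  }
})

test_that("truth table counts equal emitted planted features", {
  co <- fixtureMini()
  for (tr in truthTable(co)) {
    g <- genomes(co)[[tr$strain_id]]
    feats <- genomeFeatures(g)
    role <- S4Vectors::mcols(feats)$role
    lab <- S4Vectors::mcols(feats)$label
    planted <- role %in% c("planted_cluster", "planted_scattered")
    emitted <- table(lab[planted])
    for (f in names(arsenicFamilies())) {
      expect_equal(tr$family_counts[[f]],
                   if (f %in% names(emitted)) unname(emitted[f]) else 0L,
                   label = paste(tr$strain_id, f))
    }
    expect_equal(tr$n_planted, sum(planted))
    # exactly one copy of every core gene
    expect_equal(sum(role == "core"), length(tr$core_genes))
  }
})

test_that("cohort generation is deterministic and rejects duplicates", {
  c1 <- generateCohort(miniPlans(), seed = 42, ancestorSeed = 42)
  c2 <- generateCohort(miniPlans(), seed = 42, ancestorSeed = 42)
  expect_identical(lapply(genomes(c1), function(g) as.character(proteins(g))),
                   lapply(genomes(c2), function(g) as.character(proteins(g))))
  expect_identical(truthTable(c1), truthTable(c2))
  plans <- miniPlans()
  plans[[2]]$strainId <- "mini1"
  expect_error(generateCohort(plans), "duplicate strain_id")
})

test_that("planted features survive a GFF3 write/read round trip", {
  co <- fixtureMini()
  d <- withr::local_tempdir()
  writeCohort(co, d)
  co2 <- readCohort(d)
  for (sid in names(genomes(co))) {
    f1 <- genomeFeatures(genomes(co)[[sid]])
    f2 <- genomeFeatures(genomes(co2)[[sid]])
    expect_equal(BiocGenerics::start(f1), BiocGenerics::start(f2))
    expect_equal(BiocGenerics::end(f1), BiocGenerics::end(f2))
    expect_equal(as.character(BiocGenerics::strand(f1)),
                 as.character(BiocGenerics::strand(f2)))
    expect_equal(S4Vectors::mcols(f1)$protein_id,
                 S4Vectors::mcols(f2)$protein_id)
    expect_identical(as.character(proteins(genomes(co)[[sid]])),
                     as.character(proteins(genomes(co2)[[sid]])))
  }
  # truth conservation: per-family planted counts sum to total planted
  truth <- truthTable(co)
  total <- sum(vapply(truth, `[[`, integer(1), "n_planted"))
  perFam <- Reduce(`+`, lapply(truth, function(tr)
    unlist(tr$family_counts)))
  expect_equal(sum(perFam), total)
})
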