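test_that("single-copy core detection recovers exactly the planted genes", {
  mini <- fixtureMini()
  g <- allVsAll(mini, t = similarityThresholds(minIdentity = 50),
                minSharedKmers = 3L)
  og <- clusterOrthologs(g)
  core <- findSingleCopyCore(og, mini)
  expect_equal(length(core$groups), 5L)  # 5 planted core genes
  trueIds <- sort(unname(unlist(lapply(truthTable(mini),
                                       function(tr) unlist(tr$core_genes)))))
  gotIds <- sort(unname(unlist(lapply(core$groups,
                                      function(g) g$members$protein_id))))
  expect_equal(gotIds, trueIds)
  expect_error(findSingleCopyCore(og, GenomeCohort(
    genomes(mini)[1],
    as.data.frame(cohortMetadata(mini))[1, ])), ">= 2 genomes")
})

test_that("multi-copy and incomplete groups are excluded from the core", {
  groups <- list(
    list(group_id = "OG1", members = data.frame(
      protein_id = c("a|1", "b|1", "c|1"), genome = c("a", "b", "c"))),
    list(group_id = "OG2", members = data.frame(   # two copies in genome a
      protein_id = c("a|2", "a|3", "b|2", "c|2"),
      genome = c("a", "a", "b", "c"))),
    list(group_id = "OG3", members = data.frame(   # missing from genome c
      protein_id = c("a|4", "b|4"), genome = c("a", "b"))))
  mini <- fixtureMini()
  # remap ids onto real proteins so lengths resolve
  ids <- unlist(lapply(genomes(mini), function(g) names(proteins(g))))
  remap <- setNames(ids[1:8], c("a|1", "b|1", "c|1", "a|2", "a|3", "b|2",
                                "c|2", "a|4"))
  sid <- names(genomes(mini))
  groups <- lapply(groups, function(gr) {
    gr$members$protein_id <- unname(remap[gr$members$protein_id])
    gr$members$genome <- sid[match(substr(gr$members$genome, 1, 1),
                                   c("a", "b", "c"))]
    gr$members <- gr$members[!is.na(gr$members$protein_id), ]
    gr
  })
  core <- findSingleCopyCore(groups, mini, lengthTol = 10)
  expect_equal(vapply(core$groups, `[[`, character(1), "group_id"), "OG1")
})

test_that("identical sequences align gap-free at full identity", {
  set.seed(41)
  s <- randomPeptide(80)
  aln <- progressiveAlign(c(g1 = s, g2 = s, g3 = s))
  expect_equal(unname(nchar(aln)), rep(80L, 3))
  expect_false(any(grepl("-", aln, fixed = TRUE)))
  expect_identical(unname(aln[1]), unname(aln[2]))
})

test_that("two-sequence alignment is optimal against the global DP", {
  set.seed(42)
  for (k in 1:10) {
    a <- randomPeptide(sample(30:80, 1))
    b <- if (k %% 2) mutateProtein(a, 0.7) else randomPeptide(sample(30:80, 1))
    aln <- progressiveAlign(c(x = a, y = b))
    ref <- BiocGenerics::score(Biostrings::pairwiseAlignment(
      a, b, type = "global",
      substitutionMatrix = arsenome:::.substitutionMatrix("BLOSUM62"),
      gapOpening = 11, gapExtension = 1))
    expect_equal(alignedPairScore(aln["x"], aln["y"]), ref)
  }
})

test_that("alignment length bounds and single-sequence warning hold", {
  set.seed(43)
  seqs <- c(a = randomPeptide(60), b = randomPeptide(75),
            c = randomPeptide(50))
  aln <- progressiveAlign(seqs)
  w <- unique(nchar(aln))
  expect_length(w, 1L)
  expect_gte(w, 75L)
  expect_warning(one <- progressiveAlign(seqs[1]), "single sequence")
  expect_identical(one, seqs[1])
})

test_that("concatenation tiles partitions and validates genome sets", {
  a1 <- c(g1 = strrep("A", 100), g2 = strrep("C", 100))
  a2 <- c(g1 = strrep("D", 50), g2 = strrep("E", 50))
  sm <- concatenateAlignments(list(p1 = a1, p2 = a2))
  expect_equal(unname(nchar(sm$rows)), c(150L, 150L))
  expect_equal(sm$partitions$start, c(1L, 101L))
  expect_equal(sm$partitions$end, c(100L, 150L))
  expect_error(concatenateAlignments(list(a1, c(g1 = "AAA", g3 = "CCC"))),
               "mismatch.*g2|g2.*mismatch")
  # single alignment is the identity operation
  sm1 <- concatenateAlignments(list(a1))
  expect_equal(unname(sm1$rows), unname(a1))
})

test_that("partition order permutation leaves pairwise distances unchanged", {
  core <- fixtureCore()
  sm <- core$sm
  alns <- lapply(seq_len(nrow(sm$partitions)), function(i) {
    vapply(sm$rows, substr, character(1), sm$partitions$start[i],
           sm$partitions$end[i])
  })
  smPerm <- concatenateAlignments(rev(alns))
  d1 <- arsenome:::.poissonDist(arsenome:::.superMatrixChars(sm))
  d2 <- arsenome:::.poissonDist(arsenome:::.superMatrixChars(smPerm))
  expect_equal(d1, d2)
})

test_that("three-taxon tree solves the three-point equations", {
  rows <- c(t1 = strrep("A", 200), t2 = strrep("A", 200),
            t3 = strrep("A", 200))
  # disjoint private mutations: additive star distances, positive branches
  substr(rows["t1"], 1, 15) <- strrep("C", 15)
  substr(rows["t2"], 51, 75) <- strrep("D", 25)
  substr(rows["t3"], 101, 140) <- strrep("E", 40)
  sm <- structure(list(rows = rows,
                       partitions = data.frame(partition = "p1", start = 1L,
                                               end = 200L)),
                  class = "SuperMatrix")
  tree <- buildTree(sm, nBootstrap = 0)
  D <- arsenome:::.poissonDist(arsenome:::.superMatrixChars(sm))
  el <- setNames(tree$edge.length,
                 ifelse(tree$edge[, 2] <= 3, tree$tip.label[tree$edge[, 2]],
                        "internal"))
  # unique unrooted 3-taxon topology: x_i = (d_ij + d_ik - d_jk) / 2
  expect_equal(unname(el["t1"]),
               (D["t1", "t2"] + D["t1", "t3"] - D["t2", "t3"]) / 2,
               tolerance = 1e-9)
  expect_equal(unname(el["t2"]),
               (D["t1", "t2"] + D["t2", "t3"] - D["t1", "t3"]) / 2,
               tolerance = 1e-9)
})

test_that("identical rows are siblings at distance zero", {
  # a and b identical; c, d, e form a distant tight clade so the a-b
  # cherry is unambiguous
  set.seed(44)
  base <- randomPeptide(300)
  far <- mutateProtein(base, 0.35)
  rows <- c(a = base, b = base,
            c = mutateProtein(far, 0.9), d = mutateProtein(far, 0.9),
            e = mutateProtein(far, 0.85))
  sm <- structure(list(rows = rows,
                       partitions = data.frame(partition = "p1", start = 1L,
                                               end = 300L)),
                  class = "SuperMatrix")
  D <- arsenome:::.poissonDist(arsenome:::.superMatrixChars(sm))
  expect_equal(D["a", "b"], 0)
  tree <- buildTree(sm, nBootstrap = 0)
  # siblings: a and b share an internal parent node
  pa <- tree$edge[match(match(c("a", "b"), tree$tip.label),
                        tree$edge[, 2]), 1]
  expect_equal(pa[1], pa[2])
  expect_equal(ape::cophenetic.phylo(tree)["a", "b"], 0, tolerance = 1e-9)
})

test_that("NJ recovers the generating topology of an additive matrix", {
  skip_if_not_installed("phangorn")
  set.seed(45)
  for (k in 1:5) {
    true <- ape::rtree(6, br = NULL)
    true$edge.length <- runif(nrow(true$edge), 0.05, 0.3)
    D <- ape::cophenetic.phylo(true)
    est <- ape::nj(as.dist(D))
    expect_equal(phangorn::RF.dist(est, true, check.labels = TRUE), 0)
  }
})

test_that("bootstrap supports are reproducible under a fixed seed", {
  core <- fixtureCore()
  t1 <- buildTree(core$sm, nBootstrap = 10, seed = 77)
  t2 <- buildTree(core$sm, nBootstrap = 10, seed = 77)
  expect_identical(t1$node.label, t2$node.label)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("saturated distances raise an actionable error", {
  rows <- c(a = strrep("A", 50), b = strrep("C", 50), c = strrep("D", 50))
  sm <- structure(list(rows = rows,
                       partitions = data.frame(partition = "p1", start = 1L,
                                               end = 50L)),
                  class = "SuperMatrix")
  expect_error(buildTree(sm, nBootstrap = 0), "saturated")
})
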