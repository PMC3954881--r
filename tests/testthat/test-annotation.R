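test_that("screening finds planted genes with correct families only", {
  mini <- fixtureMini()
  db <- fixtureDb()
  g1 <- genomes(mini)[["mini1"]]  # arsR-arsC-acr3 cluster + scattered arsC
  sc <- screenCandidates(g1, db)
  expect_equal(nrow(sc), 4L)
  expect_setequal(sc$family, c("arsR", "arsC", "acr3"))
  truth <- truthTable(mini)[["mini1"]]
  expect_setequal(sc$protein_id,
                  c(truth$clusters[[1]]$member_ids,
                    truth$scattered[[1]]$protein_id))
  fam_of <- setNames(sc$family, sc$protein_id)
  expect_equal(unname(fam_of[truth$clusters[[1]]$member_ids]),
               truth$clusters[[1]]$families)
})

test_that("an all-decoy genome screens to an empty candidate list", {
  co <- generateCohort(list(genomePlan("decoyonly", "U", nBackground = 20,
                                       nDecoys = 5)),
                       seed = 55, ancestorSeed = 101)
  sc <- screenCandidates(genomes(co)[[1]], fixtureDb())
  expect_equal(nrow(sc), 0L)
})

test_that("near-miss decoys stay below the identity screen", {
  co <- generateCohort(list(genomePlan("nearmiss", "U", nBackground = 12,
                                       nNearMiss = 4)),
                       seed = 56, ancestorSeed = 101)
  sc <- screenCandidates(genomes(co)[[1]], fixtureDb())
  expect_equal(nrow(sc[sc$status == "candidate", ]), 0L)
})

test_that("MCL separates disjoint cliques and keeps singletons", {
  # two disjoint triangles
  g <- igraph::make_graph(~ a - b, b - c, c - a, x - y, y - z, z - x)
  igraph::E(g)$weight <- 10
  igraph::V(g)$genome <- "g"
  og <- clusterOrthologs(g)
  expect_equal(length(og), 2L)
  expect_setequal(vapply(og, function(o) nrow(o$members), integer(1)),
                  c(3L, 3L))
  # single node
  g1 <- igraph::make_empty_graph(1, directed = FALSE)
  g1 <- igraph::set_vertex_attr(g1, "name", value = "solo")
  g1 <- igraph::set_vertex_attr(g1, "genome", value = "g")
  og1 <- clusterOrthologs(g1)
  expect_equal(length(og1), 1L)
  expect_equal(og1[[1]]$members$protein_id, "solo")
  expect_error(clusterOrthologs(g, inflation = 1), "> 1")
})

test_that("MCL splits a barbell graph exactly as the brute-force oracle", {
  # two 4-cliques joined by one weak edge
  n <- 8L
  A <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
  for (i in 1:4) for (j in 1:4) if (i != j) A[i, j] <- 10
  for (i in 5:8) for (j in 5:8) if (i != j) A[i, j] <- 10
  A[4, 5] <- A[5, 4] <- 0.5
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected",
                                           weighted = TRUE)
  igraph::V(g)$genome <- "g"
  og <- clusterOrthologs(g, inflation = 1.5)
  got <- lapply(og, function(o) o$members$protein_id)
  oracle <- mclOracle(A, inflation = 1.5)
  oracleSets <- lapply(oracle, function(ix) letters[ix])
  expect_equal(partitionKey(got), partitionKey(oracleSets))
  expect_equal(length(got), 2L)
})

test_that("MCL grouping is invariant to vertex order permutation", {
  set.seed(21)
  n <- 9L
  A <- matrix(0, n, n)
  for (i in 1:4) for (j in 1:4) if (i != j) A[i, j] <- runif(1, 5, 15)
  for (i in 5:9) for (j in 5:9) if (i != j) A[i, j] <- runif(1, 5, 15)
  A <- (A + t(A)) / 2
  A[2, 7] <- A[7, 2] <- 0.2
  dimnames(A) <- list(paste0("p", 1:n), paste0("p", 1:n))
  mk <- function(M) {
    g <- igraph::graph_from_adjacency_matrix(M, mode = "undirected",
                                             weighted = TRUE)
    igraph::set_vertex_attr(g, "genome", value = "g")
  }
  perm <- sample(n)
  og1 <- clusterOrthologs(mk(A))
  og2 <- clusterOrthologs(mk(A[perm, perm]))
  expect_equal(partitionKey(lapply(og1, function(o) o$members$protein_id)),
               partitionKey(lapply(og2, function(o) o$members$protein_id)))
})

test_that("position partition obeys the two-gene rule and partition laws", {
  ann <- fixtureAnnotation()
  cand <- ann$annotations
  part <- partitionByPosition(cand, ann$clusters)
  expect_setequal(c(part$clustered, part$scattered), cand$protein_id)
  expect_length(intersect(part$clustered, part$scattered), 0L)
  # every cluster has >= 2 members by construction
  expect_true(all(vapply(ann$clusters,
                         function(cl) nrow(cl$members), integer(1)) >= 2))
})

test_that("scattered confirmation accepts same-family and rejects orphans", {
  ann <- fixtureAnnotation()
  co <- fixtureCohort()
  cand <- ann$annotations
  sc <- cand[cand$status == "scattered_confirmed", , drop = FALSE]
  cl <- cand[cand$status == "clustered", , drop = FALSE]
  expect_gt(nrow(sc), 0)
  sc$status <- "candidate"
  redo <- confirmScattered(sc, cl, co)
  expect_true(all(redo$status == "scattered_confirmed"))
  # a scattered gene whose family never occurs clustered is rejected
  fake <- sc[1, ]
  fake$family <- "arrA"   # no clustered arrA partner of the right family
  clNoArr <- cl[cl$family != "arrA", , drop = FALSE]
  expect_equal(confirmScattered(fake, clNoArr, co)$status, "rejected")
  # empty scattered set passes through empty
  expect_equal(nrow(confirmScattered(sc[0, ], cl, co)), 0L)
  # empty clustered set falls back with a warning
  expect_warning(out <- confirmScattered(sc, cl[0, ], co),
                 "falling back")
  expect_true(all(out$status == "scattered_confirmed"))
})

test_that("pathway tally reproduces the cohort-scale worked example", {
  t <- pathwayTally(c(ars = 1051, aio = 60, arr = 2, arsM = 4),
                    nGenomes = 188, nClustered = 795)
  expect_equal(grandTotal(t), 1117)
  expect_equal(clusteredPct(t), 71.2)
  expect_equal(perGenomeMean(t, "ars"), 5.6)
  expect_equal(pathwayPct(t, "ars"), 94.1)
  expect_error(pathwayTally(c(ars = 1, bogus = 2), 10), "bogus")
})

test_that("countByPathway conserves totals from the annotation table", {
  ann <- fixtureAnnotation()
  co <- fixtureCohort()
  t <- countByPathway(ann$annotations, co)
  expect_equal(sum(t$pathway_counts), grandTotal(t))
  expect_equal(sum(t$per_genome), grandTotal(t))
  expect_equal(sum(t$family_counts), grandTotal(t))
  conf <- ann$annotations[ann$annotations$status %in%
                            c("clustered", "scattered_confirmed"), ]
  expect_equal(grandTotal(t), nrow(conf))
})
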