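# Shared fixtures, computed once per test run and memoized. The default
# cohort and its annotation are used by several files; the expensive
# stages (screening, core phylogeny) run a single time.

.fx <- new.env(parent = emptyenv())

fixtureCohort <- function() {
  if (is.null(.fx$cohort)) {
    .fx$cohort <- generateCohort(defaultCohortPlans(), seed = 101,
                                 ancestorSeed = 101)
  }
  .fx$cohort
}

fixtureDb <- function() {
  if (is.null(.fx$db)) {
    .fx$db <- generateReferenceDB(seed = 102, ancestorSeed = 101)
  }
  .fx$db
}

fixtureAnnotation <- function() {
  if (is.null(.fx$ann)) {
    .fx$ann <- annotateCohort(fixtureCohort(), fixtureDb())
  }
  .fx$ann
}

fixtureCore <- function() {
  if (is.null(.fx$core)) {
    co <- fixtureCohort()
    g <- allVsAll(co, t = similarityThresholds(minIdentity = 50),
                  minSharedKmers = 3L)
    og <- clusterOrthologs(g)
    core <- findSingleCopyCore(og, co)
    seqsAll <- do.call(c, unname(lapply(genomes(co), proteins)))
    alns <- lapply(core$groups, function(gr) {
      s <- setNames(as.character(seqsAll[gr$members$protein_id]),
                    gr$members$genome)
      progressiveAlign(s)
    })
    names(alns) <- vapply(core$groups, `[[`, character(1), "group_id")
    sm <- concatenateAlignments(alns)
    tree <- buildTree(sm, nBootstrap = 25, seed = 103)
    .fx$core <- list(graph = g, groups = og, core = core, sm = sm,
                     tree = tree)
  }
  .fx$core
}

# A tiny 3-genome cohort for fast unit tests. mini1 carries a second
# (scattered) arsC so that no arsenic family is universal single-copy and
# the core-gene set stays exactly the five planted housekeeping genes.
# Shares ancestorSeed 101 with fixtureDb() so the screen applies.
miniPlans <- function() {
  core <- c("rpoB", "gyrB", "recA", "dnaK", "tuf")
  list(
    genomePlan("mini1", "S", nBackground = 16,
               clusters = list(c("arsR", "arsC", "acr3")),
               scattered = "arsC", coreGenes = core),
    genomePlan("mini2", "H", nBackground = 16, scattered = "arsC",
               coreGenes = core),
    genomePlan("mini3", "W", nBackground = 16,
               clusters = list(c("arsC", "acr3")), coreGenes = core))
}

fixtureMini <- function() {
  if (is.null(.fx$mini)) {
    .fx$mini <- generateCohort(miniPlans(), seed = 104, ancestorSeed = 101)
  }
  .fx$mini
}

randomPeptide <- function(n) {
  paste(sample(arsenome:::AA_ALPHABET20, n, replace = TRUE), collapse = "")
}
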