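#' Pipeline configuration
#'
#' Collects the thresholds, parameters and seeds of a full run. Input paths
#' may be \code{NULL}, in which case \code{\link{runPipeline}} generates the
#' default synthetic cohort and matching reference database.
#'
#' @param cohortDir Directory with \code{<strain>.faa} / \code{<strain>.gff3}
#'   pairs and \code{metadata.tsv}, or \code{NULL} to simulate.
#' @param refDbFasta Reference FASTA with ids \code{ref|<family>|<i>}, or
#'   \code{NULL} to generate.
#' @param screenThresholds,coreThresholds \code{\link{similarityThresholds}}
#'   for the annotation screen (identity >= 35) and core-gene screen
#'   (identity >= 50).
#' @param scheme \code{\link{scoringScheme}}.
#' @param neighborhood \code{\link{neighborhoodParams}}.
#' @param inflation MCL inflation (default 1.5).
#' @param coreMinSharedKmers k-mer prefilter stringency for the
#'   high-stringency core-gene all-vs-all (default 3: pairs at >= 50\%
#'   identity share dozens of 4-mers, so requiring three loses no true
#'   pair while skipping almost all unrelated ones).
#' @param nBootstrap Bootstrap replicates for the core tree.
#' @param seed Master seed; all stage seeds derive from it.
#' @param outDir Output directory.
#' @return A \code{PipelineConfig} (list).
#' @export
pipelineConfig <- function(cohortDir = NULL, refDbFasta = NULL,
                           screenThresholds = similarityThresholds(),
                           coreThresholds =
                             similarityThresholds(minIdentity = 50),
                           scheme = scoringScheme(),
                           neighborhood = neighborhoodParams(),
                           inflation = 1.5, coreMinSharedKmers = 3L,
                           nBootstrap = 100L,
                           seed = 1L, outDir = tempfile("arsenome_run_")) {
  for (p in c(cohortDir, refDbFasta)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input path does not exist: ", p)
    }
  }
  structure(list(cohortDir = cohortDir, refDbFasta = refDbFasta,
                 screenThresholds = screenThresholds,
                 coreThresholds = coreThresholds, scheme = scheme,
                 neighborhood = neighborhood, inflation = inflation,
                 coreMinSharedKmers = as.integer(coreMinSharedKmers),
                 nBootstrap = as.integer(nBootstrap),
                 seed = as.integer(seed), outDir = outDir),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: cohort_dir, ref_db_fasta, out_dir, seed, inflation,
#' n_bootstrap, screen (max_evalue/min_coverage/min_identity), core
#' (same), neighborhood (max_intervening/max_gap_bp).
#'
#' @param path YAML file path.
#' @return A \code{\link{pipelineConfig}}.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  thr <- function(block, default) {
    if (is.null(block)) return(default)
    similarityThresholds(
      maxEvalue = block$max_evalue %||% default$maxEvalue,
      minCoverage = block$min_coverage %||% default$minCoverage,
      minIdentity = block$min_identity %||% default$minIdentity)
  }
  nb <- y$neighborhood
  pipelineConfig(
    cohortDir = y$cohort_dir, refDbFasta = y$ref_db_fasta,
    screenThresholds = thr(y$screen, similarityThresholds()),
    coreThresholds = thr(y$core, similarityThresholds(minIdentity = 50)),
    neighborhood = if (is.null(nb)) neighborhoodParams() else
      neighborhoodParams(nb$max_intervening %||% 1L,
                         nb$max_gap_bp %||% 5000L),
    inflation = y$inflation %||% 1.5,
    nBootstrap = y$n_bootstrap %||% 100L,
    seed = y$seed %||% 1L,
    outDir = y$out_dir %||% tempfile("arsenome_run_"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ingest one annotated genome from FASTA + GFF3
#'
#' FASTA ids must match the GFF3 CDS \code{ID} attributes 1:1; features are
#' sorted by (contig, start) on load, 1-based inclusive coordinates
#' preserved.
#'
#' @param faaPath Protein FASTA path.
#' @param gffPath GFF3 path.
#' @param strain Strain id (default: file name stem).
#' @return An \code{\link{AnnotatedGenome}}.
#' @export
ingestGenome <- function(faaPath, gffPath,
                         strain = sub("\\.faa$", "", basename(faaPath))) {
  seqs <- readAAStringSet(faaPath)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gr <- rtracklayer::import(gffPath, format = "gff3")
  gr <- gr[mcols(gr)$type == "CDS"]
  ids <- mcols(gr)$ID
  orphanSeq <- setdiff(names(seqs), ids)
  orphanFeat <- setdiff(ids, names(seqs))
  if (length(orphanSeq) || length(orphanFeat)) {
    stop("FASTA/GFF3 id mismatch for ", strain, "; proteins without ",
         "features: [", paste(orphanSeq, collapse = ","),
         "], features without proteins: [",
         paste(orphanFeat, collapse = ","), "]")
  }
  keep <- intersect(c("ID", "label", "role"), colnames(mcols(gr)))
  md <- mcols(gr)[, keep, drop = FALSE]
  colnames(md)[colnames(md) == "ID"] <- "protein_id"
  mcols(gr) <- md
  AnnotatedGenome(strain, gr, seqs)
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir Directory with per-strain \code{.faa}/\code{.gff3} pairs,
#'   \code{metadata.tsv} and optionally \code{truth.json}.
#' @return A \code{\link{GenomeCohort}}.
#' @export
readCohort <- function(dir) {
  mdPath <- file.path(dir, "metadata.tsv")
  if (!file.exists(mdPath)) stop("missing metadata file: ", mdPath)
  md <- read.table(mdPath, sep = "\t", header = TRUE,
                   colClasses = c(habitat_code = "character"))
  gl <- lapply(md$strain_id, function(sid) {
    ingestGenome(file.path(dir, paste0(sid, ".faa")),
                 file.path(dir, paste0(sid, ".gff3")), strain = sid)
  })
  truthPath <- file.path(dir, "truth.json")
  truth <- if (file.exists(truthPath)) {
    read_json(truthPath, simplifyVector = FALSE)
  } else list()
  GenomeCohort(gl, md, truth)
}

#' Read a reference database FASTA
#'
#' Family labels are parsed from ids of the form \code{ref|<family>|<i>}.
#'
#' @param path FASTA path.
#' @return A \code{\link{ReferenceDB}}.
#' @export
readReferenceFasta <- function(path) {
  seqs <- readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  fam <- vapply(strsplit(names(seqs), "|", fixed = TRUE), `[`,
                character(1), 2L)
  ReferenceDB(seqs, fam)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full profiling pipeline
#'
#' Executes, in order: cohort generation/ingest, reference-database
#' generation/load, candidate screening + neighborhood clustering +
#' scattered confirmation, ortholog clustering of the arsenic candidates,
#' ars operon-form census, core-gene detection (high-stringency all-vs-all
#' + MCL + single-copy filter), per-gene alignment, concatenation and
#' bootstrapped NJ tree, distribution matrix (flagged, tree-ordered,
#' heatmap), and habitat statistics. Every intermediate is written to
#' \code{config$outDir}; a manifest (seeds, parameters, stage counts,
#' wall-clock, output checksums) is returned and written as JSON.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @return Invisibly, a list with \code{manifest} plus the in-memory stage
#'   results (\code{cohort}, \code{db}, \code{annotations},
#'   \code{clusters}, \code{orthologs}, \code{census}, \code{tree},
#'   \code{core}, \code{tally}, \code{matrix}, \code{habitat}).
#' @export
runPipeline <- function(config = pipelineConfig()) {
  t0 <- Sys.time()
  outDir <- config$outDir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  cohort <- .stage("cohort", {
    if (is.null(config$cohortDir)) {
      co <- generateCohort(defaultCohortPlans(),
                           seed = deriveSeed(config$seed, 1L),
                           ancestorSeed = config$seed)
      writeCohort(co, file.path(outDir, "cohort"))
      co
    } else {
      readCohort(config$cohortDir)
    }
  })
  db <- .stage("reference_db", {
    if (is.null(config$refDbFasta)) {
      db <- generateReferenceDB(seed = deriveSeed(config$seed, 2L),
                                ancestorSeed = config$seed)
      writeXStringSet(proteins(db), file.path(outDir, "reference_db.faa"))
      db
    } else {
      readReferenceFasta(config$refDbFasta)
    }
  })
  annRes <- .stage("annotation", {
    annotateCohort(cohort, db, t = config$screenThresholds,
                   scheme = config$scheme, p = config$neighborhood)
  })
  writeAnnotationTsv(annRes$annotations,
                     file.path(outDir, "annotations.tsv"))
  writeClustersTsv(annRes$clusters, file.path(outDir, "clusters.tsv"))

  conf <- annRes$annotations[annRes$annotations$status %in%
                               c("clustered", "scattered_confirmed"), ,
                             drop = FALSE]
  orthologs <- .stage("orthologs", {
    if (nrow(conf) >= 2L) {
      g <- allVsAll(cohort, t = config$screenThresholds,
                    scheme = config$scheme,
                    proteinIds = conf$protein_id)
      clusterOrthologs(g, inflation = config$inflation)
    } else list()
  })
  census <- .stage("form_census", censusForms(annRes$clusters, "ars"))
  writeCensusTsv(census, file.path(outDir, "form_census.tsv"))

  coreTree <- .stage("core_phylogeny", {
    gAll <- allVsAll(cohort, t = config$coreThresholds,
                     scheme = config$scheme,
                     minSharedKmers = config$coreMinSharedKmers)
    ogAll <- clusterOrthologs(gAll, inflation = config$inflation)
    core <- findSingleCopyCore(ogAll, cohort)
    if (length(core$groups) == 0L) stop("no single-copy core genes found")
    seqsAll <- do.call(c, unname(lapply(genomes(cohort), proteins)))
    alns <- lapply(core$groups, function(gr) {
      s <- setNames(as.character(seqsAll[gr$members$protein_id]),
                    gr$members$genome)
      progressiveAlign(s, scheme = config$scheme)
    })
    names(alns) <- vapply(core$groups, `[[`, character(1), "group_id")
    sm <- concatenateAlignments(alns)
    writeSuperMatrix(sm, file.path(outDir, "supermatrix"))
    tree <- buildTree(sm, nBootstrap = config$nBootstrap,
                      seed = deriveSeed(config$seed, 3L))
    ape::write.tree(tree, file.path(outDir, "core_tree.nwk"))
    list(tree = tree, core = core, sm = sm)
  })
  tally <- .stage("tally", countByPathway(annRes$annotations, cohort))
  write_json(list(pathway_counts = as.list(tally$pathway_counts),
                  grand_total = grandTotal(tally),
                  n_genomes = tally$n_genomes,
                  n_clustered = tally$n_clustered,
                  clustered_pct = clusteredPct(tally)),
             file.path(outDir, "tally.json"), auto_unbox = TRUE)
  dm <- .stage("distribution", {
    dm <- buildMatrix(annRes$annotations, annRes$clusters, cohort)
    dm <- flagOutliers(dm)
    dm <- orderByTree(dm, coreTree$tree)
    renderHeatmap(dm, file.path(outDir, "heatmap.png"))
    dm
  })
  habitat <- .stage("habitat", {
    md <- as.data.frame(cohortMetadata(cohort))
    gs <- summarizeByGroup(tally, md)
    corr <- tryCatch(
      pearsonR(md$genome_size_bp[match(names(tally$per_genome),
                                       md$strain_id)],
               as.numeric(tally$per_genome)),
      error = function(e) list(r = NA_real_, p = NA_real_))
    scatterByGroup(tally, md, file.path(outDir, "habitat_scatter.png"),
                   seed = deriveSeed(config$seed, 4L))
    list(summary = gs, size_correlation = corr)
  })
  textOutputs <- sort(setdiff(
    list.files(outDir, recursive = TRUE),
    grep("\\.png$|manifest\\.json$",
         list.files(outDir, recursive = TRUE), value = TRUE)))
  manifest <- list(
    package_version = as.character(utils::packageVersion("arsenome")),
    seed = config$seed,
    parameters = list(
      screen = unclass(config$screenThresholds),
      core = unclass(config$coreThresholds),
      neighborhood = unclass(config$neighborhood),
      inflation = config$inflation,
      n_bootstrap = config$nBootstrap),
    counts = list(
      n_genomes = length(cohort),
      n_proteins = sum(vapply(genomes(cohort),
                              function(g) length(proteins(g)), integer(1))),
      n_screened = nrow(annRes$annotations),
      n_confirmed = nrow(conf),
      n_clustered = sum(annRes$annotations$status == "clustered"),
      n_scattered_confirmed =
        sum(annRes$annotations$status == "scattered_confirmed"),
      n_rejected = sum(annRes$annotations$status == "rejected"),
      n_ortholog_groups = length(orthologs),
      n_operons = census$total,
      n_forms = census$n_forms,
      n_core_genes = length(coreTree$core$groups),
      grand_total = grandTotal(tally)),
    habitat = list(host_mean = habitat$summary$host_mean,
                   env_mean = habitat$summary$env_mean,
                   size_correlation_r = habitat$size_correlation$r,
                   size_correlation_p = habitat$size_correlation$p),
    checksums = as.list(tools::md5sum(file.path(outDir, textOutputs))),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  names(manifest$checksums) <- textOutputs
  write_json(manifest, file.path(outDir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(
    manifest = manifest,
    cohort = cohort, db = db, annotations = annRes$annotations,
    clusters = annRes$clusters, orthologs = orthologs, census = census,
    tree = coreTree$tree, core = coreTree$core, tally = tally,
    matrix = dm, habitat = habitat))
}

#' Write a supermatrix as relaxed PHYLIP + FASTA + partition map
#'
#' @param sm A \code{\link{concatenateAlignments}} supermatrix.
#' @param stem Output path stem (writes \code{<stem>.phy},
#'   \code{<stem>.fasta}, \code{<stem>.partitions.tsv}).
#' @return \code{stem}, invisibly.
#' @export
writeSuperMatrix <- function(sm, stem) {
  phy <- c(paste(length(sm$rows), nchar(sm$rows[[1L]])),
           paste(format(names(sm$rows), width = 12), sm$rows))
  writeLines(phy, paste0(stem, ".phy"))
  writeXStringSet(AAStringSet(sm$rows), paste0(stem, ".fasta"))
  write.table(sm$partitions, paste0(stem, ".partitions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(stem)
}
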