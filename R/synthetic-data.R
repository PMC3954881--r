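#' @importFrom jsonlite write_json read_json
NULL

# Deterministic per-family ancestor proteins. Every exemplar, planted gene
# and near-miss decoy is a mutated copy of its family ancestor, so
# within-family similarity is controlled while cross-family similarity is
# that of unrelated random proteins.
.familyAncestors <- function(ancestorSeed = 1L) {
  fams <- names(arsenicFamilies())
  withSeed(deriveSeed(ancestorSeed, 101L), {
    lens <- sample(150:450, length(fams), replace = TRUE)
    setNames(vapply(lens, randomProtein, character(1)), fams)
  })
}

# Ancestors for the phosphate-transporter (pstSCAB) context genes planted
# next to aio operons; non-arsenic, but conserved across strains.
.pstAncestors <- function(ancestorSeed = 1L) {
  labs <- c("pstS", "pstC", "pstA", "pstB")
  withSeed(deriveSeed(ancestorSeed, 102L), {
    lens <- sample(200:350, length(labs), replace = TRUE)
    setNames(vapply(lens, randomProtein, character(1)), labs)
  })
}

# Ancestors for the universal single-copy core genes, one per id.
.coreAncestors <- function(coreIds, ancestorSeed = 1L) {
  coreIds <- sort(unique(coreIds))
  withSeed(deriveSeed(ancestorSeed, 103L), {
    lens <- sample(200:400, length(coreIds), replace = TRUE)
    setNames(vapply(lens, randomProtein, character(1)), coreIds)
  })
}

#' Mutate a protein to a target global identity
#'
#' Substitutes a fixed number of positions (each to a different residue,
#' chosen uniformly) so that the Hamming identity between input and output
#' equals \code{targetIdentity} up to rounding; length is preserved.
#'
#' @param seq Protein string of length >= 10.
#' @param targetIdentity Fraction in (0, 1].
#' @param seed Optional integer seed; \code{NULL} uses the current RNG
#'   stream (for callers that manage seeding themselves).
#' @return Mutated protein string.
#' @examples
#' mutateProtein("MKTAYIAKQRQISFVK", 0.75, seed = 1)
#' @export
mutateProtein <- function(seq, targetIdentity, seed = NULL) {
  checkProtein(seq)
  if (nchar(seq) < 10L) {
    stop("sequence too short to mutate (length ", nchar(seq), " < 10)")
  }
  if (targetIdentity <= 0 || targetIdentity > 1) {
    stop("targetIdentity must be in (0, 1]")
  }
  doit <- function() {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    nmut <- round((1 - targetIdentity) * length(chars))
    if (nmut == 0L) return(seq)
    pos <- sample(length(chars), nmut)
    for (p in pos) {
      chars[p] <- sample(setdiff(AA_ALPHABET20, chars[p]), 1L)
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) doit() else withSeed(seed, doit())
}

#' Generate a curated reference protein database
#'
#' Emits \code{nPerFamily} exemplar proteins per gene family, each a mutated
#' copy (85-90\% identity) of a deterministic family ancestor, so exemplars
#' of one family are mutually >= 70\% identical while different families are
#' unrelated random sequences (far below the 35\% screen).
#'
#' @param families Character vector of family names (default: all 20).
#' @param nPerFamily Exemplars per family (>= 1).
#' @param seed Integer seed; identical calls are byte-identical.
#' @param ancestorSeed Seed fixing the family ancestor sequences; a cohort
#'   generated with the same \code{ancestorSeed} carries planted genes
#'   homologous to this database.
#' @return A \code{\link{ReferenceDB}}.
#' @examples
#' db <- generateReferenceDB(nPerFamily = 2, seed = 1)
#' @export
generateReferenceDB <- function(families = names(arsenicFamilies()),
                                nPerFamily = 3L, seed = 1L,
                                ancestorSeed = 1L) {
  stopifnot(nPerFamily >= 1L)
  bad <- setdiff(families, names(arsenicFamilies()))
  if (length(bad)) {
    stop("unknown gene family: ", paste(bad, collapse = ", "))
  }
  anc <- .familyAncestors(ancestorSeed)
  withSeed(deriveSeed(seed, 201L), {
    seqs <- character(0)
    fam <- character(0)
    for (f in families) {
      for (i in seq_len(nPerFamily)) {
        target <- runif(1, 0.85, 0.90)
        seqs <- c(seqs, setNames(mutateProtein(anc[[f]], target),
                                 paste0("ref|", f, "|", i)))
        fam <- c(fam, f)
      }
    }
    ReferenceDB(seqs, fam)
  })
}

#' Specify one synthetic genome
#'
#' A plan describes what \code{\link{generateCohort}} plants in one strain:
#' operon-organized clusters of arsenic gene families, scattered single
#' family members, universal single-copy core genes, random background
#' genes, decoys, and optional near-miss decoys (family members mutated to
#' ~25\% identity, below the screen).
#'
#' @param strainId Unique strain identifier.
#' @param habitat Habitat code: H (human), P (plant), Z (animal),
#'   R (rhizosphere), S (soil), D (sediment), W (wastewater), E
#'   (endosymbiont), U (miscellaneous) or "NA" (unknown).
#' @param arsenicRich Flag: strain isolated from an arsenic-rich niche.
#' @param nContigs Number of contigs (draft genomes have > 1).
#' @param nBackground Random background genes.
#' @param clusters List of planted clusters; each is either a character
#'   vector of family names (gene order; all plus strand) or a list with
#'   \code{form} (family names), optional \code{strands} (per-gene
#'   \code{"+"}/\code{"-"}) and optional \code{contextAfter} (labelled
#'   non-arsenic genes, e.g. \code{c("pstS","pstC","pstA","pstB")}, placed
#'   immediately downstream).
#' @param scattered Character vector of family names planted in isolation
#'   (>= 2 non-arsenic genes on each side).
#' @param nDecoys Random decoy genes.
#' @param nNearMiss Near-miss decoys (mutated family members at ~25\%
#'   identity).
#' @param coreGenes Core gene ids (one copy each is planted).
#' @return A \code{GenomePlan} (list).
#' @export
genomePlan <- function(strainId, habitat = "U", arsenicRich = FALSE,
                       nContigs = 1L, nBackground = 30L,
                       clusters = list(), scattered = character(0),
                       nDecoys = 0L, nNearMiss = 0L,
                       coreGenes = character(0)) {
  if (!habitat %in% HABITAT_CODES) {
    stop("invalid habitat code '", habitat, "'")
  }
  stopifnot(nContigs >= 1L, nBackground >= 0L, nDecoys >= 0L, nNearMiss >= 0L)
  clusters <- lapply(clusters, function(cl) {
    if (is.character(cl)) cl <- list(form = cl)
    if (is.null(cl$strands)) cl$strands <- rep("+", length(cl$form))
    if (length(cl$strands) != length(cl$form)) {
      stop("strand layout length must match cluster form length")
    }
    if (length(cl$form) < 2L) stop("a planted cluster needs >= 2 genes")
    cl
  })
  fams <- unlist(c(lapply(clusters, `[[`, "form"), scattered))
  bad <- setdiff(fams, names(arsenicFamilies()))
  if (length(bad)) stop("unknown gene family: ", paste(bad, collapse = ", "))
  structure(list(strainId = strainId, habitat = habitat,
                 arsenicRich = arsenicRich, nContigs = as.integer(nContigs),
                 nBackground = as.integer(nBackground), clusters = clusters,
                 scattered = scattered, nDecoys = as.integer(nDecoys),
                 nNearMiss = as.integer(nNearMiss), coreGenes = coreGenes),
            class = "GenomePlan")
}

# Greedily pick k insertion slots from `range` (inclusive bounds), all
# pairwise >= 2 apart and >= 2 away from `taken`; errors if impossible.
.pickSlots <- function(k, lo, hi, taken = integer(0)) {
  if (k == 0L) return(integer(0))
  cand <- sample(seq(lo, hi))
  chosen <- integer(0)
  for (p in cand) {
    if (all(abs(p - c(chosen, taken)) >= 2L)) {
      chosen <- c(chosen, p)
      if (length(chosen) == k) return(sort(chosen))
    }
  }
  stop("not enough background genes to separate planted features; ",
       "increase nBackground")
}

# Cheap post-generation screen: a freshly drawn random protein is rejected
# (and redrawn) if it shares any 8-mer with a family/core/pst ancestor --
# long exact word matches are the only way an unrelated random sequence
# could approach the similarity screen.
.cleanRandomProtein <- function(len, ancestorKmers) {
  repeat {
    s <- randomProtein(len)
    if (!any(proteinKmers(s, 8L) %in% ancestorKmers)) return(s)
  }
}

#' Generate a synthetic annotated-genome cohort with ground truth
#'
#' Emits one \code{\link{AnnotatedGenome}} per plan. Planted clusters are
#' consecutive CDS features on one contig; scattered genes have at least two
#' non-arsenic genes on each side (and never sit within one gene of another
#' arsenic gene, so neighborhood detection cannot merge them); every strain
#' carries exactly one copy of each core gene at ~85\% identity to a shared
#' ancestor (>= 70\% between strains); background and decoy genes are random
#' proteins guaranteed free of long word matches to any ancestor.
#' Coordinates are 1-based inclusive GFF3 convention with intergenic gaps of
#' 50-500 bp.
#'
#' @param plans List of \code{\link{genomePlan}}s with unique strain ids.
#' @param seed Integer seed; output is fully deterministic.
#' @param ancestorSeed Must match the \code{ancestorSeed} of the
#'   \code{\link{generateReferenceDB}} used for screening.
#' @return A \code{\link{GenomeCohort}} whose \code{truthTable} records, per
#'   strain: per-family planted counts, planted clusters (members and
#'   canonical form), scattered genes, the core-gene identity map, and
#'   near-miss decoy ids.
#' @export
generateCohort <- function(plans, seed = 1L, ancestorSeed = 1L) {
  ids <- vapply(plans, `[[`, character(1), "strainId")
  if (anyDuplicated(ids)) {
    stop("duplicate strain_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  famAnc <- .familyAncestors(ancestorSeed)
  pstAnc <- .pstAncestors(ancestorSeed)
  coreAnc <- .coreAncestors(unlist(lapply(plans, `[[`, "coreGenes")),
                            ancestorSeed)
  ancKmers <- unique(unlist(lapply(c(famAnc, pstAnc, coreAnc),
                                   proteinKmers, k = 8L)))
  genomesList <- vector("list", length(plans))
  truth <- vector("list", length(plans))
  names(truth) <- ids
  for (gi in seq_along(plans)) {
    plan <- plans[[gi]]
    res <- withSeed(deriveSeed(seed, 300L + gi), {
      .emitGenome(plan, famAnc, pstAnc, coreAnc, ancKmers)
    })
    genomesList[[gi]] <- res$genome
    truth[[plan$strainId]] <- res$truth
  }
  meta <- DataFrame(
    strain_id = ids,
    habitat_code = vapply(plans, `[[`, character(1), "habitat"),
    genome_size_bp = vapply(genomesList, function(g) {
      f <- genomeFeatures(g)
      sum(vapply(split(end(f), as.character(seqnames(f))),
                 max, numeric(1))) + 500
    }, numeric(1)),
    arsenic_rich = vapply(plans, `[[`, logical(1), "arsenicRich"))
  GenomeCohort(genomesList, meta, truth)
}

# Build one genome from its plan; RNG stream already seeded by the caller.
.emitGenome <- function(plan, famAnc, pstAnc, coreAnc, ancKmers) {
  sid <- plan$strainId
  # --- non-arsenic gene pool, shuffled ---
  pool <- list()
  for (i in seq_len(plan$nBackground)) {
    pool[[length(pool) + 1L]] <- list(
      seq = .cleanRandomProtein(sample(150:450, 1L), ancKmers),
      label = "background", role = "background")
  }
  for (i in seq_len(plan$nDecoys)) {
    pool[[length(pool) + 1L]] <- list(
      seq = .cleanRandomProtein(sample(150:450, 1L), ancKmers),
      label = "decoy", role = "decoy")
  }
  for (cg in plan$coreGenes) {
    pool[[length(pool) + 1L]] <- list(
      seq = mutateProtein(coreAnc[[cg]], 0.85),
      label = cg, role = "core")
  }
  for (i in seq_len(plan$nNearMiss)) {
    f <- sample(names(famAnc), 1L)
    pool[[length(pool) + 1L]] <- list(
      seq = mutateProtein(famAnc[[f]], 0.25),
      label = paste0("near_miss:", f), role = "near_miss")
  }
  pool <- pool[sample(length(pool))]
  # --- distribute pool over contigs, assign planted features to contigs ---
  nc <- plan$nContigs
  contig_of_pool <- sort(rep_len(seq_len(nc), length(pool)))
  clContig <- rep_len(seq_len(nc), length(plan$clusters))
  scContig <- rep_len(rev(seq_len(nc)), length(plan$scattered))
  contigs <- vector("list", nc)
  for (ci in seq_len(nc)) {
    nonars <- pool[contig_of_pool == ci]
    N <- length(nonars)
    scHere <- which(scContig == ci)
    clHere <- which(clContig == ci)
    if (N < 4L && length(scHere) > 0L) {
      stop("not enough background genes on contig for scattered placement")
    }
    scSlots <- .pickSlots(length(scHere), 2L, max(2L, N - 2L))
    clSlots <- .pickSlots(length(clHere), 0L, N, taken = scSlots)
    ins <- list()  # slot -> list of gene entries
    addAt <- function(slot, genes) {
      key <- as.character(slot)
      ins[[key]] <<- c(ins[[key]], genes)
    }
    for (k in seq_along(scHere)) {
      f <- plan$scattered[scHere[k]]
      addAt(scSlots[k], list(list(
        seq = mutateProtein(famAnc[[f]], 0.75), label = f,
        role = "planted_scattered",
        strand = sample(c("+", "-"), 1L))))
    }
    for (k in seq_along(clHere)) {
      cl <- plan$clusters[[clHere[k]]]
      # minus-strand operons are laid down in reversed coordinate order so
      # that reading in transcription direction recovers the planned form
      if (sum(cl$strands == "-") > sum(cl$strands == "+")) {
        cl$form <- rev(cl$form)
        cl$strands <- rev(cl$strands)
      }
      genes <- lapply(seq_along(cl$form), function(j) {
        list(seq = mutateProtein(famAnc[[cl$form[j]]], 0.75),
             label = cl$form[j], role = "planted_cluster",
             strand = cl$strands[j], cluster_index = clHere[k])
      })
      ctx <- lapply(cl$contextAfter, function(lab) {
        list(seq = mutateProtein(pstAnc[[lab]], 0.80), label = lab,
             role = "context", strand = cl$strands[length(cl$strands)])
      })
      addAt(clSlots[k], c(genes, ctx))
    }
    ordered <- list()
    for (slot in 0:N) {
      key <- as.character(slot)
      if (!is.null(ins[[key]])) ordered <- c(ordered, ins[[key]])
      if (slot < N) ordered <- c(ordered, nonars[slot + 1L])
    }
    contigs[[ci]] <- ordered
  }
  # --- coordinates, ids, containers ---
  seqs <- character(0)
  rows <- list()
  idx <- 0L
  for (ci in seq_len(nc)) {
    pos <- 0L
    for (g in contigs[[ci]]) {
      idx <- idx + 1L
      pid <- paste0(sid, "|g", idx)
      gap <- sample(50:500, 1L)
      st <- pos + gap + 1L
      en <- st + 3L * nchar(g$seq) + 2L
      pos <- en
      strand <- if (!is.null(g$strand)) g$strand else sample(c("+", "-"), 1L)
      rows[[idx]] <- data.frame(
        contig = paste0(sid, "_c", ci), start = st, end = en,
        strand = strand, protein_id = pid, label = g$label, role = g$role,
        cluster_index = if (is.null(g$cluster_index)) NA_integer_
                        else g$cluster_index)
      seqs[pid] <- g$seq
    }
  }
  tab <- do.call(rbind, rows)
  gr <- GRanges(seqnames = tab$contig,
                ranges = IRanges(tab$start, tab$end),
                strand = tab$strand)
  mcols(gr)$protein_id <- tab$protein_id
  mcols(gr)$label <- tab$label
  mcols(gr)$role <- tab$role
  genome <- AnnotatedGenome(sid, gr, AAStringSet(seqs))
  # --- ground truth ---
  famCounts <- setNames(integer(length(arsenicFamilies())),
                        names(arsenicFamilies()))
  planted <- tab$role %in% c("planted_cluster", "planted_scattered")
  tc <- table(tab$label[planted])
  famCounts[names(tc)] <- as.integer(tc)
  trueClusters <- lapply(seq_along(plan$clusters), function(k) {
    sub <- tab[!is.na(tab$cluster_index) & tab$cluster_index == k, ,
               drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    list(contig = sub$contig[1L],
         families = sub$label,
         strands = sub$strand,
         member_ids = sub$protein_id,
         form = canonicalForm(sub$label, sub$strand))
  })
  scatteredTruth <- lapply(which(tab$role == "planted_scattered"),
    function(i) list(family = tab$label[i], protein_id = tab$protein_id[i]))
  coreMap <- setNames(tab$protein_id[tab$role == "core"],
                      tab$label[tab$role == "core"])[plan$coreGenes]
  list(genome = genome,
       truth = list(
         strain_id = sid,
         family_counts = as.list(famCounts),
         clusters = trueClusters,
         scattered = scatteredTruth,
         core_genes = as.list(coreMap),
         near_miss_ids = tab$protein_id[tab$role == "near_miss"],
         n_planted = sum(planted)))
}

#' The default 12-strain study cohort
#'
#' Twelve strains spanning all ten habitat codes, with two arsenic-rich
#' strains (soil and wastewater) carrying more than four times the
#' cohort-average arsenic gene count, several strains with no arsenic genes
#' or only scattered genes, aio operons flanked by the pstSCAB phosphate
#' transporter, a single arrAB strain, and an arsR-arsM cluster -- the gene
#' inventory patterns reported for Burkholderiales at one-sixteenth cohort
#' scale. All strains share ten universal single-copy core genes. The five
#' most frequent ars operon organizations (arsC-acr3, arsR-arsC-acr3,
#' arsR-arsC-acr3-arsH, arsR-glo-arsC-acr3, arsR-arsC-acr3-arsC-arsH) are
#' all planted.
#'
#' @return List of \code{\link{genomePlan}}s for
#'   \code{\link{generateCohort}}.
#' @export
defaultCohortPlans <- function() {
  core <- c("rpoB", "gyrB", "recA", "rpsB", "rplB",
            "infB", "secY", "ftsZ", "dnaK", "tuf")
  pst <- c("pstS", "pstC", "pstA", "pstB")
  list(
    genomePlan("strain01", "H", nBackground = 28,
               clusters = list(c("arsR", "arsC", "acr3")), coreGenes = core),
    genomePlan("strain02", "H", nBackground = 40,
               scattered = "arsC", coreGenes = core),
    genomePlan("strain03", "P", nContigs = 2, nBackground = 30,
               clusters = list(c("arsC", "acr3")), scattered = "arsC",
               coreGenes = core),
    genomePlan("strain04", "Z", nBackground = 55, nDecoys = 2,
               coreGenes = core),
    genomePlan("strain05", "R", nBackground = 26,
               clusters = list(c("arsR", "arsC", "acr3", "arsH")),
               coreGenes = core),
    genomePlan("strain06", "S", arsenicRich = TRUE, nContigs = 2,
               nBackground = 34, nNearMiss = 1,
               clusters = list(
                 c("arsR", "arsC", "acr3"),
                 c("arsR", "glo", "arsC", "acr3"),
                 c("arsR", "arsC", "acr3", "arsC", "arsH"),
                 c("arsC", "acr3"),
                 c("arsD", "arsA", "arsB", "arsC"),
                 list(form = c("aioB", "aioA"), contextAfter = pst),
                 c("aioX", "aioS", "aioR"),
                 c("arsO", "mfs")),
               scattered = c("arsM", "arsC", "arsC", "arsH", "glo"),
               coreGenes = core),
    genomePlan("strain07", "S", nBackground = 35,
               clusters = list(c("arsC", "acr3")), scattered = "glo",
               coreGenes = core),
    genomePlan("strain08", "D", nBackground = 30,
               clusters = list(
                 list(form = c("aioB", "aioA"), contextAfter = pst),
                 c("arsR", "arsC")),
               coreGenes = core),
    genomePlan("strain09", "W", arsenicRich = TRUE, nBackground = 34,
               nNearMiss = 1,
               clusters = list(
                 c("arsC", "acr3"),
                 c("arsR", "arsC", "acr3"),
                 c("arsR", "arsC", "acr3", "arsH"),
                 c("arsR", "glo", "arsC", "acr3"),
                 c("arsD", "arsA", "arsB", "arsC"),
                 list(form = c("aioB", "aioA"),
                      strands = c("-", "-"), contextAfter = pst),
                 c("aioC", "aioD"),
                 c("arsR", "arsC", "acr3", "arsC", "arsH")),
               scattered = c("arsC", "acr3", "arsC", "arsH"),
               coreGenes = core),
    genomePlan("strain10", "E", nBackground = 45, scattered = "arsC",
               coreGenes = core),
    genomePlan("strain11", "U", nBackground = 24,
               clusters = list(list(form = c("arsR", "arsC", "acr3"),
                                    strands = c("-", "-", "-"))),
               coreGenes = core),
    genomePlan("strain12", "NA", nBackground = 30,
               clusters = list(c("arrA", "arrB"), c("arsR", "arsM")),
               coreGenes = core)
  )
}

#' Write a cohort to disk in standard formats
#'
#' Per strain: \code{<strain>.faa} (protein FASTA) and \code{<strain>.gff3}
#' (CDS features; column 9 carries \code{ID}, and \code{family}/\code{role}
#' ground-truth attributes for synthetic cohorts). Plus cohort-level
#' \code{metadata.tsv} and, if truth is present, \code{truth.json}.
#'
#' @param cohort A \code{\link{GenomeCohort}}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in genomes(cohort)) {
    sid <- strainId(g)
    writeXStringSet(proteins(g), file.path(dir, paste0(sid, ".faa")))
    f <- genomeFeatures(g)
    mcols(f)$type <- "CDS"
    mcols(f)$ID <- mcols(f)$protein_id
    mcols(f)$source <- "arsenome"
    mcols(f)$phase <- 0L
    rtracklayer::export(f, file.path(dir, paste0(sid, ".gff3")),
                        format = "gff3")
  }
  md <- as.data.frame(cohortMetadata(cohort))
  write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (length(truthTable(cohort)) > 0L) {
    write_json(truthTable(cohort), file.path(dir, "truth.json"),
               auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}

#' Precision and recall of annotation calls against planted truth
#'
#' A call is a (protein id, family) pair from the confirmed annotations;
#' truth is the set of planted cluster members and scattered genes with
#' their planted families. Near-miss decoys and background genes are true
#' negatives.
#'
#' @param annotations Confirmed annotation table (see
#'   \code{\link{annotateCohort}}).
#' @param cohort Synthetic \code{\link{GenomeCohort}} carrying truth.
#' @return List with \code{precision}, \code{recall}, \code{n_called},
#'   \code{n_true}.
#' @export
scoreRecovery <- function(annotations, cohort) {
  truth <- truthTable(cohort)
  if (length(truth) == 0L) stop("cohort carries no ground truth")
  truePairs <- unlist(lapply(truth, function(tr) {
    c(unlist(lapply(tr$clusters, function(cl) {
        paste(cl$member_ids, cl$families)
      })),
      vapply(tr$scattered, function(s) paste(s$protein_id, s$family),
             character(1)))
  }), use.names = FALSE)
  called <- annotations[annotations$status %in%
                          c("clustered", "scattered_confirmed"), ,
                        drop = FALSE]
  calledPairs <- paste(called$protein_id, called$family)
  tp <- sum(calledPairs %in% truePairs)
  list(precision = if (length(calledPairs)) tp / length(calledPairs) else NA,
       recall = if (length(truePairs)) tp / length(truePairs) else NA,
       n_called = length(calledPairs), n_true = length(truePairs))
}
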