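#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom GenomicRanges GRanges seqnames strand start end
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet
#' @importFrom S4Vectors DataFrame mcols mcols<- Rle
#' @importFrom IRanges IRanges
#' @importFrom BiocGenerics width
NULL

#' AnnotatedGenome: one annotated bacterial genome
#'
#' Holds the ordered protein-coding gene features of one strain (as a
#' \code{GRanges} with 1-based inclusive coordinates, contig as seqname) and
#' the corresponding protein sequences (as an \code{AAStringSet} named by
#' protein id). Feature metadata columns: \code{protein_id}, and optionally
#' \code{label} (ground-truth or product label) and \code{role}.
#'
#' @slot strainId Single strain identifier.
#' @slot features \code{GRanges} of CDS features, sorted by (contig, start).
#' @slot proteins \code{AAStringSet}, one entry per feature.
#' @export
setClass("AnnotatedGenome",
  representation(strainId = "character",
                 features = "GRanges",
                 proteins = "AAStringSet"))

setValidity("AnnotatedGenome", function(object) {
  msgs <- character(0)
  if (length(object@strainId) != 1L || !nzchar(object@strainId)) {
    msgs <- c(msgs, "strainId must be a single non-empty string")
  }
  ids <- mcols(object@features)$protein_id
  if (is.null(ids)) {
    msgs <- c(msgs, "features must carry a protein_id metadata column")
  } else {
    if (anyDuplicated(ids)) msgs <- c(msgs, "duplicate protein_id in features")
    if (!setequal(ids, names(object@proteins)) ||
        length(ids) != length(object@proteins)) {
      msgs <- c(msgs, "feature protein_ids and protein names must match 1:1")
    }
  }
  if (length(object@features) > 0L) {
    o <- order(as.character(seqnames(object@features)),
               start(object@features))
    if (!identical(o, seq_along(object@features))) {
      msgs <- c(msgs, "features must be sorted by (contig, start)")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct an AnnotatedGenome
#'
#' @param strainId Strain identifier.
#' @param features \code{GRanges} with a \code{protein_id} metadata column.
#' @param proteins \code{AAStringSet} named by protein id.
#' @return An \code{AnnotatedGenome}.
#' @export
AnnotatedGenome <- function(strainId, features, proteins) {
  o <- order(as.character(seqnames(features)), start(features))
  features <- features[o]
  proteins <- proteins[mcols(features)$protein_id]
  new("AnnotatedGenome", strainId = strainId, features = features,
      proteins = proteins)
}

#' @describeIn AnnotatedGenome strain identifier
#' @param x,object An \code{AnnotatedGenome}.
#' @export
setGeneric("strainId", function(x) standardGeneric("strainId"))

#' @export
setMethod("strainId", "AnnotatedGenome", function(x) x@strainId)

#' @describeIn AnnotatedGenome gene features as GRanges
#' @export
setGeneric("genomeFeatures", function(x) standardGeneric("genomeFeatures"))

#' @export
setMethod("genomeFeatures", "AnnotatedGenome", function(x) x@features)

#' @describeIn AnnotatedGenome protein sequences as AAStringSet
#' @export
setGeneric("proteins", function(x) standardGeneric("proteins"))

#' @export
setMethod("proteins", "AnnotatedGenome", function(x) x@proteins)

setMethod("show", "AnnotatedGenome", function(object) {
  cat("AnnotatedGenome '", object@strainId, "': ",
      length(object@features), " genes on ",
      length(unique(as.character(seqnames(object@features)))),
      " contig(s)\n", sep = "")
})

#' GenomeCohort: a set of annotated genomes with strain metadata
#'
#' @slot genomes Named list of \code{AnnotatedGenome} (names = strain ids).
#' @slot metadata \code{DataFrame} with columns \code{strain_id},
#'   \code{habitat_code}, \code{genome_size_bp}, \code{arsenic_rich}.
#' @slot truth List of per-strain ground truth (empty for real cohorts).
#' @export
setClass("GenomeCohort",
  representation(genomes = "list", metadata = "DataFrame", truth = "list"))

setValidity("GenomeCohort", function(object) {
  msgs <- character(0)
  ids <- vapply(object@genomes, strainId, character(1))
  if (anyDuplicated(ids)) msgs <- c(msgs, "duplicate strain_id in cohort")
  if (!identical(names(object@genomes), unname(ids))) {
    msgs <- c(msgs, "genome list names must equal strain ids")
  }
  need <- c("strain_id", "habitat_code", "genome_size_bp", "arsenic_rich")
  if (!all(need %in% colnames(object@metadata))) {
    msgs <- c(msgs, paste("metadata must have columns:",
                          paste(need, collapse = ", ")))
  } else {
    if (!setequal(object@metadata$strain_id, ids)) {
      msgs <- c(msgs, "metadata strain_ids must match genomes")
    }
    badhab <- setdiff(object@metadata$habitat_code, HABITAT_CODES)
    if (length(badhab)) {
      msgs <- c(msgs, paste("invalid habitat code(s):",
                            paste(badhab, collapse = ", ")))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenomeCohort
#'
#' @param genomes List of \code{AnnotatedGenome}.
#' @param metadata \code{data.frame} or \code{DataFrame} of strain metadata
#'   (\code{strain_id}, \code{habitat_code}, \code{genome_size_bp},
#'   \code{arsenic_rich}).
#' @param truth Optional per-strain ground-truth list.
#' @return A \code{GenomeCohort}.
#' @export
GenomeCohort <- function(genomes, metadata, truth = list()) {
  ids <- vapply(genomes, strainId, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate strain_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(genomes) <- ids
  metadata <- DataFrame(metadata)
  metadata <- metadata[match(ids, metadata$strain_id), , drop = FALSE]
  new("GenomeCohort", genomes = genomes, metadata = metadata, truth = truth)
}

#' @describeIn GenomeCohort list of member genomes
#' @param x,object A \code{GenomeCohort}.
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))

#' @export
setMethod("genomes", "GenomeCohort", function(x) x@genomes)

#' @describeIn GenomeCohort strain metadata table
#' @export
setGeneric("cohortMetadata", function(x) standardGeneric("cohortMetadata"))

#' @export
setMethod("cohortMetadata", "GenomeCohort", function(x) x@metadata)

#' @describeIn GenomeCohort planted ground truth (synthetic cohorts)
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' @export
setMethod("truthTable", "GenomeCohort", function(x) x@truth)

#' @export
setMethod("length", "GenomeCohort", function(x) length(x@genomes))

setMethod("show", "GenomeCohort", function(object) {
  cat("GenomeCohort of", length(object@genomes), "genomes;",
      sum(vapply(object@genomes,
                 function(g) length(genomeFeatures(g)), integer(1))),
      "genes total\n")
})

#' ReferenceDB: curated exemplar proteins for the screened gene families
#'
#' @slot proteins \code{AAStringSet} of exemplar proteins.
#' @slot family Character vector, one family label per protein.
#' @export
setClass("ReferenceDB",
  representation(proteins = "AAStringSet", family = "character"))

setValidity("ReferenceDB", function(object) {
  msgs <- character(0)
  if (length(object@proteins) != length(object@family)) {
    msgs <- c(msgs, "one family label per protein required")
  }
  bad <- setdiff(object@family, names(arsenicFamilies()))
  if (length(bad)) {
    msgs <- c(msgs, paste("unknown gene family:",
                          paste(unique(bad), collapse = ", ")))
  }
  if (anyDuplicated(names(object@proteins))) {
    msgs <- c(msgs, "duplicate reference protein ids")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a ReferenceDB
#'
#' @param proteins Named \code{AAStringSet} (or named character vector).
#' @param family Character vector of family labels, one per protein.
#' @return A \code{ReferenceDB}.
#' @export
ReferenceDB <- function(proteins, family) {
  if (is.character(proteins)) proteins <- AAStringSet(proteins)
  new("ReferenceDB", proteins = proteins, family = family)
}

#' @export
setMethod("proteins", "ReferenceDB", function(x) x@proteins)

#' @describeIn ReferenceDB family label of each exemplar
#' @param x,object A \code{ReferenceDB}.
#' @export
setGeneric("refFamily", function(x) standardGeneric("refFamily"))

#' @export
setMethod("refFamily", "ReferenceDB", function(x) x@family)

#' @export
setMethod("length", "ReferenceDB", function(x) length(x@proteins))

setMethod("show", "ReferenceDB", function(object) {
  cat("ReferenceDB:", length(object@proteins), "exemplar proteins,",
      length(unique(object@family)), "gene families\n")
})

#' DistributionMatrix: strains x gene-family count matrix
#'
#' Rows are strains (ordered by the core-gene phylogeny after
#' \code{\link{orderByTree}}), columns the configured gene families plus one
#' \code{ars_clusters} column counting ars-like clusters per strain.
#'
#' @slot counts Integer matrix.
#' @slot flags Per-strain flag: \code{none}, \code{2x} or \code{4x}
#'   (at least two/four times the cohort-average gene total).
#' @export
setClass("DistributionMatrix",
  representation(counts = "matrix", flags = "character"))

setValidity("DistributionMatrix", function(object) {
  msgs <- character(0)
  if (any(object@counts < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (length(object@flags) != nrow(object@counts)) {
    msgs <- c(msgs, "one flag per strain row required")
  }
  if (!all(object@flags %in% c("none", "2x", "4x"))) {
    msgs <- c(msgs, "flags must be one of none/2x/4x")
  }
  if (length(msgs)) msgs else TRUE
})

#' @describeIn DistributionMatrix the count matrix
#' @param x,object A \code{DistributionMatrix}.
#' @export
setGeneric("distCounts", function(x) standardGeneric("distCounts"))

#' @export
setMethod("distCounts", "DistributionMatrix", function(x) x@counts)

#' @describeIn DistributionMatrix per-strain outlier flags
#' @export
setGeneric("strainFlags", function(x) standardGeneric("strainFlags"))

#' @export
setMethod("strainFlags", "DistributionMatrix", function(x) x@flags)

setMethod("show", "DistributionMatrix", function(object) {
  cat("DistributionMatrix:", nrow(object@counts), "strains x",
      ncol(object@counts), "columns;",
      sum(object@flags != "none"), "flagged strain(s)\n")
})
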