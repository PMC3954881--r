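#' @import methods
#' @importFrom stats median setNames cor.test runif rnorm
#' @importFrom utils write.table read.table head tail
NULL

# The 20 standard amino acids; X is tolerated on input as an unknown residue.
AA_ALPHABET20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Gene families of the four arsenic pathways
#'
#' The 20 curated gene families screened by the pipeline, mapped to their
#' pathway: \code{ars} (cytoplasmic As(V) reduction / resistance operon),
#' \code{arr} (respiratory As(V) reduction), \code{aio} (As(III) oxidation)
#' and \code{arsM} (As(III) methylation).
#'
#' @return Named character vector; names are family names (e.g. \code{arsC},
#'   \code{acr3}), values are pathway labels.
#' @examples
#' arsenicFamilies()
#' @export
arsenicFamilies <- function() {
  c(arsR = "ars", arsB = "ars", arsC = "ars", arsH = "ars", acr3 = "ars",
    arsA = "ars", arsD = "ars", arsO = "ars", glo = "ars", mfs = "ars",
    arrA = "arr", arrB = "arr",
    aioA = "aio", aioB = "aio", aioX = "aio", aioS = "aio", aioR = "aio",
    aioC = "aio", aioD = "aio",
    arsM = "arsM")
}

#' Pathway of one or more gene families
#'
#' @param family Character vector of family names.
#' @return Character vector of pathway labels (\code{ars}, \code{arr},
#'   \code{aio} or \code{arsM}).
#' @export
familyPathway <- function(family) {
  fam <- arsenicFamilies()
  bad <- setdiff(family, names(fam))
  if (length(bad) > 0L) {
    stop("unknown gene family: ", paste(unique(bad), collapse = ", "))
  }
  unname(fam[family])
}

# Habitat codes used in strain metadata: human host (H), plant pathogen (P),
# animal host (Z), rhizosphere/root nodule (R), soil (S), sediment (D),
# wastewater/sludge (W), endosymbiont (E), miscellaneous (U), unknown (NA).
HABITAT_CODES <- c("H", "P", "Z", "R", "S", "D", "W", "E", "U", "NA")

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a per-stage seed from a master seed, kept inside 32-bit range.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% .Machine$integer.max)
}

# Round half away from zero (so 71.15 -> 71.2), unlike base round()'s
# banker's rounding; used for the reported one-decimal percentages.
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Validate a protein string: non-empty, 20 amino acids plus X.
checkProtein <- function(seq, what = "sequence") {
  if (length(seq) != 1L || is.na(seq) || !nzchar(seq)) {
    stop(what, " must be a non-empty protein string")
  }
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  ok <- chars %in% c(AA_ALPHABET20, "X")
  if (!all(ok)) {
    pos <- which(!ok)[1L]
    stop("invalid amino-acid character '", chars[pos], "' at position ", pos,
         " of ", what)
  }
  invisible(seq)
}

# All overlapping k-mers of a protein string.
proteinKmers <- function(seq, k = 4L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

randomProtein <- function(len) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}
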