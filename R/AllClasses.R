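#' Design parameters for the exon-array pipeline
#'
#' One home for every numeric threshold the design uses: the minimum read
#' length kept after cleaning (100 bp), the maximum tolerated fraction of
#' undetermined bases (3\%), the unconditional end trim (60 bp per end), the
#' minimum consensus exon length (60 bp), the length below which an exonic
#' region is score-penalised (100 bp), the minimum ORF length for EST strand
#' inference (150 bp), the redundancy identity threshold (98\%), the maximal
#' tolerated repeat overlap (25\%), and the probes-per-exon / probe-length
#' targets (4 x 25-mer).
#'
#' @slot minReadLen integer, reads shorter than this are removed.
#' @slot maxAmbiguityFrac numeric, reads with strictly more than this
#'   fraction of non-ACGT bases are removed.
#' @slot endTrim integer, bases trimmed from each read end.
#' @slot minExonLen integer, consensus regions shorter than this are dropped.
#' @slot shortExonPenaltyLen integer, regions shorter than this are
#'   score-penalised.
#' @slot minOrfLen integer, minimum ORF length (stop codon included).
#' @slot redundancyIdentity numeric, identity at or above which two
#'   candidates are redundant.
#' @slot maxRepeatOverlapFrac numeric, regions overlapping repeats by
#'   strictly more than this fraction are filtered.
#' @slot probesPerExon integer, probes selected per exon candidate.
#' @slot probeLen integer, probe length.
#' @export
setClass("DesignParams", representation(
  minReadLen = "integer",
  maxAmbiguityFrac = "numeric",
  endTrim = "integer",
  minExonLen = "integer",
  shortExonPenaltyLen = "integer",
  minOrfLen = "integer",
  redundancyIdentity = "numeric",
  maxRepeatOverlapFrac = "numeric",
  probesPerExon = "integer",
  probeLen = "integer"
))

setValidity("DesignParams", function(object) {
  lens <- c(minReadLen = object@minReadLen, endTrim = object@endTrim,
            minExonLen = object@minExonLen,
            shortExonPenaltyLen = object@shortExonPenaltyLen,
            minOrfLen = object@minOrfLen, probeLen = object@probeLen)
  msgs <- character(0)
  if (any(lens <= 0L)) {
    msgs <- c(msgs, paste("length thresholds must be positive integers:",
                          paste(names(lens)[lens <= 0L], collapse = ", ")))
  }
  fr <- c(maxAmbiguityFrac = object@maxAmbiguityFrac,
          redundancyIdentity = object@redundancyIdentity,
          maxRepeatOverlapFrac = object@maxRepeatOverlapFrac)
  if (any(fr <= 0 | fr > 1)) {
    msgs <- c(msgs, "fractions must lie in (0, 1]")
  }
  if (object@probesPerExon < 1L) {
    msgs <- c(msgs, "probesPerExon must be >= 1")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct design parameters
#'
#' @param minReadLen minimum kept read length (bp).
#' @param maxAmbiguityFrac maximum fraction of undetermined bases (strict).
#' @param endTrim bases trimmed from each 5' and 3' end.
#' @param minExonLen minimum consensus exon length (bp).
#' @param shortExonPenaltyLen regions shorter than this are penalised (bp).
#' @param minOrfLen minimum ORF length, stop included (bp).
#' @param redundancyIdentity identity threshold for redundancy removal.
#' @param maxRepeatOverlapFrac maximal tolerated repeat overlap fraction
#'   (strictly-greater overlap is filtered).
#' @param probesPerExon probes per exon candidate.
#' @param probeLen probe length (bp).
#' @return a \code{DesignParams} object.
#' @export
#' @examples
#' designParams()
designParams <- function(minReadLen = 100L, maxAmbiguityFrac = 0.03,
                         endTrim = 60L, minExonLen = 60L,
                         shortExonPenaltyLen = 100L, minOrfLen = 150L,
                         redundancyIdentity = 0.98,
                         maxRepeatOverlapFrac = 0.25,
                         probesPerExon = 4L, probeLen = 25L) {
  new("DesignParams",
      minReadLen = as.integer(minReadLen),
      maxAmbiguityFrac = maxAmbiguityFrac,
      endTrim = as.integer(endTrim),
      minExonLen = as.integer(minExonLen),
      shortExonPenaltyLen = as.integer(shortExonPenaltyLen),
      minOrfLen = as.integer(minOrfLen),
      redundancyIdentity = redundancyIdentity,
      maxRepeatOverlapFrac = maxRepeatOverlapFrac,
      probesPerExon = as.integer(probesPerExon),
      probeLen = as.integer(probeLen))
}

setMethod("show", "DesignParams", function(object) {
  cat("DesignParams\n")
  cat("  reads : min length", object@minReadLen, "bp, ambiguity >",
      object@maxAmbiguityFrac, "removed, end trim", object@endTrim, "bp\n")
  cat("  exons : min", object@minExonLen, "bp, penalty <",
      object@shortExonPenaltyLen, "bp, repeat overlap >",
      object@maxRepeatOverlapFrac, "filtered\n")
  cat("  ESTs  : min ORF", object@minOrfLen, "bp, redundancy identity >=",
      object@redundancyIdentity, "\n")
  cat("  probes:", object@probesPerExon, "x", object@probeLen, "mer per exon\n")
})

#' Removal categories of the read-cleaning cascade, in cascade order
#' @export
CLEANING_CATEGORIES <- c("vector", "contaminant", "organelle", "short",
                         "ambiguous", "trim_casualty")

#' Read-cleaning accounting ledger
#'
#' Per-category removal counts for the cleaning cascade, with the
#' conservation guarantee that the input count equals the kept count plus
#' the sum of all removals. Categories are \code{vector}, \code{contaminant},
#' \code{organelle}, \code{short}, \code{ambiguous} and
#' \code{trim_casualty}; each removed read is counted in exactly one
#' category (the first cascade stage that claims it).
#'
#' @slot inputCount integer, reads entering the cascade.
#' @slot removed named integer vector over the six categories.
#' @slot keptCount integer, reads surviving all stages.
#' @export
setClass("CleaningLedger", representation(
  inputCount = "integer",
  removed = "integer",
  keptCount = "integer"
))

setValidity("CleaningLedger", function(object) {
  msgs <- character(0)
  if (!identical(names(object@removed), CLEANING_CATEGORIES)) {
    msgs <- c(msgs, paste("removed counts must be named",
                          paste(CLEANING_CATEGORIES, collapse = ", ")))
  }
  if (any(c(object@inputCount, object@removed, object@keptCount) < 0L)) {
    msgs <- c(msgs, "all counts must be >= 0")
  }
  if (object@inputCount != object@keptCount + sum(object@removed)) {
    msgs <- c(msgs, sprintf(
      "conservation violated: input %d != kept %d + removed %d",
      object@inputCount, object@keptCount, sum(object@removed)))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a cleaning ledger
#'
#' @param inputCount number of reads entering the cascade.
#' @param removed named numeric vector of removal counts; missing categories
#'   default to 0. Names must be among \code{vector}, \code{contaminant},
#'   \code{organelle}, \code{short}, \code{ambiguous}, \code{trim_casualty}.
#' @param keptCount kept reads; when \code{NULL}, derived as
#'   \code{inputCount - sum(removed)}.
#' @return a \code{CleaningLedger}.
#' @export
#' @examples
#' ## the accounting from a published GSS cleaning run
#' cleaningLedger(1271256, c(vector = 13010, contaminant = 146,
#'                           organelle = 23883, short = 245, ambiguous = 257))
cleaningLedger <- function(inputCount, removed = integer(0), keptCount = NULL) {
  full <- setNames(integer(length(CLEANING_CATEGORIES)), CLEANING_CATEGORIES)
  if (length(removed)) {
    bad <- setdiff(names(removed), CLEANING_CATEGORIES)
    if (length(bad)) stop("unknown removal categories: ",
                          paste(bad, collapse = ", "))
    full[names(removed)] <- as.integer(removed)
  }
  if (is.null(keptCount)) keptCount <- inputCount - sum(full)
  new("CleaningLedger", inputCount = as.integer(inputCount),
      removed = full, keptCount = as.integer(keptCount))
}

setMethod("show", "CleaningLedger", function(object) {
  cat("CleaningLedger:", object@inputCount, "reads in,",
      object@keptCount, "kept\n")
  rm <- object@removed[object@removed > 0L]
  if (length(rm)) {
    for (i in seq_along(rm)) cat(sprintf("  removed %-13s %d\n",
                                         names(rm)[i], rm[i]))
  }
})

#' Scored consensus exonic regions
#'
#' A \code{GRanges} subclass holding non-overlapping consensus exonic
#' regions on assembly contigs. Metadata columns: \code{supportingSources}
#' (a \code{CharacterList} of evidence source ids), \code{score} (integer
#' 0--7: number of distinct supporting sources minus the short-region
#' penalty, clamped), \code{shortPenalized}, \code{repeatOverlapFrac} and
#' \code{origin} (\code{"genomic"} or \code{"est"}).
#'
#' @export
#' @import GenomicRanges
setClass("ExonicRegions", contains = "GRanges")

setValidity("ExonicRegions", function(object) {
  msgs <- character(0)
  need <- c("supportingSources", "score", "shortPenalized",
            "repeatOverlapFrac", "origin")
  missing <- setdiff(need, colnames(S4Vectors::mcols(object)))
  if (length(missing)) {
    return(paste("missing metadata columns:", paste(missing, collapse = ", ")))
  }
  sc <- S4Vectors::mcols(object)$score
  if (length(sc) && (any(sc < 0L) || any(sc > 7L))) {
    msgs <- c(msgs, "scores must lie in [0, 7]")
  }
  if (length(object) > 1L) {
    ov <- GenomicRanges::findOverlaps(object, ignore.strand = TRUE,
                                      drop.self = TRUE)
    if (length(ov)) msgs <- c(msgs, "regions must be pairwise non-overlapping")
  }
  if (!all(S4Vectors::mcols(object)$origin %in% c("genomic", "est"))) {
    msgs <- c(msgs, "origin must be 'genomic' or 'est'")
  }
  if (length(msgs)) msgs else TRUE
})

#' Merged exon-candidate set with accounting
#'
#' The union of genomic consensus regions and ORF-bearing EST contigs after
#' redundancy removal, together with a ledger of every status transition.
#'
#' @slot regions an [ExonicRegions] with both origins.
#' @slot ledger named integer vector of per-stage counts.
#' @slot estStatus data.frame with one row per input EST contig
#'   (\code{id}, \code{status}).
#' @export
setClass("CandidateSet", representation(
  regions = "ExonicRegions",
  ledger = "integer",
  estStatus = "data.frame"
))

setValidity("CandidateSet", function(object) {
  lg <- object@ledger
  need <- c("genomic_in", "est_in", "est_te_filtered", "est_redundant",
            "est_no_orf", "est_kept", "genomic_redundant", "genomic_kept",
            "final")
  missing <- setdiff(need, names(lg))
  if (length(missing)) {
    return(paste("ledger missing:", paste(missing, collapse = ", ")))
  }
  msgs <- character(0)
  if (lg[["est_in"]] != lg[["est_te_filtered"]] + lg[["est_redundant"]] +
      lg[["est_no_orf"]] + lg[["est_kept"]]) {
    msgs <- c(msgs, "EST ledger does not conserve totals")
  }
  if (lg[["genomic_in"]] != lg[["genomic_redundant"]] + lg[["genomic_kept"]]) {
    msgs <- c(msgs, "genomic ledger does not conserve totals")
  }
  if (lg[["final"]] != lg[["genomic_kept"]] + lg[["est_kept"]]) {
    msgs <- c(msgs, "final count must equal genomic_kept + est_kept")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CandidateSet", function(object) {
  lg <- object@ledger
  cat("CandidateSet:", lg[["final"]], "exon candidates (",
      lg[["genomic_kept"]], "genomic +", lg[["est_kept"]], "EST )\n")
  cat("  ESTs in:", lg[["est_in"]], "| TE/repeat:", lg[["est_te_filtered"]],
      "| redundant:", lg[["est_redundant"]], "| no ORF:",
      lg[["est_no_orf"]], "\n")
})

#' A probeset: the probes interrogating one exon candidate
#'
#' @slot exonId exon candidate identifier.
#' @slot probes data.frame with columns \code{offset} (1-based start within
#'   the exon), \code{length}, \code{sequence}, \code{gc}.
#' @slot complete TRUE iff the target number of probes was selected.
#' @slot overlapping TRUE when the exon was too short for disjoint probes
#'   and overlap was allowed.
#' @slot probesPerExon the selection target.
#' @export
setClass("ProbeSet", representation(
  exonId = "character",
  probes = "data.frame",
  complete = "logical",
  overlapping = "logical",
  probesPerExon = "integer"
))

setValidity("ProbeSet", function(object) {
  msgs <- character(0)
  if (nrow(object@probes) > object@probesPerExon) {
    msgs <- c(msgs, "more probes than probesPerExon")
  }
  if (object@complete != (nrow(object@probes) == object@probesPerExon)) {
    msgs <- c(msgs, "complete flag inconsistent with probe count")
  }
  if (nrow(object@probes) &&
      any(grepl("[^ACGT]", object@probes$sequence))) {
    msgs <- c(msgs, "probe sequences must be uppercase ACGT only")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ProbeSet", function(object) {
  cat("ProbeSet", object@exonId, ":", nrow(object@probes), "/",
      object@probesPerExon, "probes",
      if (object@complete) "(complete)" else "(incomplete)",
      if (object@overlapping) "[overlapping]" else "", "\n")
})

#' GGE biplot decomposition result
#'
#' Centered-SVD decomposition of a genotype-by-environment matrix after
#' environment centering (removing E, leaving G + GxE) with symmetric
#' (f = 0.5) scaling of genotype scores and environment loadings.
#'
#' @slot genotypeScores genotypes x axes matrix (U scaled by sqrt singular
#'   values).
#' @slot environmentLoadings environments x axes matrix (V scaled by sqrt
#'   singular values).
#' @slot singularValues singular values of the centered matrix.
#' @slot varianceExplained percent of total inertia per axis (sums to 100).
#' @slot nAxes number of axes requested for display/ranking.
#' @slot centered the environment-centered matrix that was decomposed.
#' @export
setClass("GGEResult", representation(
  genotypeScores = "matrix",
  environmentLoadings = "matrix",
  singularValues = "numeric",
  varianceExplained = "numeric",
  nAxes = "integer",
  centered = "matrix"
))

setValidity("GGEResult", function(object) {
  msgs <- character(0)
  if (sum(object@singularValues) > 0 &&
      abs(sum(object@varianceExplained) - 100) > 1e-6) {
    msgs <- c(msgs, "varianceExplained must sum to 100")
  }
  if (ncol(object@genotypeScores) != ncol(object@environmentLoadings)) {
    msgs <- c(msgs, "score and loading matrices must share axis count")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GGEResult", function(object) {
  cat("GGEResult:", nrow(object@genotypeScores), "genotypes x",
      nrow(object@environmentLoadings), "environments\n")
  k <- min(object@nAxes, length(object@varianceExplained))
  cat(sprintf("  axes 1..%d explain %.1f%% of G+GxE inertia\n", k,
              sum(object@varianceExplained[seq_len(k)])))
})
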