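#' Default evidence source configuration
#'
#' Up to seven supporting evidence sources are scored. The default set
#' covers two ab initio gene predictors, three transcript sources, protein
#' homology and genomic conservation; it is configurable wherever sources
#' are consumed. \code{DEFAULT_SOURCE_PRIORITY} orders sources for strand
#' voting: transcript evidence outranks ab initio predictions, which
#' outrank protein homology, which outranks conservation.
#'
#' @export
DEFAULT_SOURCES <- c("augustus", "fgenesh", "tobacco_est", "tobacco_cdna",
                     "protein_homology", "conservation", "related_cdna")

#' @rdname DEFAULT_SOURCES
#' @export
DEFAULT_SOURCE_PRIORITY <- c("tobacco_est", "tobacco_cdna", "related_cdna",
                             "augustus", "fgenesh", "protein_homology",
                             "conservation")

.emptyExonicRegions <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    supportingSources = IRanges::CharacterList(),
    score = integer(0), shortPenalized = logical(0),
    repeatOverlapFrac = numeric(0), origin = character(0))
  new("ExonicRegions", gr)
}

# union coverage of `regions` by `masks`, vectorized
.repeatOverlapFrac <- function(regionsGr, masks) {
  frac <- numeric(length(regionsGr))
  if (!length(masks) || !length(regionsGr)) return(frac)
  red <- GenomicRanges::reduce(masks, ignore.strand = TRUE)
  ov <- GenomicRanges::findOverlaps(regionsGr, red, ignore.strand = TRUE)
  if (!length(ov)) return(frac)
  pi <- GenomicRanges::pintersect(regionsGr[S4Vectors::queryHits(ov)],
                                  red[S4Vectors::subjectHits(ov)],
                                  ignore.strand = TRUE)
  covered <- tapply(GenomicRanges::width(pi), S4Vectors::queryHits(ov), sum)
  idx <- as.integer(names(covered))
  frac[idx] <- as.numeric(covered) / GenomicRanges::width(regionsGr)[idx]
  frac
}

#' Build consensus exonic regions from evidence tracks
#'
#' The core evidence-combination step: supporting intervals from all
#' sources whose pairwise overlap is at least 1 bp are clustered
#' transitively, and each cluster becomes one candidate region spanning
#' the union of its intervals (merely adjacent intervals are not joined).
#' Regions shorter than \code{minExonLen} are dropped; regions shorter
#' than \code{shortExonPenaltyLen} carry a one-point score penalty. Repeat
#' masks act as negative evidence via \code{repeatOverlapFrac}. The score
#' is the number of distinct supporting sources minus the penalty, clamped
#' to \[0, 7\].
#'
#' @param tracks named list of \code{GRanges}, one per evidence source
#'   (names are the source ids; at most one track per source).
#' @param repeats \code{GRanges} of repeat masks (negative evidence).
#' @param params a [DesignParams].
#' @return an [ExonicRegions], sorted and pairwise non-overlapping, with
#'   strand \code{*} (assign strands with [assignStrand()]).
#' @export
buildConsensusRegions <- function(tracks, repeats = GenomicRanges::GRanges(),
                                  params = designParams()) {
  if (is.null(names(tracks)) || any(!nzchar(names(tracks)))) {
    stop("tracks must be a named list (source ids)")
  }
  if (anyDuplicated(names(tracks))) stop("duplicate source tracks")
  allIv <- do.call(c, unname(lapply(names(tracks), function(s) {
    gr <- tracks[[s]]
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      source_id = rep(s, length(gr)))
    gr
  })))
  if (is.null(allIv) || !length(allIv)) return(.emptyExonicRegions())
  # contiguity defines a cluster: intervals sharing or abutting positions
  # merge, exactly as a positionwise union of the evidence would
  merged <- GenomicRanges::reduce(allIv, ignore.strand = TRUE)
  merged <- merged[GenomicRanges::width(merged) >= params@minExonLen]
  if (!length(merged)) return(.emptyExonicRegions())
  ov <- GenomicRanges::findOverlaps(merged, allIv, ignore.strand = TRUE)
  srcList <- split(S4Vectors::mcols(allIv)$source_id[S4Vectors::subjectHits(ov)],
                   factor(S4Vectors::queryHits(ov),
                          levels = seq_along(merged)))
  srcList <- lapply(srcList, function(x) sort(unique(x)))
  shortPen <- GenomicRanges::width(merged) < params@shortExonPenaltyLen
  nSrc <- lengths(srcList)
  score <- pmin(7L, pmax(0L, as.integer(nSrc) - as.integer(shortPen)))
  S4Vectors::mcols(merged) <- S4Vectors::DataFrame(
    supportingSources = IRanges::CharacterList(srcList),
    score = score,
    shortPenalized = shortPen,
    repeatOverlapFrac = .repeatOverlapFrac(merged, repeats),
    origin = rep("genomic", length(merged)))
  merged <- GenomicRanges::sort(merged, ignore.strand = TRUE)
  new("ExonicRegions", merged)
}

#' Filter consensus regions by evidence rules
#'
#' Removes, in order of rule precedence:
#' \describe{
#'   \item{est_only (a)}{genomic regions whose only support is EST
#'     evidence;}
#'   \item{fgenesh_repeat (b)}{regions supported only by the ab initio
#'     \code{fgenesh} source that overlap a repeat at all;}
#'   \item{te_match (c)}{regions flagged by the transposable-element
#'     protein label track;}
#'   \item{repeat_overlap (d)}{regions overlapping repeats by strictly
#'     more than \code{maxRepeatOverlapFrac} of their length.}
#' }
#' Every removal is logged with its rule id in
#' \code{S4Vectors::metadata(result)$filterLog}.
#'
#' @param regionsObj an [ExonicRegions] from [buildConsensusRegions()].
#' @param params a [DesignParams].
#' @param teLabels \code{GRanges} of precomputed transposable-element
#'   protein matches (rule c), or \code{NULL}.
#' @param estSources source ids counted as EST-only evidence for rule (a).
#' @return the filtered [ExonicRegions] with a \code{filterLog} data.frame
#'   in its metadata.
#' @export
filterRegions <- function(regionsObj, params = designParams(),
                          teLabels = NULL, estSources = "tobacco_est") {
  src <- S4Vectors::mcols(regionsObj)$supportingSources
  origin <- S4Vectors::mcols(regionsObj)$origin
  rof <- S4Vectors::mcols(regionsObj)$repeatOverlapFrac
  ruleA <- origin == "genomic" & lengths(src) > 0L &
    vapply(src, function(s) all(s %in% estSources), logical(1))
  ruleB <- vapply(src, function(s) identical(s, "fgenesh"), logical(1)) &
    rof > 0
  ruleC <- if (!is.null(teLabels) && length(teLabels)) {
    IRanges::overlapsAny(regionsObj, teLabels, ignore.strand = TRUE)
  } else rep(FALSE, length(regionsObj))
  ruleD <- rof > params@maxRepeatOverlapFrac
  rule <- rep(NA_character_, length(regionsObj))
  rule[ruleD] <- "repeat_overlap"
  rule[ruleC] <- "te_match"
  rule[ruleB] <- "fgenesh_repeat"
  rule[ruleA] <- "est_only"
  drop <- !is.na(rule)
  log <- data.frame(
    seqnames = as.character(GenomicRanges::seqnames(regionsObj))[drop],
    start = GenomicRanges::start(regionsObj)[drop],
    end = GenomicRanges::end(regionsObj)[drop],
    rule = rule[drop])
  out <- regionsObj[!drop]
  S4Vectors::metadata(out)$filterLog <- log
  out
}

#' Assign a likely strand to each region by weighted majority vote
#'
#' Stranded supporting intervals vote for their strand; votes are weighted
#' by source priority so that any higher-priority source outweighs all
#' lower-priority sources combined. Regions with no stranded evidence stay
#' \code{*}; an exact tie is resolved to \code{+}.
#'
#' @param regionsObj an [ExonicRegions].
#' @param tracks the named list of evidence \code{GRanges} used to build
#'   the regions.
#' @param priority character vector of source ids, highest priority first.
#' @return the regions with strands filled in.
#' @export
assignStrand <- function(regionsObj, tracks,
                         priority = DEFAULT_SOURCE_PRIORITY) {
  if (!length(regionsObj)) return(regionsObj)
  allSrc <- unique(c(priority, names(tracks)))
  rank <- setNames(match(names(tracks), allSrc), names(tracks))
  nR <- length(allSrc)
  votes <- matrix(0, nrow = length(regionsObj), ncol = 2,
                  dimnames = list(NULL, c("+", "-")))
  for (s in names(tracks)) {
    gr <- tracks[[s]]
    gr <- gr[as.character(GenomicRanges::strand(gr)) %in% c("+", "-")]
    if (!length(gr)) next
    w <- 2^(nR - rank[[s]])
    ov <- GenomicRanges::findOverlaps(regionsObj, gr, ignore.strand = TRUE)
    if (!length(ov)) next
    st <- as.character(GenomicRanges::strand(gr))[S4Vectors::subjectHits(ov)]
    for (sgn in c("+", "-")) {
      tab <- table(factor(S4Vectors::queryHits(ov)[st == sgn],
                          levels = seq_along(regionsObj)))
      votes[, sgn] <- votes[, sgn] + w * as.numeric(tab)
    }
  }
  newStrand <- rep("*", length(regionsObj))
  newStrand[votes[, "+"] > votes[, "-"]] <- "+"
  newStrand[votes[, "-"] > votes[, "+"]] <- "-"
  tie <- votes[, "+"] == votes[, "-"] & votes[, "+"] > 0
  newStrand[tie] <- "+"
  GenomicRanges::strand(regionsObj) <- newStrand
  regionsObj
}

#' Rank regions by evidence score
#'
#' Stable sort by score (descending), then length (descending), then
#' contig id and start; optionally truncated to \code{targetCount}.
#'
#' @param regionsObj an [ExonicRegions].
#' @param targetCount optional number of regions to keep.
#' @return the reordered (and possibly truncated) regions.
#' @export
rankRegions <- function(regionsObj, targetCount = NULL) {
  if (!is.null(targetCount) && targetCount < 0) {
    stop("targetCount must be >= 0")
  }
  o <- order(-S4Vectors::mcols(regionsObj)$score,
             -GenomicRanges::width(regionsObj),
             as.character(GenomicRanges::seqnames(regionsObj)),
             GenomicRanges::start(regionsObj))
  out <- regionsObj[o]
  if (!is.null(targetCount)) out <- head(out, targetCount)
  out
}

#' Exon-level sensitivity and specificity
#'
#' Boundary matching in the gene-prediction convention: a truth exon
#' counts as found when a predicted exon matches both boundaries within
#' \code{tolerance} bp (exact matching at the default 0). Sensitivity is
#' the matched fraction of truth exons; specificity is the matched
#' fraction of predictions (i.e. precision).
#'
#' @param predicted,truth \code{GRanges} of predicted and true exons.
#' @param tolerance allowed boundary deviation in bp.
#' @return list with \code{sensitivity}, \code{specificity} and
#'   \code{specificityDefined} (FALSE when there were no predictions, in
#'   which case specificity is reported as 0).
#' @export
exonEval <- function(predicted, truth, tolerance = 0L) {
  if (!length(truth)) stop("empty truth set: sensitivity undefined")
  if (!length(predicted)) {
    return(list(sensitivity = 0, specificity = 0,
                specificityDefined = FALSE))
  }
  matchMat <- function(a, b) {
    # for each range in a, is there a range in b matching both boundaries?
    vapply(seq_along(a), function(i) {
      sameSeq <- as.character(GenomicRanges::seqnames(b)) ==
        as.character(GenomicRanges::seqnames(a))[i]
      any(sameSeq &
            abs(GenomicRanges::start(b) - GenomicRanges::start(a)[i]) <= tolerance &
            abs(GenomicRanges::end(b) - GenomicRanges::end(a)[i]) <= tolerance)
    }, logical(1))
  }
  list(sensitivity = mean(matchMat(truth, predicted)),
       specificity = mean(matchMat(predicted, truth)),
       specificityDefined = TRUE)
}

#' Run the full evidence-integration stage
#'
#' Convenience wrapper: build consensus regions, apply the filter rules,
#' and assign strands.
#'
#' @inheritParams buildConsensusRegions
#' @inheritParams filterRegions
#' @inheritParams assignStrand
#' @return a stranded, filtered [ExonicRegions].
#' @export
integrateEvidence <- function(tracks, repeats = GenomicRanges::GRanges(),
                              params = designParams(), teLabels = NULL,
                              estSources = "tobacco_est",
                              priority = DEFAULT_SOURCE_PRIORITY) {
  regs <- buildConsensusRegions(tracks, repeats, params)
  regs <- filterRegions(regs, params, teLabels = teLabels,
                        estSources = estSources)
  assignStrand(regs, tracks, priority = priority)
}
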