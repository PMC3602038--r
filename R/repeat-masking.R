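#' Find perfect tandem repeat arrays
#'
#' Detects maximal perfect tandem arrays with periods between
#' \code{minPeriod} and \code{maxPeriod}: intervals where every base equals
#' the base one period upstream. An array qualifies when its total length
#' reaches \code{minTotalLen} and spans at least \code{minCopies} copies of
#' the repeat unit. Overlapping qualifying arrays (across periods and
#' phases) are merged; each merged annotation is labelled with the smallest
#' contributing period.
#'
#' @param seq uppercase nucleotide sequence (character scalar).
#' @param seqId sequence name used on the returned ranges.
#' @param minPeriod,maxPeriod period range of the repeat unit (bp).
#' @param minTotalLen minimum array length (bp).
#' @param minCopies minimum number of unit copies (may be fractional for a
#'   partial trailing copy).
#' @return a \code{GRanges} with metadata columns \code{kind}
#'   (\code{"simple"}) and \code{label} (\code{"period=<p>"}).
#' @export
#' @examples
#' findTandemRepeats(strrep("ACG", 7), "s1")
findTandemRepeats <- function(seq, seqId = "seq", minPeriod = 1L,
                              maxPeriod = 6L, minTotalLen = 18L,
                              minCopies = 4) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  hits <- list()
  for (p in seq.int(minPeriod, maxPeriod)) {
    if (n <= p) next
    eq <- ch[seq_len(n - p)] == ch[seq.int(p + 1L, n)]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in which(r$values)) {
      total <- r$lengths[i] + p           # array spans the matched run + p
      if (total >= minTotalLen && total / p >= minCopies) {
        hits[[length(hits) + 1L]] <-
          c(start = starts[i], end = starts[i] + total - 1L, period = p)
      }
    }
  }
  if (!length(hits)) {
    return(GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges(),
                                  kind = character(0), label = character(0)))
  }
  df <- as.data.frame(do.call(rbind, hits))
  gr <- GenomicRanges::GRanges(seqId,
                               IRanges::IRanges(df$start, df$end))
  merged <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(merged, gr)
  lab <- vapply(seq_along(merged), function(i) {
    min(df$period[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]])
  }, numeric(1))
  S4Vectors::mcols(merged)$kind <- rep("simple", length(merged))
  S4Vectors::mcols(merged)$label <- paste0("period=", lab)
  merged
}

#' Mask a sequence with a complex-repeat library
#'
#' Marks intervals of \code{seq} matching any library record (both
#' strands) at the identity and length thresholds, labelled by repeat
#' family (the library record id).
#'
#' @param seq character scalar (contig or read).
#' @param seqId sequence name used on the returned ranges.
#' @param repeatLibrary named character vector (or XStringSet) of repeat
#'   family consensus sequences.
#' @param minIdentity minimum identity of a masked segment.
#' @param minLen minimum masked segment length (bp).
#' @return a \code{GRanges} with metadata columns \code{kind}
#'   (\code{"complex"}) and \code{label} (repeat family).
#' @export
maskWithLibrary <- function(seq, seqId = "seq", repeatLibrary,
                            minIdentity = 0.8, minLen = 50L) {
  empty <- GenomicRanges::GRanges(seqnames = character(0),
                                  ranges = IRanges::IRanges(),
                                  kind = character(0), label = character(0))
  if (!length(repeatLibrary)) return(empty)
  hits <- .libraryHits(seq, repeatLibrary, minIdentity = minIdentity,
                       minLen = minLen, allHits = TRUE)
  if (is.null(hits)) return(empty)
  hits <- hits[hits$length >= minLen, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  gr <- GenomicRanges::GRanges(seqId,
                               IRanges::IRanges(hits$qstart, hits$qend))
  merged <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(merged, gr)
  lab <- vapply(seq_along(merged), function(i) {
    fams <- hits$libId[S4Vectors::subjectHits(ov)[S4Vectors::queryHits(ov) == i]]
    paste(sort(unique(fams)), collapse = ",")
  }, character(1))
  S4Vectors::mcols(merged)$kind <- rep("complex", length(merged))
  S4Vectors::mcols(merged)$label <- lab
  merged
}

#' Apply soft masking to a sequence
#'
#' Lowercases the masked positions; every letter and the length are
#' preserved, so \code{toupper()} inverts the operation.
#'
#' @param seq character scalar.
#' @param masks \code{GRanges} (coordinates within the sequence) or an
#'   \code{IRanges}.
#' @return soft-masked sequence.
#' @export
#' @examples
#' applySoftmask("ACGTACGT", GenomicRanges::GRanges("s", IRanges::IRanges(3, 4)))
applySoftmask <- function(seq, masks) {
  rng <- if (is(masks, "GRanges")) GenomicRanges::ranges(masks) else masks
  if (!length(rng)) return(seq)
  n <- nchar(seq)
  if (min(IRanges::start(rng)) < 1L || max(IRanges::end(rng)) > n) {
    stop("mask interval out of sequence bounds")
  }
  ch <- strsplit(seq, "")[[1]]
  for (i in seq_along(rng)) {
    idx <- IRanges::start(rng)[i]:IRanges::end(rng)[i]
    ch[idx] <- tolower(ch[idx])
  }
  paste(ch, collapse = "")
}

#' Fraction of an interval covered by a set of masks
#'
#' Computed on the union of the masks, so overlapping mask intervals are
#' never double-counted. Only masks on the same sequence as the interval
#' contribute.
#'
#' @param interval a length-1 \code{GRanges}.
#' @param masks a \code{GRanges} of mask intervals.
#' @return covered fraction in \[0, 1\].
#' @export
overlapFraction <- function(interval, masks) {
  stopifnot(is(interval, "GRanges"), length(interval) == 1L)
  if (!length(masks)) return(0)
  masks <- masks[as.character(GenomicRanges::seqnames(masks)) ==
                 as.character(GenomicRanges::seqnames(interval))]
  if (!length(masks)) return(0)
  ov <- GenomicRanges::intersect(
    GenomicRanges::reduce(masks, ignore.strand = TRUE),
    interval, ignore.strand = TRUE)
  sum(GenomicRanges::width(ov)) / GenomicRanges::width(interval)
}
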