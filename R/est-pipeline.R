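#' Create an EST-contig table
#'
#' EST contigs travel through the pipeline as a data.frame with one row
#' per contig: \code{id}, \code{seq}, \code{status} (one of
#' \code{unscreened}, \code{te_filtered}, \code{redundant},
#' \code{no_orf}, \code{kept}) and ORF columns (\code{orf_start},
#' \code{orf_end} 1-based on the forward strand, \code{orf_strand},
#' \code{orf_frame}; NA until an ORF is found).
#'
#' @param bases named character vector of contig sequences.
#' @return the EST-contig data.frame.
#' @export
estContigs <- function(bases) {
  if (anyDuplicated(names(bases))) stop("duplicate EST contig ids")
  data.frame(id = as.character(names(bases)), seq = unname(bases),
             status = rep("unscreened", length(bases)),
             orf_start = rep(NA_integer_, length(bases)),
             orf_end = rep(NA_integer_, length(bases)),
             orf_strand = rep(NA_character_, length(bases)),
             orf_frame = rep(NA_integer_, length(bases)),
             stringsAsFactors = FALSE)
}

#' Longest open reading frame over six frames
#'
#' Scans three frames on each strand for ATG-initiated, stop-terminated
#' codon runs (the stop codon counts toward the length) and returns the
#' longest one of at least \code{minOrfLen} bases. Ties are broken in
#' favour of the plus strand, then the smallest forward-strand start.
#' Coordinates are reported on the forward strand.
#'
#' @param seq uppercase nucleotide sequence.
#' @param minOrfLen minimum ORF length in bases (stop included).
#' @return list with \code{start}, \code{end} (1-based, forward strand),
#'   \code{strand} and \code{frame} (1--3 on the ORF's own strand), or
#'   \code{NULL} when no qualifying ORF exists.
#' @export
longestOrf <- function(seq, minOrfLen = 150L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  stops <- c("TAA", "TAG", "TGA")
  scanStrand <- function(s, strandLabel) {
    res <- list()
    for (f in 1:3) {
      cs <- seq.int(f, nchar(s) - 2L, by = 3L)
      if (!length(cs)) next
      codons <- substring(s, cs, cs + 2L)
      isStop <- codons %in% stops
      isAtg <- codons == "ATG"
      prevStop <- 0L
      for (j in which(isStop)) {
        cand <- which(isAtg[seq.int(prevStop + 1L, j)]) + prevStop
        if (length(cand)) {
          i <- cand[1L]
          len <- (j - i + 1L) * 3L
          if (len >= minOrfLen) {
            res[[length(res) + 1L]] <- c(f = f, sPos = cs[i],
                                         ePos = cs[j] + 2L, len = len)
          }
        }
        prevStop <- j
      }
    }
    if (!length(res)) return(NULL)
    df <- as.data.frame(do.call(rbind, res))
    df$strand <- strandLabel
    df
  }
  fwd <- scanStrand(seq, "+")
  rev <- scanStrand(revComp(seq), "-")
  if (!is.null(rev)) {
    fs <- n - rev$ePos + 1L
    fe <- n - rev$sPos + 1L
    rev$sPos <- fs
    rev$ePos <- fe
  }
  cands <- rbind(fwd, rev)
  if (is.null(cands) || !nrow(cands)) return(NULL)
  o <- order(-cands$len, cands$strand != "+", cands$sPos)
  b <- cands[o[1L], ]
  list(start = b$sPos, end = b$ePos, strand = b$strand, frame = b$f)
}

#' Screen EST contigs for a qualifying ORF
#'
#' Runs [longestOrf()] on every contig still unscreened; contigs with an
#' ORF become \code{kept} (with the ORF recorded and the strand inferred
#' from it), the rest become \code{no_orf}.
#'
#' @param ests EST-contig data.frame (see [estContigs()]).
#' @param minOrfLen minimum ORF length (bp).
#' @return the updated table.
#' @export
orfScreen <- function(ests, minOrfLen = 150L) {
  for (i in which(ests$status == "unscreened")) {
    orf <- longestOrf(ests$seq[i], minOrfLen)
    if (is.null(orf)) {
      ests$status[i] <- "no_orf"
    } else {
      ests$status[i] <- "kept"
      ests$orf_start[i] <- orf$start
      ests$orf_end[i] <- orf$end
      ests$orf_strand[i] <- orf$strand
      ests$orf_frame[i] <- orf$frame
    }
  }
  ests
}

#' Flag transposable-element / repeat-laden EST contigs
#'
#' Applies the same rules as the genomic branch: a contig is filtered
#' when it carries a transposable-element protein label, or when the
#' union of its repeat masks covers strictly more than
#' \code{maxRepeatOverlapFrac} of its length.
#'
#' @param ests EST-contig data.frame.
#' @param masks \code{GRanges} of repeat masks with seqnames equal to
#'   contig ids.
#' @param teLabels character vector of contig ids flagged as TE-protein
#'   matches.
#' @param maxRepeatOverlapFrac strict overlap threshold.
#' @return the updated table (\code{status = "te_filtered"} where
#'   flagged).
#' @export
teRepeatFilter <- function(ests, masks = GenomicRanges::GRanges(),
                           teLabels = character(0),
                           maxRepeatOverlapFrac = 0.25) {
  for (i in which(ests$status == "unscreened")) {
    id <- ests$id[i]
    frac <- 0
    if (length(masks)) {
      m <- masks[as.character(GenomicRanges::seqnames(masks)) == id]
      if (length(m)) {
        iv <- GenomicRanges::GRanges(id, IRanges::IRanges(1L,
                                                          nchar(ests$seq[i])))
        frac <- overlapFraction(iv, m)
      }
    }
    if (id %in% teLabels || frac > maxRepeatOverlapFrac) {
      ests$status[i] <- "te_filtered"
    }
  }
  ests
}

# is `seq` redundant with any member of `library` (named chr)?
# identity >= redundancyIdentity over >= minCovShorter of the shorter seq
.isRedundant <- function(seq, library, redundancyIdentity = 0.98,
                         minCovShorter = 0.8, index = NULL) {
  if (!length(library)) return(FALSE)
  hits <- .libraryHits(seq, library, minIdentity = redundancyIdentity,
                       minLen = 30L, index = index)
  if (is.null(hits)) return(FALSE)
  shorter <- pmin(nchar(seq), nchar(library)[hits$lib])
  any(hits$length >= minCovShorter * shorter)
}

#' Remove EST contigs redundant with genomic exon candidates
#'
#' An EST contig is redundant when some genomic candidate sequence aligns
#' to it at identity at least \code{redundancyIdentity} over at least
#' \code{minCovShorter} of the shorter of the two sequences; genomic
#' members always take precedence and are retained. The decision is made
#' per contig against the fixed genomic set, so the result does not
#' depend on the input order.
#'
#' @param ests EST-contig data.frame.
#' @param genomicSeqs named character vector of genomic candidate
#'   sequences.
#' @param redundancyIdentity identity threshold.
#' @param minCovShorter coverage-of-the-shorter-sequence threshold.
#' @return the updated table (\code{status = "redundant"} where flagged).
#' @export
redundancyFilter <- function(ests, genomicSeqs,
                             redundancyIdentity = 0.98,
                             minCovShorter = 0.8) {
  if (!length(genomicSeqs)) return(ests)
  idx <- .buildKmerIndex(toupper(.asSeqChar(genomicSeqs)), 12L)
  for (i in which(ests$status == "unscreened")) {
    if (.isRedundant(ests$seq[i], genomicSeqs, redundancyIdentity,
                     minCovShorter, index = idx)) {
      ests$status[i] <- "redundant"
    }
  }
  ests
}

#' EST-contig accounting
#'
#' The EST branch's arithmetic: contigs entering the ORF search are the
#' assembled total minus the TE/repeat-filtered and redundancy-filtered
#' contigs.
#'
#' @param total assembled EST contigs.
#' @param teFiltered contigs removed by the TE/repeat criteria.
#' @param redundant contigs removed as redundant with genomic candidates.
#' @return number of contigs entering the ORF search.
#' @export
#' @examples
#' estContigAccounting(55520, 8451, 26882)
estContigAccounting <- function(total, teFiltered, redundant) {
  stopifnot(total >= 0, teFiltered >= 0, redundant >= 0)
  out <- total - teFiltered - redundant
  if (out < 0) stop("removals exceed the total")
  out
}

#' Merge genomic and EST exon candidates into the final set
#'
#' Joins the two origins and removes within-set redundancy at the
#' \code{redundancyIdentity} threshold, giving precedence to genomic
#' candidates, then higher score, then longer sequence. EST contigs enter
#' as whole-contig regions (origin \code{"est"}, supported by EST
#' evidence only, strand from their ORF). Every status transition is
#' recorded in the ledger.
#'
#' @param genomicRegions an [ExonicRegions] of genomic candidates; must be
#'   named (region ids).
#' @param genomicSeqs named character vector of the region sequences (ids
#'   matching \code{names(genomicRegions)}).
#' @param ests EST-contig data.frame after [teRepeatFilter()],
#'   [redundancyFilter()] and [orfScreen()].
#' @param params a [DesignParams].
#' @return a [CandidateSet].
#' @export
buildCandidateSet <- function(genomicRegions, genomicSeqs, ests,
                              params = designParams()) {
  stopifnot(length(genomicRegions) == length(genomicSeqs))
  if (length(genomicRegions) && is.null(names(genomicRegions))) {
    stop("genomicRegions must be named")
  }
  tally <- function(st) sum(ests$status == st)
  # candidate pool ordered by precedence: genomic first, then score desc,
  # then longer
  gScore <- S4Vectors::mcols(genomicRegions)$score
  gLen <- nchar(genomicSeqs)
  gOrd <- order(-gScore, -gLen)
  eKeep <- which(ests$status == "kept")
  eOrd <- eKeep[order(-nchar(ests$seq[eKeep]))]
  pool <- data.frame(
    id = c(names(genomicRegions)[gOrd], ests$id[eOrd]),
    seq = c(unname(genomicSeqs)[gOrd], ests$seq[eOrd]),
    origin = c(rep("genomic", length(gOrd)), rep("est", length(eOrd))),
    stringsAsFactors = FALSE)
  keptIdx <- integer(0)
  nGenomicDropped <- 0L
  nEstDropped <- 0L
  for (i in seq_len(nrow(pool))) {
    redundant <- FALSE
    if (length(keptIdx)) {
      keptSeqs <- setNames(pool$seq[keptIdx], pool$id[keptIdx])
      redundant <- .isRedundant(pool$seq[i], keptSeqs,
                                params@redundancyIdentity, 0.8)
    }
    if (redundant) {
      if (pool$origin[i] == "genomic") {
        nGenomicDropped <- nGenomicDropped + 1L
      } else {
        nEstDropped <- nEstDropped + 1L
        ests$status[ests$id == pool$id[i]] <- "redundant"
      }
    } else {
      keptIdx <- c(keptIdx, i)
    }
  }
  keptPool <- pool[keptIdx, , drop = FALSE]
  gKeptIds <- keptPool$id[keptPool$origin == "genomic"]
  eKeptIds <- keptPool$id[keptPool$origin == "est"]
  gOut <- genomicRegions[names(genomicRegions) %in% gKeptIds]
  eRows <- ests[ests$id %in% eKeptIds, , drop = FALSE]
  if (nrow(eRows)) {
    eGr <- GenomicRanges::GRanges(
      eRows$id,
      IRanges::IRanges(1L, nchar(eRows$seq)),
      strand = ifelse(is.na(eRows$orf_strand), "*", eRows$orf_strand))
    names(eGr) <- eRows$id
    S4Vectors::mcols(eGr) <- S4Vectors::DataFrame(
      supportingSources = IRanges::CharacterList(
        rep(list("tobacco_est"), nrow(eRows))),
      score = rep(1L, nrow(eRows)),
      shortPenalized = nchar(eRows$seq) < params@shortExonPenaltyLen,
      repeatOverlapFrac = rep(0, nrow(eRows)),
      origin = rep("est", nrow(eRows)))
    allGr <- suppressWarnings(c(GenomicRanges::GRanges(gOut), eGr))
  } else {
    allGr <- GenomicRanges::GRanges(gOut)
  }
  ledgerV <- c(
    genomic_in = length(genomicRegions),
    est_in = nrow(ests),
    est_te_filtered = tally("te_filtered"),
    est_redundant = tally("redundant"),
    est_no_orf = tally("no_orf"),
    est_kept = tally("kept") ,
    genomic_redundant = nGenomicDropped,
    genomic_kept = length(genomicRegions) - nGenomicDropped,
    final = (length(genomicRegions) - nGenomicDropped) + tally("kept"))
  new("CandidateSet",
      regions = new("ExonicRegions", allGr),
      ledger = setNames(as.integer(ledgerV), names(ledgerV)),
      estStatus = ests[c("id", "status")])
}
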