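#' Select probes for one exon candidate
#'
#' Picks \code{probesPerExon} probe windows spread across the exon.
#' Candidate windows must be uppercase ACGT only (soft-masked or
#' ambiguous positions disqualify a window) and must not contain any
#' k-mer marked non-unique in the optional background index. Windows with
#' GC fraction in \[0.3, 0.7\] are preferred. When the exon is long enough
#' (\code{probesPerExon x probeLen}) the probes are non-overlapping;
#' shorter exons fall back to overlapping windows and the probeset is
#' flagged. Selection is deterministic and uses no randomness.
#'
#' @param exonSeq named character scalar: the exon sequence (name = exon
#'   id).
#' @param params a [DesignParams] (probe length and count).
#' @param backgroundKmers optional character vector of k-mers that must
#'   not occur in any probe (all of one length).
#' @param gcRange preferred GC window.
#' @return a [ProbeSet].
#' @export
selectProbes <- function(exonSeq, params = designParams(),
                         backgroundKmers = NULL, gcRange = c(0.3, 0.7)) {
  exonId <- if (is.null(names(exonSeq))) "exon" else names(exonSeq)
  seq <- unname(exonSeq)
  plen <- params@probeLen
  n <- params@probesPerExon
  L <- nchar(seq)
  if (L < plen) stop("exon shorter than probe length")
  offs <- seq_len(L - plen + 1L)
  wins <- substring(seq, offs, offs + plen - 1L)
  valid <- !grepl("[^ACGT]", wins)
  if (!is.null(backgroundKmers) && length(backgroundKmers)) {
    bgK <- nchar(backgroundKmers[1L])
    banned <- vapply(wins, function(w) {
      kk <- .kmerStrings(w, bgK)
      any(kk %in% backgroundKmers)
    }, logical(1))
    valid <- valid & !banned
  }
  gc <- vapply(wins, gcFraction, numeric(1), USE.NAMES = FALSE)
  gcOk <- !is.na(gc) & gc >= gcRange[1L] & gc <= gcRange[2L]
  targets <- round(seq(1L, L - plen + 1L, length.out = n))
  chosen <- integer(0)
  disjoint <- L >= n * plen
  for (i in seq_len(n)) {
    cand <- offs[valid]
    cand <- setdiff(cand, chosen)
    if (disjoint) {
      lo <- if (length(chosen)) max(chosen) + plen else 1L
      hi <- L - plen + 1L - (n - i) * plen
      cand <- cand[cand >= lo & cand <= hi]
    }
    if (!length(cand)) next
    pref <- cand[gcOk[cand]]
    pick <- if (length(pref)) pref else cand
    chosen <- c(chosen, pick[which.min(abs(pick - targets[i]))])
  }
  probesDf <- data.frame(offset = chosen, length = rep(plen, length(chosen)),
                         sequence = wins[chosen], gc = gc[chosen],
                         stringsAsFactors = FALSE)
  new("ProbeSet", exonId = exonId, probes = probesDf,
      complete = length(chosen) == n,
      overlapping = !disjoint && length(chosen) > 0L,
      probesPerExon = n)
}

#' Probeset accounting
#'
#' Totals over a collection of probesets. When every probeset is
#' complete, the probe total equals \code{probesPerExon} times the
#' probeset count.
#'
#' @param probesets a list of [ProbeSet] objects, or an integer vector of
#'   per-probeset probe counts.
#' @return list with \code{nProbesets} and \code{nProbes}.
#' @export
#' @examples
#' probesetAccounting(rep(4L, 10))
probesetAccounting <- function(probesets) {
  if (is.numeric(probesets)) {
    counts <- as.integer(probesets)
  } else {
    counts <- vapply(probesets, function(ps) {
      stopifnot(is(ps, "ProbeSet"))
      nrow(probes(ps))
    }, integer(1))
  }
  list(nProbesets = length(counts), nProbes = sum(counts))
}
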