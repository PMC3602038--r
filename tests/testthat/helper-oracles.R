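# Independent oracles used across the suite. Each one recomputes the
# quantity under test by a different route than the package (brute-force
# scans, positionwise bitmaps, Biostrings local alignment).

randSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# brute-force local alignment presence check: is there an (ungapped) local
# alignment of query (either strand) vs any library record with width >=
# minLen and identity >= minIdentity?  Gaps are priced out so the dynamic
# programme is effectively ungapped.
oracleHasLocalHit <- function(query, library, minIdentity, minLen) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -3)
  tryAln <- function(q) {
    for (s in library) {
      aln <- Biostrings::pairwiseAlignment(
        q, s, type = "local", substitutionMatrix = mat,
        gapOpening = 1000, gapExtension = 1000)
      w <- Biostrings::nchar(Biostrings::pattern(aln))
      if (w >= minLen && Biostrings::pid(aln) >= 100 * minIdentity) {
        return(TRUE)
      }
    }
    FALSE
  }
  tryAln(query) || tryAln(exonforge::revComp(query))
}

# exhaustive tandem-array finder: for each period, locate maximal full-copy
# arrays with a backreference regex, then extend over a partial trailing
# copy character by character; qualifying arrays are unioned.
oracleTandem <- function(seq, minPeriod = 1L, maxPeriod = 6L,
                         minTotalLen = 18L, minCopies = 4) {
  n <- nchar(seq)
  ch <- strsplit(seq, "")[[1]]
  ivs <- list()
  for (p in seq.int(minPeriod, maxPeriod)) {
    m <- gregexpr(sprintf("([ACGTN]{%d})\\1+", p), seq, perl = TRUE)[[1]]
    if (m[1L] == -1L) next
    for (i in seq_along(m)) {
      a <- m[i]
      b <- a + attr(m, "match.length")[i] - 1L
      while (b < n && ch[b + 1L] == ch[b + 1L - p]) b <- b + 1L
      total <- b - a + 1L
      if (total >= minTotalLen && total / p >= minCopies) {
        ivs[[length(ivs) + 1L]] <- c(a, b)
      }
    }
  }
  if (!length(ivs)) return(IRanges::IRanges())
  df <- do.call(rbind, ivs)
  IRanges::reduce(IRanges::IRanges(df[, 1L], df[, 2L]))
}

# brute-force 6-frame ORF search: walk codons from every ATG to the first
# stop, both strands, and keep the longest (ties: plus strand, then
# smallest forward start)
oracleLongestOrf <- function(seq, minOrfLen = 150L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  best <- NULL
  consider <- function(start, end, strand) {
    len <- end - start + 1L
    if (len < minOrfLen) return()
    cand <- list(start = start, end = end, strand = strand, len = len)
    if (is.null(best) || cand$len > best$len ||
        (cand$len == best$len &&
           (cand$strand == "+" && best$strand == "-")) ||
        (cand$len == best$len && cand$strand == best$strand &&
           cand$start < best$start)) {
      best <<- cand
    }
  }
  scan <- function(s, strand) {
    ns <- nchar(s)
    for (i in seq_len(max(0L, ns - 2L))) {
      if (substr(s, i, i + 2L) != "ATG") next
      j <- i
      while (j + 2L <= ns) {
        cod <- substr(s, j, j + 2L)
        if (cod %in% c("TAA", "TAG", "TGA") && j > i) {
          if (strand == "+") consider(i, j + 2L, "+")
          else consider(n - (j + 2L) + 1L, n - i + 1L, "-")
          break
        }
        j <- j + 3L
      }
    }
  }
  scan(seq, "+")
  scan(exonforge::revComp(seq), "-")
  if (is.null(best)) NULL else best[c("start", "end", "strand")]
}

# positionwise union of supporting evidence tracks on one contig
oracleConsensusRuns <- function(tracks, contig, contigLen, minExonLen) {
  cov <- logical(contigLen)
  for (gr in tracks) {
    gr <- gr[as.character(GenomicRanges::seqnames(gr)) == contig]
    for (i in seq_along(gr)) {
      cov[GenomicRanges::start(gr)[i]:GenomicRanges::end(gr)[i]] <- TRUE
    }
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minExonLen
  IRanges::IRanges(starts[keep], ends[keep])
}

# positionwise covered fraction of [start, end] by mask intervals
oracleOverlapFraction <- function(start, end, maskStarts, maskEnds) {
  pos <- logical(end - start + 1L)
  for (i in seq_along(maskStarts)) {
    a <- max(start, maskStarts[i])
    b <- min(end, maskEnds[i])
    if (a <= b) pos[(a - start + 1L):(b - start + 1L)] <- TRUE
  }
  mean(pos)
}
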