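# Seed-and-extend ungapped matcher.
#
# All library screens (vector, contaminant/organelle, complex-repeat,
# redundancy) share this core: shared 12-mers seed diagonals, and on every
# seeded diagonal the optimal contiguous segment(s) satisfying an identity
# floor are found exactly from the run-length structure of the match vector
# (an optimal segment always starts and ends on a match run). Ungapped
# matching is sufficient for the screens this package performs (planted or
# near-identical copies); accuracy at desk scale is checked against a
# local-alignment oracle in the test suite.

.kmerStrings <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  p <- seq_len(n - k + 1L)
  substring(s, p, p + k - 1L)
}

# named character library (uppercased) -> list kmer -> data.frame(seq, pos)
.buildKmerIndex <- function(libChr, k) {
  pieces <- lapply(seq_along(libChr), function(i) {
    km <- .kmerStrings(libChr[[i]], k)
    if (!length(km)) return(NULL)
    data.frame(kmer = km, seq = i, pos = seq_along(km),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, pieces)
  if (is.null(df) || !nrow(df)) return(list())
  split(df[c("seq", "pos")], df$kmer)
}

# high-identity contiguous segments on one diagonal, found by X-drop
# extension (+1 match, -3 mismatch; stop when the running score falls
# xDrop below its maximum) from every exact-match run. The score trims
# each segment at the true copy boundary instead of drifting into
# flanking chance matches. mv: logical match vector; returns
# data.frame(start, end, matches) in mv coordinates.
.diagSegments <- function(mv, minIdentity, minLen, allHits = FALSE,
                          xDrop = 12L) {
  r <- rle(mv)
  nr <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  trueIdx <- which(r$values)
  if (!length(trueIdx)) return(NULL)
  extend <- function(i, step) {
    # walk (mismatch run, match run) pairs outward from seed run i;
    # returns c(extraMatches, boundary) at the best-scoring stop point
    score <- 0L
    bestScore <- 0L
    bestMatches <- 0L
    bestBoundary <- if (step > 0L) ends[i] else starts[i]
    matches <- 0L
    j <- i + step
    while (j >= 1L && j <= nr && !r$values[j]) {
      if (j + step < 1L || j + step > nr) break
      score <- score - 3L * r$lengths[j]
      if (bestScore - score > xDrop) break
      k <- j + step
      score <- score + r$lengths[k]
      matches <- matches + r$lengths[k]
      if (score > bestScore) {
        bestScore <- score
        bestMatches <- matches
        bestBoundary <- if (step > 0L) ends[k] else starts[k]
      }
      j <- k + step
    }
    c(bestMatches, bestBoundary)
  }
  segs <- lapply(trueIdx, function(i) {
    rt <- extend(i, 1L)
    lt <- extend(i, -1L)
    c(start = lt[2L], end = rt[2L],
      matches = r$lengths[i] + lt[1L] + rt[1L])
  })
  df <- unique(as.data.frame(do.call(rbind, segs)))
  len <- df$end - df$start + 1L
  ok <- len >= minLen & df$matches / len >= minIdentity
  df <- df[ok, , drop = FALSE]
  if (!nrow(df)) return(NULL)
  if (!allHits) {
    len <- df$end - df$start + 1L
    score <- df$matches - 3L * (len - df$matches)
    df <- df[order(-score, -len), , drop = FALSE][1L, , drop = FALSE]
  }
  rownames(df) <- NULL
  df
}

# query (character scalar, uppercase) vs library (list of char vectors)
# index: prebuilt k-mer index of the library
# returns data.frame(lib, qstart, qend, sstart, send, matches, length,
#                    identity, strand)
.seedExtendHits <- function(query, libChars, index, k, minIdentity, minLen,
                            strand = "+", allHits = FALSE) {
  qkm <- .kmerStrings(query, k)
  if (!length(qkm) || !length(index)) return(NULL)
  present <- which(qkm %in% names(index))
  if (!length(present)) return(NULL)
  seeds <- do.call(rbind, lapply(present, function(qi) {
    hit <- index[[qkm[qi]]]
    data.frame(lib = hit$seq, qi = qi, d = hit$pos - qi)
  }))
  seeds <- unique(seeds[c("lib", "d")])
  qch <- strsplit(query, "")[[1]]
  rows <- list()
  for (idx in seq_len(nrow(seeds))) {
    li <- seeds$lib[idx]
    d <- seeds$d[idx]
    sch <- libChars[[li]]
    ns <- length(sch)
    a <- max(1L, 1L - d)
    b <- min(length(qch), ns - d)
    if (b - a + 1L < minLen) next
    mv <- qch[a:b] == sch[(a + d):(b + d)]
    mv[qch[a:b] == "N" | sch[(a + d):(b + d)] == "N"] <- FALSE
    segs <- .diagSegments(mv, minIdentity, minLen, allHits = allHits)
    if (is.null(segs)) next
    segs$qstart <- segs$start + a - 1L
    segs$qend <- segs$end + a - 1L
    segs$sstart <- segs$qstart + d
    segs$send <- segs$qend + d
    segs$lib <- li
    rows[[length(rows) + 1L]] <- segs
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df$length <- df$qend - df$qstart + 1L
  df$identity <- df$matches / df$length
  df$strand <- strand
  # the same segment can be seeded from several k-mers
  df <- unique(df[c("lib", "qstart", "qend", "sstart", "send", "matches",
                    "length", "identity", "strand")])
  df
}

# strand-aware hits of one query against a library (named character).
# coordinates are always on the forward query.
.libraryHits <- function(query, library, k = 12L, minIdentity = 0.96,
                         minLen = 30L, allHits = FALSE, index = NULL) {
  libUp <- toupper(.asSeqChar(library))
  if (is.null(index)) index <- .buildKmerIndex(libUp, k)
  libChars <- lapply(libUp, function(s) strsplit(s, "")[[1]])
  qUp <- toupper(query)
  nq <- nchar(qUp)
  fwd <- .seedExtendHits(qUp, libChars, index, k, minIdentity, minLen,
                         strand = "+", allHits = allHits)
  rcq <- revComp(qUp)
  rev <- .seedExtendHits(rcq, libChars, index, k, minIdentity, minLen,
                         strand = "-", allHits = allHits)
  if (!is.null(rev) && nrow(rev)) {
    qs <- nq - rev$qend + 1L
    qe <- nq - rev$qstart + 1L
    rev$qstart <- qs
    rev$qend <- qe
  }
  out <- rbind(fwd, rev)
  if (is.null(out) || !nrow(out)) return(NULL)
  out$libId <- names(libUp)[out$lib]
  out
}
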