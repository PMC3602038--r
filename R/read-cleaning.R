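#' Screen a read against a vector library
#'
#' Finds the best strand-aware match of the read against any record of the
#' vector library (both strands are searched). A hit qualifies when it
#' reaches \code{minHitLen} anywhere in the read, or the shorter
#' \code{minHitLenEnd} when it touches the terminal \code{endWindow} bases
#' (cloning-vector remnants sit at read ends, so terminal hits are accepted
#' at a shorter length, as sequence-cleaning tools conventionally do).
#'
#' @param read single named character: the read sequence (name = read id).
#' @param vectorLibrary named character vector (or XStringSet) of vector
#'   sequences.
#' @param minIdentity minimum identity of the matched segment.
#' @param minHitLen minimum internal hit length (bp).
#' @param minHitLenEnd minimum hit length near read ends (bp).
#' @param endWindow how close to a read end a hit must come to qualify at
#'   \code{minHitLenEnd}.
#' @param index optional prebuilt k-mer index (internal reuse).
#' @return a list describing the best hit (\code{readId}, \code{libId},
#'   \code{start}, \code{end} 1-based on the read, \code{identity},
#'   \code{strand}, \code{kind}) or \code{NULL} when nothing qualifies.
#' @export
screenVector <- function(read, vectorLibrary, minIdentity = 0.96,
                         minHitLen = 60L, minHitLenEnd = 30L,
                         endWindow = 30L, index = NULL) {
  if (!nzchar(read)) stop("empty read")
  if (!length(vectorLibrary)) stop("empty vector library")
  hits <- .libraryHits(read, vectorLibrary, minIdentity = minIdentity,
                       minLen = minHitLenEnd, index = index)
  if (is.null(hits)) return(NULL)
  nq <- nchar(read)
  atEnd <- hits$qstart <= endWindow | hits$qend >= nq - endWindow + 1L
  ok <- hits$length >= minHitLen | (atEnd & hits$length >= minHitLenEnd)
  hits <- hits[ok, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  best <- hits[order(-hits$length, -hits$identity), , drop = FALSE][1L, ]
  list(readId = if (is.null(names(read))) NA_character_ else names(read),
       libId = best$libId, start = best$qstart, end = best$qend,
       identity = best$identity, strand = best$strand, kind = "vector")
}

#' Screen a read against reference genomes (contaminant or organelle)
#'
#' Like [screenVector()] but the read itself must be covered by the match:
#' the best hit must span at least \code{minCov} of the read length. Used
#' for bacterial contamination and organellar (mitochondrial/plastid)
#' read removal, where whole reads originate from the reference.
#'
#' @inheritParams screenVector
#' @param referenceSet named character vector (or XStringSet) of reference
#'   sequences.
#' @param minCov minimum fraction of the read covered by the hit.
#' @param kind label recorded on the hit (e.g. \code{"contaminant"} or
#'   \code{"organelle"}).
#' @return best qualifying hit as in [screenVector()], or \code{NULL}.
#' @export
screenReference <- function(read, referenceSet, minIdentity = 0.96,
                            minCov = 0.8, kind = "contaminant",
                            index = NULL) {
  if (!nzchar(read)) stop("empty read")
  if (!length(referenceSet)) return(NULL)
  nq <- nchar(read)
  minLen <- as.integer(ceiling(minCov * nq))
  hits <- .libraryHits(read, referenceSet, minIdentity = minIdentity,
                       minLen = minLen, index = index)
  if (is.null(hits)) return(NULL)
  hits <- hits[hits$length >= minCov * nq, , drop = FALSE]
  if (!nrow(hits)) return(NULL)
  best <- hits[order(-hits$length, -hits$identity), , drop = FALSE][1L, ]
  list(readId = if (is.null(names(read))) NA_character_ else names(read),
       libId = best$libId, start = best$qstart, end = best$qend,
       identity = best$identity, strand = best$strand, kind = kind)
}

#' Fraction of undetermined bases in a read
#'
#' @param read character scalar; must be non-empty.
#' @return fraction of characters that are not A, C, G or T
#'   (case-insensitive). The removal rule is strictly greater than the
#'   \code{maxAmbiguityFrac} threshold, so a read at exactly 3\% N is kept.
#' @export
#' @examples
#' ambiguityFraction(paste(c(rep("A", 97), rep("N", 3)), collapse = ""))
ambiguityFraction <- function(read) {
  if (!nzchar(read)) stop("empty read")
  ch <- strsplit(toupper(read), "")[[1]]
  sum(!ch %in% c("A", "C", "G", "T")) / length(ch)
}

#' Trim read ends
#'
#' Removes \code{endTrim} bases from each end unconditionally (terminal
#' bases of single-pass reads are unreliable and may carry masked
#' sequence), then re-applies the minimum-length rule: if the remainder is
#' shorter than \code{minReadLen} the read is a trim casualty.
#'
#' @param read character scalar.
#' @param endTrim bases removed from each end.
#' @param minReadLen minimum length of the trimmed read.
#' @return trimmed sequence, or \code{NULL} when the remainder is too
#'   short.
#' @export
trimEnds <- function(read, endTrim = 60L, minReadLen = 100L) {
  n <- nchar(read)
  if (n <= 2L * endTrim) return(NULL)
  out <- substr(read, endTrim + 1L, n - endTrim)
  if (nchar(out) < minReadLen) return(NULL)
  out
}

#' Clean GSS reads through the full cascade with ledger accounting
#'
#' Applies the cleaning cascade in a fixed order -- vector, contaminant,
#' organelle, short-read, ambiguity, end trim -- removing each read at the
#' first stage that claims it, so the per-category counts are disjoint and
#' the ledger conserves totals exactly.
#'
#' @param reads named character vector of read sequences (unique ids).
#' @param libraries list with optional elements \code{vectors},
#'   \code{contaminants}, \code{organelles}: named character vectors of
#'   library sequences. A missing element disables that screen.
#' @param params a [DesignParams].
#' @param minIdentity identity threshold for all screens.
#' @param minCov read-coverage threshold for the reference screens.
#' @return list with \code{kept} (named character vector of trimmed kept
#'   reads) and \code{ledger} (a [CleaningLedger]).
#' @export
cleanReads <- function(reads, libraries = list(), params = designParams(),
                       minIdentity = 0.96, minCov = 0.8) {
  if (anyDuplicated(names(reads))) stop("duplicate read ids")
  n <- length(reads)
  removed <- setNames(integer(length(CLEANING_CATEGORIES)),
                      CLEANING_CATEGORIES)
  kept <- character(0)
  idxV <- if (!is.null(libraries$vectors))
    .buildKmerIndex(toupper(.asSeqChar(libraries$vectors)), 12L)
  idxC <- if (!is.null(libraries$contaminants))
    .buildKmerIndex(toupper(.asSeqChar(libraries$contaminants)), 12L)
  idxO <- if (!is.null(libraries$organelles))
    .buildKmerIndex(toupper(.asSeqChar(libraries$organelles)), 12L)
  for (id in names(reads)) {
    r <- reads[[id]]
    if (!is.null(libraries$vectors) &&
        !is.null(screenVector(setNames(r, id), libraries$vectors,
                              minIdentity = minIdentity, index = idxV))) {
      removed[["vector"]] <- removed[["vector"]] + 1L
      next
    }
    if (!is.null(libraries$contaminants) &&
        !is.null(screenReference(setNames(r, id), libraries$contaminants,
                                 minIdentity = minIdentity, minCov = minCov,
                                 kind = "contaminant", index = idxC))) {
      removed[["contaminant"]] <- removed[["contaminant"]] + 1L
      next
    }
    if (!is.null(libraries$organelles) &&
        !is.null(screenReference(setNames(r, id), libraries$organelles,
                                 minIdentity = minIdentity, minCov = minCov,
                                 kind = "organelle", index = idxO))) {
      removed[["organelle"]] <- removed[["organelle"]] + 1L
      next
    }
    if (nchar(r) < params@minReadLen) {
      removed[["short"]] <- removed[["short"]] + 1L
      next
    }
    if (ambiguityFraction(r) > params@maxAmbiguityFrac) {
      removed[["ambiguous"]] <- removed[["ambiguous"]] + 1L
      next
    }
    tr <- trimEnds(r, endTrim = params@endTrim,
                   minReadLen = params@minReadLen)
    if (is.null(tr)) {
      removed[["trim_casualty"]] <- removed[["trim_casualty"]] + 1L
      next
    }
    kept[[id]] <- tr
  }
  list(kept = kept,
       ledger = cleaningLedger(n, removed, keptCount = length(kept)))
}
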