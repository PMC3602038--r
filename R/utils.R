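#' @import methods
#' @import GenomicRanges
#' @importFrom stats rnorm runif sd setNames quantile median coef predict aggregate
#' @importFrom utils head read.delim write.table
#' @importFrom withr with_seed
NULL

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

#' Coerce sequence input to a named character vector
#'
#' Accepts a character vector or any [Biostrings::XStringSet] and returns a
#' plain named character vector. Character vectors are used throughout the
#' package so that lowercase soft-masking survives every operation
#' (`DNAStringSet` normalises case).
#'
#' @param x character vector or XStringSet.
#' @return named character vector of sequences.
#' @keywords internal
#' @noRd
.asSeqChar <- function(x) {
  if (is(x, "XStringSet")) {
    out <- as.character(x)
  } else if (is.character(x)) {
    out <- x
  } else {
    stop("sequences must be a character vector or an XStringSet")
  }
  out
}

.checkIUPAC <- function(seqs, where = "sequence") {
  bad <- vapply(seqs, function(s) {
    ch <- unique(strsplit(toupper(s), "")[[1]])
    any(!ch %in% IUPAC_CHARS)
  }, logical(1))
  if (any(bad)) {
    stop("non-IUPAC character in ", where, ": ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  invisible(TRUE)
}

#' Reverse complement preserving case
#'
#' @param seq character scalar (IUPAC nucleotides, case carries mask state).
#' @return reverse complement with lowercase masking preserved.
#' @export
#' @examples
#' revComp("ACgtN")  # "NacGT"
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  comp <- chartr("ACGTURYSWKMBDHVNacgturyswkmbdhvn",
                 "TGCAAYRSWMKVHDBNtgcaayrswmkvhdbn", seq)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

#' GC fraction of a sequence window
#'
#' @param seq character scalar.
#' @return fraction of G/C among A/C/G/T characters (case-insensitive).
#' @export
gcFraction <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  acgt <- ch %in% c("A", "C", "G", "T")
  if (!any(acgt)) return(NA_real_)
  sum(ch[acgt] %in% c("G", "C")) / sum(acgt)
}

# uniform random DNA; local RNG state is the caller's responsibility
.randSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# mutate a sequence at exactly n positions (substitutions to a different base)
.mutateSeq <- function(seq, n) {
  ch <- strsplit(seq, "")[[1]]
  if (n == 0L) return(seq)
  pos <- sample(seq_along(ch), n)
  for (p in pos) {
    ch[p] <- sample(setdiff(c("A", "C", "G", "T"), toupper(ch[p])), 1L)
  }
  paste(ch, collapse = "")
}
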