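#' Read a FASTA file with an optional phred quality file
#'
#' Sequences are returned as a named character vector so that lowercase
#' (soft-masked) letters are preserved verbatim. When a companion phred
#' \code{.qual} file is given, records must appear in the same order with
#' identical ids and one quality value per base.
#'
#' @param fastaPath path to a FASTA file.
#' @param qualPath optional path to a phred \code{.qual} file.
#' @return a list with elements \code{bases} (named character vector) and
#'   \code{quals} (named list of integer vectors, or \code{NULL} when no
#'   quality file was given).
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT"), fa)
#' readFastaQual(fa)$bases
readFastaQual <- function(fastaPath, qualPath = NULL) {
  if (!file.exists(fastaPath)) stop("FASTA file not found: ", fastaPath)
  ss <- Biostrings::readBStringSet(fastaPath)
  bases <- as.character(ss)
  names(bases) <- sub("\\s.*$", "", names(bases))
  if (anyDuplicated(names(bases))) {
    stop("duplicate read ids in ", fastaPath)
  }
  .checkIUPAC(bases, where = basename(fastaPath))
  quals <- NULL
  if (!is.null(qualPath)) {
    if (!file.exists(qualPath)) stop("qual file not found: ", qualPath)
    quals <- .readPhredQual(qualPath)
    if (!identical(names(bases), names(quals))) {
      fastaOnly <- setdiff(names(bases), names(quals))
      qualOnly <- setdiff(names(quals), names(bases))
      stop("fasta/qual id mismatch: fasta-only {",
           paste(fastaOnly, collapse = ","), "} qual-only {",
           paste(qualOnly, collapse = ","), "}")
    }
    nb <- nchar(bases)
    nq <- lengths(quals)
    if (any(nb != nq)) {
      bad <- names(bases)[nb != nq][1L]
      stop("quality length differs from sequence length for record ", bad)
    }
  }
  list(bases = bases, quals = quals)
}

# phred .qual: FASTA-style headers, whitespace-separated integers over any
# number of lines (no installed package reads this format)
.readPhredQual <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (length(lines) && !hdr[1L]) stop("malformed qual file: ", path)
  rec <- cumsum(hdr)
  ids <- sub("\\s.*$", "", sub("^>", "", lines[hdr]))
  vals <- lapply(split(lines[!hdr], rec[!hdr]), function(ll) {
    as.integer(scan(text = paste(ll, collapse = " "), quiet = TRUE))
  })
  # records with no value lines (empty sequence) still need a slot
  out <- rep(list(integer(0)), length(ids))
  names(out) <- ids
  present <- as.integer(names(vals))
  out[present] <- vals
  out
}

#' Write sequences to FASTA (and optionally phred qualities)
#'
#' @param bases named character vector of sequences (case preserved).
#' @param path output FASTA path.
#' @param quals optional named list of integer vectors, written alongside
#'   to \code{qualPath}.
#' @param qualPath output path for qualities.
#' @return invisibly, \code{path}.
#' @export
writeFasta <- function(bases, path, quals = NULL, qualPath = NULL) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(bases), path)
  if (!is.null(quals)) {
    if (is.null(qualPath)) qualPath <- sub("\\.[^.]*$", ".qual", path)
    con <- file(qualPath, "w")
    on.exit(close(con))
    for (id in names(quals)) {
      writeLines(c(paste0(">", id), paste(quals[[id]], collapse = " ")), con)
    }
  }
  invisible(path)
}

#' Import a GFF3 evidence track
#'
#' Features are returned as a \code{GRanges} (1-based closed coordinates,
#' the native convention of the container; GFF3 is 1-based inclusive so the
#' import is a coordinate identity). Strandless features (\code{.}) map to
#' \code{*}. A \code{source_id} metadata column labels every interval with
#' the evidence source.
#'
#' @param path GFF3 file.
#' @param sourceLabel evidence source id attached to all intervals.
#' @return a \code{GRanges} with metadata column \code{source_id}.
#' @export
readGff3Track <- function(path, sourceLabel) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) {
                   stop("GFF3 format error in ", path, ": ",
                        conditionMessage(e))
                 })
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source_id = rep(sourceLabel, length(gr)))
  gr
}

#' Write / read genomic intervals as BED
#'
#' BED is 0-based half-open on disk; \code{GRanges} are 1-based closed in
#' memory. \code{rtracklayer} performs the conversion, so a write/read
#' round-trip is the identity on coordinates.
#'
#' @param gr a \code{GRanges}.
#' @param path output (or input) BED path.
#' @return \code{writeBed} invisibly returns \code{path}; \code{readBed}
#'   returns a \code{GRanges}.
#' @export
writeBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' @rdname writeBed
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  rtracklayer::import(path, format = "bed")
}

#' Write / read a cleaning ledger as TSV
#'
#' Columns \code{category} and \code{count}; the \code{input} and
#' \code{kept} rows bracket the per-category removals so the file is a
#' lossless round-trip of the ledger.
#'
#' @param ledgerObj a [CleaningLedger].
#' @param path TSV path.
#' @return \code{writeTsvLedger} invisibly returns \code{path};
#'   \code{readTsvLedger} returns a [CleaningLedger].
#' @export
writeTsvLedger <- function(ledgerObj, path) {
  stopifnot(is(ledgerObj, "CleaningLedger"))
  df <- data.frame(
    category = c("input", names(removedCounts(ledgerObj)), "kept"),
    count = c(inputCount(ledgerObj), unname(removedCounts(ledgerObj)),
              keptCount(ledgerObj)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsvLedger
#' @export
readTsvLedger <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  counts <- setNames(df$count, df$category)
  cleaningLedger(counts[["input"]],
                 counts[setdiff(names(counts), c("input", "kept"))],
                 keptCount = counts[["kept"]])
}
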