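#' Default Illumina small-RNA 3' adapter
#'
#' The standard TruSeq small RNA 3' adapter; ligated downstream of the
#' insert, so the insert is everything before its first occurrence.
#' @export
SMALL_RNA_ADAPTER <- "TGGAATTCTCGGGTGCCAAGG"

#' Trim the 3' sequencing adapter from reads
#'
#' Searches each read for the leftmost exact occurrence of the first
#' `min_overlap` bases of the adapter and removes everything from that
#' position to the read end.  Reads without a match are returned unmodified
#' and flagged, since the insert may fill the whole read.
#'
#' @param seqs Character vector of read sequences (ACGT or ACGU).
#' @param adapter Adapter sequence; only its first `min_overlap` bases are
#'   required to match (0 mismatches).
#' @param min_overlap Minimum adapter prefix length that must match
#'   (`>= 6`, default 8).
#' @return A list with `trimmed` (character vector) and `found` (logical
#'   vector, `FALSE` where no adapter was detected or the read was empty).
#' @examples
#' trimAdapter("ACGTACGTTGGAATTCTCGGGTGCC", adapter = "TGGAATTCTCGG")
#' @export
trimAdapter <- function(seqs, adapter = SMALL_RNA_ADAPTER, min_overlap = 8L) {
  stopifnot(min_overlap >= 6L, nchar(adapter) >= min_overlap)
  seqs <- toupper(as.character(seqs))
  probe <- toupper(substr(adapter, 1L, min_overlap))
  pos <- regexpr(probe, seqs, fixed = TRUE)
  found <- pos > 0L & nzchar(seqs)
  trimmed <- ifelse(found, substr(seqs, 1L, pos - 1L), seqs)
  list(trimmed = trimmed, found = found)
}

#' Collapse reads into unique sequences with counts
#'
#' Discards reads shorter than `min_len` nucleotides and collapses the
#' survivors so that every distinct sequence becomes one entry whose count
#' is the number of times that molecule was sequenced.  DNA input is
#' normalized to RNA (`T` -> `U`) so downstream comparison against RNA
#' references is uniform.  The result is order-invariant: any permutation of
#' the input yields the same object.
#'
#' @param seqs Character vector of (trimmed) read sequences.
#' @param min_len Minimum read length retained (default 15).
#' @param sample_id Sample identifier stored on the result.
#' @param n_no_adapter Tally of reads lacking an adapter, carried through
#'   from [trimAdapter()].
#' @return A [UniqueReadSet-class].
#' @export
collapseReads <- function(seqs, min_len = 15L, sample_id = "sample",
                          n_no_adapter = 0L) {
  stopifnot(min_len >= 1L)
  seqs <- chartr("Tt", "Uu", toupper(as.character(seqs)))
  n_raw <- length(seqs)
  keep <- seqs[nchar(seqs) >= min_len]
  counts <- integer(0)
  if (length(keep)) {
    tab <- table(keep)
    counts <- as.integer(tab)
    names(counts) <- names(tab)
    # deterministic order: most abundant first, ties by sequence
    ord <- order(-counts, names(counts))
    counts <- counts[ord]
  }
  new("UniqueReadSet", sample_id = sample_id, counts = counts,
      n_raw = as.integer(n_raw), n_pass = as.integer(sum(counts)),
      n_no_adapter = as.integer(n_no_adapter), min_len = as.integer(min_len))
}

#' Preprocess a FASTQ file into unique read counts
#'
#' Runs the per-sample read preprocessing used before isomiR calling:
#' adapter trimming, deletion of reads shorter than `min_len` nucleotides,
#' and collapsing of identical sequences into unique reads with counts.
#'
#' @param path FASTQ file (optionally gzipped).
#' @param adapter,min_overlap Passed to [trimAdapter()].
#' @param min_len Passed to [collapseReads()].
#' @param discard_untrimmed Drop reads in which no adapter was found
#'   (default `FALSE`: such reads are kept, the insert may fill the read).
#' @param sample_id Sample identifier; defaults to the file base name.
#' @return A [UniqueReadSet-class].
#' @export
preprocessFastq <- function(path, adapter = SMALL_RNA_ADAPTER,
                            min_len = 15L, min_overlap = 8L,
                            discard_untrimmed = FALSE,
                            sample_id = sub("\\.(fastq|fq)(\\.gz)?$", "",
                                            basename(path))) {
  reads <- as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  tr <- trimAdapter(reads, adapter = adapter, min_overlap = min_overlap)
  seqs <- tr$trimmed
  if (discard_untrimmed) seqs <- seqs[tr$found]
  urs <- collapseReads(seqs, min_len = min_len, sample_id = sample_id,
                       n_no_adapter = sum(!tr$found))
  urs@n_raw <- length(reads)
  validObject(urs)
  urs
}

#' Write / read collapsed unique reads as TSV
#'
#' The TSV has columns `sequence`, `count`; processing tallies are written
#' alongside as a small JSON log (`<path>.json`).
#'
#' @param urs A [UniqueReadSet-class].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
writeUniqueReads <- function(urs, path) {
  cnt <- readCounts(urs)
  utils::write.table(
    data.frame(sequence = names(cnt), count = as.integer(cnt)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sample_id = urs@sample_id, n_raw = urs@n_raw, n_pass = urs@n_pass,
         n_no_adapter = urs@n_no_adapter, min_len = urs@min_len),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeUniqueReads
#' @param sample_id Sample id for the reloaded object; defaults to the value
#'   in the JSON log when present.
#' @export
readUniqueReads <- function(path, sample_id = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  log_path <- paste0(path, ".json")
  meta <- if (file.exists(log_path)) jsonlite::read_json(log_path) else list()
  counts <- as.integer(df$count)
  names(counts) <- df$sequence
  new("UniqueReadSet",
      sample_id = sample_id %||% meta$sample_id %||% basename(path),
      counts = counts,
      n_raw = as.integer(meta$n_raw %||% sum(counts)),
      n_pass = as.integer(sum(counts)),
      n_no_adapter = as.integer(meta$n_no_adapter %||% 0L),
      min_len = as.integer(meta$min_len %||% min(nchar(df$sequence), 15L)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
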