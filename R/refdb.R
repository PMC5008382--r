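#' Load a hairpin reference from FASTA plus a mature-coordinate table
#'
#' Reads precursor hairpin sequences from FASTA (`T` or `U` accepted, stored
#' as RNA) and a tab-separated annotation table giving, for each mature
#' miRNA, its hairpin and its 0-based half-open coordinates on that hairpin.
#'
#' @param hairpin_fasta Path to a FASTA file of hairpin sequences.
#' @param mature_table Path to a TSV with columns
#'   `mirna_id, hairpin_id, start, end, arm`.
#' @return A validated [ReferenceSet-class].
#' @export
loadReference <- function(hairpin_fasta, mature_table) {
  seqs <- Biostrings::readBStringSet(hairpin_fasta)
  # keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  ma <- utils::read.delim(mature_table, stringsAsFactors = FALSE)
  ReferenceSet(as.character(seqs), ma)
}

#' Write a ReferenceSet to FASTA + TSV
#'
#' Inverse of [loadReference()]: round-tripping through these files yields
#' an identical `ReferenceSet`.
#'
#' @param ref A [ReferenceSet-class].
#' @param hairpin_fasta,mature_table Output paths.
#' @return Invisibly, `ref`.
#' @export
writeReference <- function(ref, hairpin_fasta, mature_table) {
  Biostrings::writeXStringSet(hairpins(ref), hairpin_fasta)
  utils::write.table(matureAnnotations(ref), mature_table, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(ref)
}

#' Templated continuation of a hairpin
#'
#' Returns up to `n` nucleotides of the hairpin starting at 0-based position
#' `pos` — the sequence a templated 3' elongation would have.  Used to decide
#' whether trailing read bases are templated or non-templated additions.
#'
#' @param ref A [ReferenceSet-class].
#' @param hairpin_id Hairpin name.
#' @param pos 0-based start position, `0 <= pos <= hairpin length`.
#' @param n Maximum number of nucleotides to return; the result is shorter
#'   than `n` only where the hairpin 3' end is reached.
#' @return RNA character string (possibly empty at the hairpin 3' end).
#' @examples
#' ref <- makeToyReference()
#' templatedSuffix(ref, "hp-mir-21-like", 26, 2)  # "GG"
#' @export
templatedSuffix <- function(ref, hairpin_id, pos, n) {
  hp <- hairpins(ref)
  if (!hairpin_id %in% names(hp))
    stop("unknown hairpin_id: ", hairpin_id)
  len <- Biostrings::width(hp)[match(hairpin_id, names(hp))]
  if (pos < 0 || pos > len)
    stop("pos must be in [0, hairpin length] for ", hairpin_id)
  if (n <= 0 || pos == len) return("")
  substr(as.character(hp[[hairpin_id]]), pos + 1L, min(pos + n, len))
}

#' Canonical mature sequence of a miRNA
#'
#' @param ref A [ReferenceSet-class].
#' @param mirna_id Mature miRNA id present in the annotation table.
#' @return The hairpin substring `[start, end)` as an RNA character string.
#' @export
canonicalSequence <- function(ref, mirna_id) {
  ma <- matureAnnotations(ref)
  i <- match(mirna_id, ma$mirna_id)
  if (is.na(i)) stop("unknown mirna_id: ", mirna_id)
  substr(as.character(hairpins(ref)[[ma$hairpin_id[i]]]),
         ma$start[i] + 1L, ma$end[i])
}

#' Import miRBase-style GFF3 annotations relative to hairpins
#'
#' Optional reader converting a miRBase GFF3 (genomic, 1-based inclusive
#' coordinates; `miRNA` features carrying a `Derives_from` pointer to their
#' `miRNA_primary_transcript`) into the hairpin-relative 0-based half-open
#' convention used by [ReferenceSet()].  Mature arms are labelled `5p`/`3p`
#' from the name when present, otherwise by position on the hairpin.
#'
#' @param gff3 Path to the GFF3 file.
#' @param hairpin_fasta FASTA of the hairpin sequences named by the primary
#'   transcript `Name` (or `ID`).
#' @return A [ReferenceSet-class].
#' @export
readMirbaseGff3 <- function(gff3, hairpin_fasta) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("readMirbaseGff3 requires the rtracklayer package")
  gr <- rtracklayer::import(gff3)
  md <- S4Vectors::mcols(gr)
  nameOf <- function(x) ifelse(!is.na(x$Name) & nzchar(x$Name), x$Name, x$ID)
  is_hp <- md$type == "miRNA_primary_transcript"
  hp <- gr[is_hp]
  mat <- gr[md$type == "miRNA"]
  hp_names <- nameOf(S4Vectors::mcols(hp))
  hp_id_key <- S4Vectors::mcols(hp)$ID
  der <- S4Vectors::mcols(mat)$Derives_from
  idx <- match(der, hp_id_key)
  if (anyNA(idx))
    stop("miRNA feature(s) without matching primary transcript: ",
         paste(nameOf(S4Vectors::mcols(mat))[is.na(idx)], collapse = ", "))
  strand_hp <- as.character(BiocGenerics::strand(hp))[idx]
  hp_start <- BiocGenerics::start(hp)[idx]
  hp_end <- BiocGenerics::end(hp)[idx]
  # hairpin-relative, strand-aware: position 0 is the hairpin 5' end
  rel_start <- ifelse(strand_hp == "-",
                      hp_end - BiocGenerics::end(mat),
                      BiocGenerics::start(mat) - hp_start)
  rel_end <- rel_start + BiocGenerics::width(mat)
  mat_names <- nameOf(S4Vectors::mcols(mat))
  arm <- ifelse(grepl("-5p$", mat_names), "5p",
                ifelse(grepl("-3p$", mat_names), "3p", NA))
  seqs <- Biostrings::readBStringSet(hairpin_fasta)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  hp_len <- nchar(as.character(seqs))[match(hp_names[idx], names(seqs))]
  arm[is.na(arm)] <- ifelse(rel_start[is.na(arm)] < hp_len[is.na(arm)] / 2,
                            "5p", "3p")
  ReferenceSet(as.character(seqs),
               data.frame(mirna_id = mat_names,
                          hairpin_id = hp_names[idx],
                          start = rel_start, end = rel_end, arm = arm,
                          stringsAsFactors = FALSE))
}
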