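#' Isoform key used to index count matrices
#'
#' @param mirna_id,d5,d3,nta_tail Vectors describing isomiR calls.
#' @return Character vector `"mirna|d5|d3|tail"`; distinct NTA tails (e.g.
#'   `U` vs `UU`) are distinct features.
#' @export
isoformKey <- function(mirna_id, d5, d3, nta_tail) {
  paste(mirna_id, d5, d3, nta_tail, sep = "|")
}

#' Build isoform-level and summed-miRNA count matrices
#'
#' From per-sample isomiR calls, assembles (i) an isoform-level matrix keyed
#' by the full `(mirna, d5, d3, tail)` identity and (ii) a summed matrix in
#' which all reads mapping to a miRNA are added up, the two quantification
#' levels used throughout the analysis.  Features absent from a sample get
#' a zero count.
#'
#' @param call_list Named list (`sample_id` -> calls `data.frame` from
#'   [callSample()]).
#' @return List with elements `isoform` and `mature` — each a
#'   [SummarizedExperiment::SummarizedExperiment] with a `counts` assay;
#'   the isoform object carries `mirna_id`, `d5`, `d3`, `nta_tail` and
#'   `variant_class` in its `rowData` and both carry their level in
#'   `metadata(x)$level`.
#' @export
buildMatrices <- function(call_list) {
  stopifnot(length(call_list) >= 1L)
  samples <- names(call_list)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("call_list must be named by sample_id")
  if (anyDuplicated(samples))
    stop("duplicate sample_id: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  aug <- lapply(samples, function(s) {
    df <- call_list[[s]]
    if (nrow(df))
      data.frame(sample = s,
                 key = isoformKey(df$mirna_id, df$d5, df$d3, df$nta_tail),
                 df, stringsAsFactors = FALSE)
    else NULL
  })
  all <- do.call(rbind, aug)
  if (is.null(all)) stop("no aligned reads in any sample")
  feats <- sort(unique(all$key))
  iso <- matrix(0L, nrow = length(feats), ncol = length(samples),
                dimnames = list(feats, samples))
  # a (key, sample) pair can occur once per unique sequence; accumulate
  ij <- cbind(match(all$key, feats), match(all$sample, samples))
  for (r in seq_len(nrow(all))) iso[ij[r, 1L], ij[r, 2L]] <-
      iso[ij[r, 1L], ij[r, 2L]] + all$count[r]
  first <- all[!duplicated(all$key), ]
  rd <- S4Vectors::DataFrame(
    mirna_id = first$mirna_id[match(feats, first$key)],
    d5 = first$d5[match(feats, first$key)],
    d3 = first$d3[match(feats, first$key)],
    nta_tail = first$nta_tail[match(feats, first$key)],
    variant_class = first$variant_class[match(feats, first$key)],
    row.names = feats)
  iso_se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = iso), rowData = rd,
    metadata = list(level = "isoform"))
  mat <- rowsum(iso, group = as.character(rd$mirna_id))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  storage.mode(mat) <- "integer"
  mat_se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat), metadata = list(level = "mature_summed"))
  list(isoform = iso_se, mature = mat_se)
}

#' Reads-per-million normalization over miRNA-mapped totals
#'
#' Scales each sample's counts to reads per million using the total number
#' of miRNA-mapped reads of that sample as the denominator — never the raw
#' read yield, so the value is independent of sequencing depth and of the
#' relative frequency of other small-RNA classes.  Because every aligned
#' read belongs to exactly one isoform and one miRNA, the summed-level
#' column totals equal the isoform-level totals and the same denominator
#' serves both levels.
#'
#' @param se A `SummarizedExperiment` from [buildMatrices()] (either level).
#' @param totals Optional per-sample miRNA-mapped totals (named or in
#'   column order); defaults to `colSums(counts)`.
#' @return The input with an additional `rpm` assay; each column of `rpm`
#'   sums to 1e6 when the level is complete.
#' @export
rpmNormalize <- function(se, totals = NULL) {
  cnt <- SummarizedExperiment::assay(se, "counts")
  if (is.null(totals)) totals <- colSums(cnt)
  if (!is.null(names(totals))) totals <- totals[colnames(cnt)]
  zero <- totals <= 0
  if (any(zero))
    stop("sample(s) with zero miRNA-mapped reads: ",
         paste(colnames(cnt)[zero], collapse = ", "))
  SummarizedExperiment::assay(se, "rpm") <-
    sweep(cnt, 2L, totals, "/") * 1e6
  se
}

#' Read-length distribution of one miRNA's isomiRs
#'
#' Count-weighted relative frequency of read lengths among all isomiRs of a
#' miRNA — the per-miRNA size profile that shifts when, e.g., a 23-nt
#' elongated isoform replaces the 22-nt canonical form as the dominant
#' species.
#'
#' @param calls Calls `data.frame` (one sample, or several `rbind`-ed).
#' @param mirna_id miRNA to profile.
#' @return Named numeric vector mapping length (nt) to relative frequency;
#'   sums to 1.
#' @export
lengthDistribution <- function(calls, mirna_id) {
  sel <- calls[calls$mirna_id == mirna_id, , drop = FALSE]
  if (!nrow(sel)) stop("no calls for mirna_id: ", mirna_id)
  tot <- tapply(sel$count, sel$length, sum)
  out <- as.numeric(tot) / sum(sel$count)
  names(out) <- names(tot)
  out
}
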