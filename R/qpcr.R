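#' Read a Ct table
#'
#' @param path TSV with columns `sample_id`, `assay_id`, `ct` (missing Ct
#'   values may be absent rows or `NA`).
#' @return `data.frame` with those columns.
#' @export
readCtTable <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay_id", "ct")
  if (!all(need %in% colnames(df)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  df
}

#' Pooled-control reference Ct per assay
#'
#' Emulates a physical pool of control-sample cDNA: the per-assay reference
#' Ct is the arithmetic mean of the control samples' Ct values (a pool
#' approximates the mean on the cycle scale); missing control values are
#' skipped.
#'
#' @param ct Ct `data.frame` (`sample_id`, `assay_id`, `ct`).
#' @param control_ids Sample ids of the control group.
#' @param fun Aggregation across control Cts; `mean` (default).  A
#'   geometric-style alternative differs only by convention and can be
#'   supplied here.
#' @return Named numeric vector: assay_id -> reference Ct.
#' @export
pooledReference <- function(ct, control_ids, fun = mean) {
  assays <- unique(ct$assay_id)
  ctrl <- ct[ct$sample_id %in% control_ids & !is.na(ct$ct), , drop = FALSE]
  ref <- vapply(assays, function(a) {
    v <- ctrl$ct[ctrl$assay_id == a]
    if (!length(v)) return(NA_real_)
    fun(v)
  }, numeric(1))
  if (anyNA(ref))
    stop("no control Ct for assay(s): ",
         paste(assays[is.na(ref)], collapse = ", "))
  ref
}

#' Delta-Ct normalization to a reference, on the natural-log scale
#'
#' Computes `delta_ct = ct - reference` per assay and the natural-log
#' expression `ln_expr = -delta_ct * ln(2)` — the natural logarithm of the
#' fold change `2^(-delta_ct)` relative to the reference, so that one fewer
#' cycle (2-fold more template) raises `ln_expr` by exactly `ln 2` and a
#' sample at the reference Ct has `ln_expr = 0`.  Missing Ct values
#' propagate as `NA`, never silently imputed.
#'
#' @param ct Ct `data.frame` (`sample_id`, `assay_id`, `ct`).
#' @param reference Named per-assay reference Ct from [pooledReference()]
#'   (or zeros, to treat an already delta-Ct'd table as its own scale).
#' @return `data.frame` with `sample_id`, `assay_id`, `delta_ct`,
#'   `ln_expr`.
#' @export
normalizeDeltaCt <- function(ct, reference) {
  missing_ref <- setdiff(unique(ct$assay_id), names(reference))
  if (length(missing_ref))
    stop("no reference Ct for assay(s): ",
         paste(missing_ref, collapse = ", "))
  ref <- reference[ct$assay_id]
  delta <- ct$ct - ref
  data.frame(sample_id = ct$sample_id, assay_id = ct$assay_id,
             delta_ct = as.numeric(delta),
             ln_expr = as.numeric(-delta * log(2)),
             stringsAsFactors = FALSE)
}

#' Reshape an expression table to a samples x assays matrix
#'
#' @param expr Output of [normalizeDeltaCt()].
#' @param value Column to spread (default `"ln_expr"`).
#' @return Numeric matrix, rows = samples, columns = assays; absent
#'   combinations are `NA`.
#' @export
toExpressionMatrix <- function(expr, value = "ln_expr") {
  samples <- unique(expr$sample_id)
  assays <- unique(expr$assay_id)
  m <- matrix(NA_real_, length(samples), length(assays),
              dimnames = list(samples, assays))
  m[cbind(match(expr$sample_id, samples), match(expr$assay_id, assays))] <-
    expr[[value]]
  m
}
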