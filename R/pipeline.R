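.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeBin(serialize(x, NULL, version = 2L), f)
  unname(tools::md5sum(f))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

.resolveClinical <- function(x) {
  if (is.character(x)) x <- utils::read.delim(x, stringsAsFactors = FALSE)
  x <- as.data.frame(x)
  if (!all(c("sample_id", "label") %in% colnames(x)))
    stop("clinical table needs columns sample_id, label")
  x
}

#' Pipeline configuration
#'
#' Collects the inputs and options of the two orchestrated entry points.
#' Paths are checked when the pipeline runs.
#'
#' @param reference A [ReferenceSet-class], or a
#'   `list(fasta = ..., table = ...)` of paths for [loadReference()].
#' @param fastq_dir Directory of per-sample FASTQ files (discovery phase).
#' @param clinical Clinical table (`sample_id`, `label`, optionally `psa`)
#'   or a TSV path.
#' @param ct_table Ct table (`sample_id`, `assay_id`, `ct`) or TSV path
#'   (validation phase).
#' @param preset Candidate-selection preset, `"methods"` or `"results"`
#'   (see [candidatePreset()]).
#' @param policy An [alignPolicy()].
#' @param adapter,min_len,min_overlap,discard_untrimmed Preprocessing
#'   options (see [preprocessFastq()]).
#' @param log_psa Use ln(PSA) in PSA-containing panel models.
#' @param seed Seed recorded in the run manifest.
#' @return List of class `PipelineConfig`.
#' @export
pipelineConfig <- function(reference = NULL, fastq_dir = NULL,
                           clinical = NULL, ct_table = NULL,
                           preset = c("methods", "results"),
                           policy = alignPolicy(),
                           adapter = SMALL_RNA_ADAPTER, min_len = 15L,
                           min_overlap = 8L, discard_untrimmed = FALSE,
                           log_psa = TRUE, seed = 1L) {
  structure(list(reference = reference, fastq_dir = fastq_dir,
                 clinical = clinical, ct_table = ct_table,
                 preset = match.arg(preset), policy = policy,
                 adapter = adapter, min_len = as.integer(min_len),
                 min_overlap = as.integer(min_overlap),
                 discard_untrimmed = discard_untrimmed,
                 log_psa = log_psa, seed = as.integer(seed)),
            class = "PipelineConfig")
}

.resolveReference <- function(reference) {
  if (inherits(reference, "ReferenceSet")) return(reference)
  if (is.list(reference) && all(c("fasta", "table") %in% names(reference))) {
    for (p in unlist(reference[c("fasta", "table")]))
      if (!file.exists(p)) stop("reference path does not exist: ", p)
    return(loadReference(reference$fasta, reference$table))
  }
  stop("reference must be a ReferenceSet or list(fasta=, table=)")
}

#' Run the discovery phase: reads to differential isomiR candidates
#'
#' Orchestrates preprocessing, isomiR calling, quantification and NB
#' differential abundance for a sequencing cohort:
#' trim/filter/collapse each FASTQ, call isomiRs, build isoform and
#' summed-miRNA matrices, RPM-normalize, estimate dispersions, run the
#' likelihood-ratio test, select candidates under the configured preset,
#' and summarize the isoform occurrence of significant changes.  Any stage
#' failure aborts with the stage name.
#'
#' @param cfg A [pipelineConfig()] with `reference`, `fastq_dir` and
#'   `clinical` set; FASTQ base names must match clinical `sample_id`s.
#' @return List: `matrices` (isoform + mature `SummarizedExperiment`s with
#'   `rpm` assays), `diff_table`, `candidates`, `occurrence`,
#'   `length_distributions` (per panel miRNA), `unaligned` tallies, and
#'   `manifest` (config hash, seed, versions).
#' @export
runDiscovery <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  ref <- .stage("config", {
    if (is.null(cfg$fastq_dir) || !dir.exists(cfg$fastq_dir))
      stop("fastq_dir does not exist: ", cfg$fastq_dir)
    if (is.null(cfg$clinical)) stop("clinical table required")
    .resolveReference(cfg$reference)
  })
  clinical <- .stage("config", .resolveClinical(cfg$clinical))
  files <- list.files(cfg$fastq_dir, pattern = "\\.(fastq|fq)(\\.gz)?$",
                      full.names = TRUE)
  if (!length(files)) stop("stage 'config': no FASTQ files in fastq_dir")
  urs_list <- .stage("preprocess", lapply(files, function(f)
    preprocessFastq(f, adapter = cfg$adapter, min_len = cfg$min_len,
                    min_overlap = cfg$min_overlap,
                    discard_untrimmed = cfg$discard_untrimmed)))
  names(urs_list) <- vapply(urs_list, function(u) u@sample_id, character(1))
  calls <- .stage("call", lapply(urs_list, callSample, ref = ref,
                                 policy = cfg$policy))
  mats <- .stage("quantify", {
    m <- buildMatrices(calls)
    totals <- colSums(SummarizedExperiment::assay(m$isoform, "counts"))
    list(isoform = rpmNormalize(m$isoform, totals),
         mature = rpmNormalize(m$mature, totals))
  })
  diff <- .stage("diffexp", {
    idx <- match(colnames(mats$isoform), clinical$sample_id)
    if (anyNA(idx))
      stop("samples missing from clinical table: ",
           paste(colnames(mats$isoform)[is.na(idx)], collapse = ", "))
    groups <- factor(ifelse(clinical$label[idx] == 1, "cancer", "control"),
                     levels = c("control", "cancer"))
    cnt <- SummarizedExperiment::assay(mats$isoform, "counts")
    disp <- estimateNBDispersions(cnt, groups)
    lrtTest(cnt, groups, disp,
            variant_class = SummarizedExperiment::rowData(
              mats$isoform)$variant_class)
  })
  pre <- candidatePreset(cfg$preset)
  candidates <- selectCandidates(diff, min_abs_log2fc = pre$min_abs_log2fc,
                                 max_p = pre$max_p,
                                 inclusive = pre$inclusive)
  occurrence <- isoformOccurrence(diff)
  panel <- intersect(panelAssays("mature")$mirna_id,
                     unlist(lapply(calls, function(d) d$mirna_id)))
  all_calls <- do.call(rbind, calls)
  ld <- lapply(stats::setNames(panel, panel),
               function(m) lengthDistribution(all_calls, m))
  list(matrices = mats, diff_table = diff, candidates = candidates,
       occurrence = occurrence, length_distributions = ld,
       unaligned = vapply(calls, attr, numeric(1), "unaligned"),
       manifest = runManifest(cfg))
}

#' Run the validation phase: Ct table to the five-model panel report
#'
#' Normalizes the Ct table by delta-Ct against the pooled control
#' reference, transforms to natural-log expression, and evaluates the
#' five panel models by LOOCV logistic regression, ROC and operating
#' points.
#'
#' @param cfg A [pipelineConfig()] with `ct_table` and `clinical` set
#'   (clinical must carry `psa` for the PSA models).
#' @param models Model list, default [panelModels()].
#' @return A `PanelReport` (see [evaluatePanels()]) with the run manifest
#'   in its `manifest` element.
#' @export
runValidation <- function(cfg, models = panelModels()) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  ct <- .stage("config", {
    if (is.null(cfg$ct_table)) stop("ct_table required")
    if (is.character(cfg$ct_table)) readCtTable(cfg$ct_table)
    else as.data.frame(cfg$ct_table)
  })
  clinical <- .stage("config", .resolveClinical(cfg$clinical))
  expr <- .stage("qpcr_norm", {
    controls <- clinical$sample_id[clinical$label == 0]
    ref_ct <- pooledReference(ct, controls)
    normalizeDeltaCt(ct, ref_ct)
  })
  report <- .stage("diagnostics",
                   evaluatePanels(expr, clinical, models = models,
                                  log_psa = cfg$log_psa))
  report$manifest <- runManifest(cfg)
  report
}

#' Run manifest
#'
#' Deterministic provenance record: hash of the configuration, the seed,
#' and package/R versions.  Re-running with the same configuration yields
#' an identical hash.
#'
#' @param cfg A [pipelineConfig()].
#' @return List `(config_hash, seed, package_version, r_version)`.
#' @export
runManifest <- function(cfg) {
  list(config_hash = .hashObject(unclass(cfg)),
       seed = cfg$seed,
       package_version = as.character(utils::packageVersion("isomiRdx")),
       r_version = paste(R.version$major, R.version$minor, sep = "."))
}
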