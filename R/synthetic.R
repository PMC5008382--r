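# derive a secondary stream seed without leaving 32-bit integer range
.deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) + k) %% 2147483647)
}

#' The three-hairpin toy reference plus random decoys
#'
#' Builds a synthetic [ReferenceSet-class] whose first three hairpins mimic
#' mir-21, mir-204 and mir-375: each embeds the canonical mature sequence of
#' miR-21-5p, miR-204-5p or miR-375 with 4-nt flanks, so the published
#' urine-EV isomiR assay sequences are classifiable without any database
#' download.  The remaining `n_mirnas - 3` hairpins are random decoys with
#' valid 5p annotations, 8-nt flanks, and a 3' flank starting with G or C so
#' that simulated NTA-U / NTA-A isoforms are always non-templated.  The
#' fixtures are seed-independent; only the decoys change with `seed`.
#'
#' @param seed RNG seed for the decoys (default 1).
#' @param n_mirnas Total number of miRNAs including the 3 fixtures
#'   (default 30).
#' @return A [ReferenceSet-class].
#' @export
makeToyReference <- function(seed = 1L, n_mirnas = 30L) {
  stopifnot(n_mirnas >= 3L)
  fix_seqs <- c(
    "hp-mir-21-like"  = "AAAAUAGCUUAUCAGACUGAUGUUGAGGGG",
    "hp-mir-204-like" = "GCACUUCCCUUUGUCAUCCUAUGCCUGUCA",
    "hp-mir-375-like" = "ACGCUUUGUUCGUUCGGCUCGCGUGACCGC")
  fix_ma <- data.frame(
    mirna_id = c("miR-21-5p", "miR-204-5p", "miR-375"),
    hairpin_id = names(fix_seqs),
    start = 4L, end = 26L, arm = "5p",
    stringsAsFactors = FALSE)
  n_dec <- n_mirnas - 3L
  if (n_dec > 0L) {
    set.seed(seed)
    alphabet <- c("A", "C", "G", "U")
    dec <- vapply(seq_len(n_dec), function(i) {
      mature <- paste(sample(alphabet, 22L, replace = TRUE), collapse = "")
      f5 <- paste(sample(alphabet, 8L, replace = TRUE), collapse = "")
      f3 <- paste(c(sample(c("G", "C"), 1L),
                    sample(alphabet, 7L, replace = TRUE)), collapse = "")
      paste0(f5, mature, f3)
    }, character(1))
    names(dec) <- sprintf("hp-sim-%03d", seq_len(n_dec))
    dec_ma <- data.frame(
      mirna_id = sprintf("miR-sim-%03d", seq_len(n_dec)),
      hairpin_id = names(dec),
      start = 8L, end = 30L, arm = "5p",
      stringsAsFactors = FALSE)
    fix_seqs <- c(fix_seqs, dec)
    fix_ma <- rbind(fix_ma, dec_ma)
  }
  ReferenceSet(fix_seqs, fix_ma)
}

#' The six-assay diagnostic panel
#'
#' The mature and isomiR stem-loop assay targets of the miR-21-5p /
#' miR-204-5p / miR-375 panel.  Mature assays target the canonical
#' sequences; the isomiR assays are named by their target sequences: the
#' 2-nt-trimmed miR-21-5p, the 1-nt-trimmed miR-375 and the 23-nt
#' (+1 templated elongation) miR-204-5p variant.
#'
#' @param type `"all"` (default), `"mature"` or `"isomir"`.
#' @return `data.frame` with `assay_id`, `mirna_id`, `d5`, `d3`,
#'   `nta_tail`, `type` and the isoform `key`.
#' @export
panelAssays <- function(type = c("all", "mature", "isomir")) {
  type <- match.arg(type)
  df <- data.frame(
    assay_id = c("miR-21-5p", "miR-204-5p", "miR-375",
                 "UAGCUUAUCAGACUGAUGUU",
                 "UUCCCUUUGUCAUCCUAUGCCUG",
                 "UUUGUUCGUUCGGCUCGCGUG"),
    mirna_id = c("miR-21-5p", "miR-204-5p", "miR-375",
                 "miR-21-5p", "miR-204-5p", "miR-375"),
    d5 = 0L,
    d3 = c(0L, 0L, 0L, -2L, 1L, -1L),
    nta_tail = "",
    type = rep(c("mature", "isomir"), each = 3L),
    stringsAsFactors = FALSE)
  df$key <- isoformKey(df$mirna_id, df$d5, df$d3, df$nta_tail)
  if (type == "all") df else df[df$type == type, , drop = FALSE]
}

#' Default planted effects of the paper-like preset
#'
#' In the cancer group: the +1-elongated miR-204-like isoform up 3-fold
#' (miR-204 mature unchanged), the trimmed miR-21-like / miR-375-like
#' isomiRs down 4-fold, and a weak (1.7-fold) decrease of the miR-21 /
#' miR-375 mature isoforms — so the mature panel is weakly informative
#' while the isomiR panel is strongly informative, the structure the
#' analysis is designed to resolve.
#'
#' @return List of effects `(mirna, isoform, fold)`; `fold < 1` means
#'   decreased in cancer.
#' @export
paperEffects <- function() {
  list(list(mirna = "miR-204-5p", isoform = "elong1", fold = 3),
       list(mirna = "miR-21-5p", isoform = "trim2", fold = 0.25),
       list(mirna = "miR-375", isoform = "trim1", fold = 0.25),
       list(mirna = "miR-21-5p", isoform = "mature", fold = 0.6),
       list(mirna = "miR-375", isoform = "mature", fold = 0.6))
}

#' Simulation configuration
#'
#' Defaults are the paper-like discovery preset: 4 control vs 9 cancer
#' samples, NB dispersion 0.2, a global 0.7x decrease of miRNA yield in
#' cancer, the [paperEffects()] isoform shifts, lognormal PSA with partial
#' group separation (large-n PSA-alone AUC near 0.7) and Gaussian Ct noise.
#' Use `n_control = 26, n_cancer = 48` for the validation-phase preset.
#'
#' @param n_control,n_cancer Group sizes.
#' @param n_mirnas Number of miRNAs (3 fixtures + decoys).
#' @param reads_per_sample Expected miRNA read yield of a control sample
#'   (default 1e6, the per-sample miRNA-mapped yield of a typical small-RNA
#'   sequencing run of this design).
#' @param dispersion NB dispersion `phi` (`variance = mean + phi mean^2`);
#'   `0` gives Poisson counts.
#' @param isomir_alpha Dirichlet concentrations over the isoform types
#'   `(mature, trim1, trim2, elong1, ntaU, ntaA)`.
#' @param planted_effects List of `(mirna, isoform, fold)` applied in the
#'   cancer group.
#' @param global_cancer_scale Multiplier (`<= 1`) on cancer samples' total
#'   miRNA yield.
#' @param psa_lognormal `c(mu0, mu1, sigma)` of log-PSA for control/cancer.
#' @param ct_noise_sd Gaussian noise (cycles) on simulated Ct values;
#'   the default 2.5 stands in for the large inter-patient biological
#'   variability of biofluid-EV qPCR on top of the planted group shifts.
#' @param ct_intercept Ct of a transcript at 0 RPM (default 38 cycles).
#' @param seed RNG seed.
#' @return Validated list of class `SimConfig`.
#' @export
simConfig <- function(n_control = 4L, n_cancer = 9L, n_mirnas = 30L,
                      reads_per_sample = 1000000L, dispersion = 0.2,
                      isomir_alpha = c(mature = 30, trim1 = 10, trim2 = 6,
                                       elong1 = 8, ntaU = 4, ntaA = 2),
                      planted_effects = paperEffects(),
                      global_cancer_scale = 0.7,
                      psa_lognormal = c(mu0 = log(6), mu1 = log(12),
                                        sigma = 0.9),
                      ct_noise_sd = 2.5, ct_intercept = 38, seed = 1L) {
  stopifnot(n_control > 0L, n_cancer > 0L, n_mirnas >= 3L,
            reads_per_sample > 0L, dispersion >= 0,
            all(isomir_alpha > 0), global_cancer_scale <= 1,
            global_cancer_scale > 0, psa_lognormal[["sigma"]] > 0,
            ct_noise_sd >= 0)
  for (e in planted_effects)
    if (is.null(e$fold) || e$fold <= 0) stop("planted fold changes must be > 0")
  structure(list(n_control = as.integer(n_control),
                 n_cancer = as.integer(n_cancer),
                 n_mirnas = as.integer(n_mirnas),
                 reads_per_sample = as.integer(reads_per_sample),
                 dispersion = dispersion, isomir_alpha = isomir_alpha,
                 planted_effects = planted_effects,
                 global_cancer_scale = global_cancer_scale,
                 psa_lognormal = psa_lognormal,
                 ct_noise_sd = ct_noise_sd, ct_intercept = ct_intercept,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

.ISO_DEFS <- data.frame(
  isoform = c("mature", "trim1", "trim2", "elong1", "ntaU", "ntaA"),
  d5 = 0L, d3 = c(0L, -1L, -2L, 1L, 0L, 0L),
  nta_tail = c("", "", "", "", "U", "A"),
  variant_class = c("mature", "trimming", "trimming", "elongation",
                    "NTA-U", "NTA-A"),
  stringsAsFactors = FALSE)

# feature table of constructible isoforms; errors on non-constructible
# *planted* isoforms, silently drops other non-constructible ones
.isoformFeatures <- function(ref, iso_names, planted) {
  ma <- matureAnnotations(ref)
  hp <- stats::setNames(as.character(hairpins(ref)), names(hairpins(ref)))
  defs <- .ISO_DEFS[.ISO_DEFS$isoform %in% iso_names, , drop = FALSE]
  planted_keys <- vapply(planted, function(e) paste(e$mirna, e$isoform),
                         character(1))
  rows <- list()
  for (i in seq_len(nrow(ma))) {
    h <- hp[[ma$hairpin_id[i]]]
    hlen <- nchar(h)
    for (j in seq_len(nrow(defs))) {
      d3 <- defs$d3[j]; tail <- defs$nta_tail[j]
      t_end <- ma$end[i] + d3
      ok <- t_end >= ma$start[i] + 15L && t_end <= hlen
      if (ok && nzchar(tail)) {
        # the tail must actually be non-templated
        nxt <- if (t_end < hlen) substr(h, t_end + 1L, t_end + 1L) else ""
        ok <- !identical(nxt, substr(tail, 1L, 1L))
      }
      pk <- paste(ma$mirna_id[i], defs$isoform[j])
      if (!ok) {
        if (pk %in% planted_keys)
          stop("planted isoform not constructible on its hairpin: ", pk)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = ma$mirna_id[i], isoform = defs$isoform[j],
        d5 = 0L, d3 = d3, nta_tail = tail,
        variant_class = defs$variant_class[j],
        sequence = paste0(substr(h, ma$start[i] + 1L, t_end), tail),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$key <- isoformKey(out$mirna_id, out$d5, out$d3, out$nta_tail)
  rownames(out) <- out$key
  out
}

#' Simulate a two-group urine-EV small-RNA cohort
#'
#' Generates a cohort with the statistical structure the analysis assumes:
#' per-miRNA baseline abundance is lognormal across miRNAs; each sample
#' splits every miRNA over its isoforms by a Dirichlet draw; planted
#' effects multiply designated isoform weights in the cancer group; the
#' cancer group's total miRNA yield is scaled by `global_cancer_scale`;
#' counts are negative-binomial around the expected values
#' (`variance = mean + phi mean^2`, Poisson when `phi = 0`); PSA is
#' lognormal per group.  Optionally the counts are emitted as per-sample
#' FASTQ files with the 3' adapter appended and constant Phred-40
#' qualities, so the whole pipeline (trim, collapse, call, quantify) can
#' run on them.
#'
#' Regeneration with the same config and seed is byte-identical.
#'
#' @param cfg A [simConfig()].
#' @param ref A [ReferenceSet-class]; default [makeToyReference()] with the
#'   config's seed and `n_mirnas`.
#' @param fastq_dir Directory to write one FASTQ per sample, or `NULL`
#'   (default) to skip read emission; truth tables are identical either
#'   way.
#' @return List of class `SyntheticCohort`: `counts` (features x samples,
#'   realized), `truth_rpm` (expected RPM), `features` (isoform table with
#'   sequences and classes), `clinical` (`sample_id`, `label`, `group`,
#'   `psa`), `groups`, `fastq` (paths or `NULL`), `config`.
#' @export
simulateCohort <- function(cfg, ref = makeToyReference(cfg$seed,
                                                       cfg$n_mirnas),
                           fastq_dir = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  feats <- .isoformFeatures(ref, names(cfg$isomir_alpha),
                            cfg$planted_effects)
  ma <- matureAnnotations(ref)
  n_mir <- nrow(ma)
  sample_ids <- c(sprintf("ctrl%02d", seq_len(cfg$n_control)),
                  sprintf("case%02d", seq_len(cfg$n_cancer)))
  groups <- factor(rep(c("control", "cancer"),
                       c(cfg$n_control, cfg$n_cancer)),
                   levels = c("control", "cancer"))
  set.seed(cfg$seed)
  w <- stats::setNames(exp(stats::rnorm(n_mir, 0, 1.5)), ma$mirna_id)
  alpha <- cfg$isomir_alpha
  eff <- stats::setNames(rep(1, nrow(feats)), feats$key)
  for (e in cfg$planted_effects) {
    k <- feats$key[feats$mirna_id == e$mirna & feats$isoform == e$isoform]
    eff[k] <- e$fold
  }
  counts <- matrix(0L, nrow(feats), length(sample_ids),
                   dimnames = list(feats$key, sample_ids))
  truth <- matrix(0, nrow(feats), length(sample_ids),
                  dimnames = list(feats$key, sample_ids))
  for (s in seq_along(sample_ids)) {
    props <- matrix(stats::rgamma(n_mir * length(alpha),
                                  shape = rep(alpha, each = n_mir)),
                    nrow = n_mir,
                    dimnames = list(ma$mirna_id, names(alpha)))
    props <- props / rowSums(props)
    pvec <- props[cbind(match(feats$mirna_id, ma$mirna_id),
                        match(feats$isoform, names(alpha)))]
    scale_g <- if (groups[s] == "cancer") cfg$global_cancer_scale else 1
    e_s <- cfg$reads_per_sample * scale_g *
      (w[feats$mirna_id] / sum(w)) * pvec
    if (groups[s] == "cancer") e_s <- e_s * eff
    counts[, s] <- as.integer(if (cfg$dispersion > 0)
      stats::rnbinom(length(e_s), mu = e_s, size = 1 / cfg$dispersion)
    else stats::rpois(length(e_s), e_s))
    truth[, s] <- e_s / sum(e_s) * 1e6
  }
  mu_psa <- ifelse(groups == "cancer",
                   cfg$psa_lognormal[["mu1"]], cfg$psa_lognormal[["mu0"]])
  psa <- stats::rlnorm(length(sample_ids), meanlog = mu_psa,
                       sdlog = cfg$psa_lognormal[["sigma"]])
  clinical <- data.frame(sample_id = sample_ids,
                         label = as.integer(groups == "cancer"),
                         group = as.character(groups),
                         psa = psa, stringsAsFactors = FALSE)
  fastq <- NULL
  if (!is.null(fastq_dir)) {
    if (!dir.exists(fastq_dir)) dir.create(fastq_dir, recursive = TRUE)
    dna <- chartr("Uu", "Tt", feats$sequence)
    fastq <- stats::setNames(
      file.path(fastq_dir, paste0(sample_ids, ".fastq")), sample_ids)
    for (s in seq_along(sample_ids)) {
      reads <- rep(paste0(dna, SMALL_RNA_ADAPTER), counts[, s])
      reads <- reads[sample.int(length(reads))]
      recs <- paste0("@", sample_ids[s], "_", seq_along(reads), "\n",
                     reads, "\n+\n", strrep("I", nchar(reads)))
      writeLines(recs, fastq[[s]])
    }
  }
  structure(list(counts = counts, truth_rpm = truth, features = feats,
                 clinical = clinical, groups = groups, fastq = fastq,
                 config = cfg),
            class = "SyntheticCohort")
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat("SyntheticCohort:", ncol(x$counts), "samples (",
      sum(x$groups == "control"), "control /",
      sum(x$groups == "cancer"), "cancer ),",
      nrow(x$counts), "isoform features\n")
  invisible(x)
}

#' Simulate stem-loop RT-qPCR measurement of a cohort
#'
#' Derives Ct values for the requested assays from the cohort's true
#' expected RPM: `Ct = ct_intercept - log2(RPM + 1) + N(0, ct_noise_sd)`,
#' so a doubling of true abundance lowers Ct by about one cycle and
#' `ct_noise_sd = 0` makes Ct exactly affine in log2 expression.
#'
#' @param cohort A [simulateCohort()] result.
#' @param assays Assay table as from [panelAssays()]; every assay `key`
#'   must exist in the cohort truth.
#' @param ct_noise_sd,ct_intercept Defaults taken from the cohort config.
#' @param seed RNG seed for the Ct noise; derived from the cohort seed by
#'   default.
#' @return List with `ct` (`sample_id`, `assay_id`, `ct`) and `clinical`
#'   (carried over from the cohort).
#' @export
simulateQpcr <- function(cohort, assays = panelAssays(),
                         ct_noise_sd = cohort$config$ct_noise_sd,
                         ct_intercept = cohort$config$ct_intercept,
                         seed = .deriveSeed(cohort$config$seed, 7919)) {
  missing <- setdiff(assays$key, rownames(cohort$truth_rpm))
  if (length(missing))
    stop("assay target(s) absent from cohort truth: ",
         paste(missing, collapse = ", "))
  set.seed(seed)
  samples <- colnames(cohort$truth_rpm)
  grid <- expand.grid(assay = seq_len(nrow(assays)),
                      sample = seq_along(samples))
  rpm <- cohort$truth_rpm[cbind(match(assays$key[grid$assay],
                                      rownames(cohort$truth_rpm)),
                                grid$sample)]
  ct <- ct_intercept - log2(rpm + 1) +
    stats::rnorm(length(rpm), 0, ct_noise_sd)
  list(ct = data.frame(sample_id = samples[grid$sample],
                       assay_id = assays$assay_id[grid$assay],
                       ct = ct, stringsAsFactors = FALSE),
       clinical = cohort$clinical)
}
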