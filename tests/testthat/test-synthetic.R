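test_that("the toy reference hosts the fixtures and well-formed decoys", {
  ref <- makeToyReference(seed = 1, n_mirnas = 12)
  ma <- matureAnnotations(ref)
  expect_true(all(c("miR-21-5p", "miR-204-5p", "miR-375") %in% ma$mirna_id))
  expect_identical(canonicalSequence(ref, "miR-21-5p"),
                   "UAGCUUAUCAGACUGAUGUUGA")
  # every decoy mature has a >= 4 nt 3' flank so +1 elongation is decidable
  hp_len <- Biostrings::width(hairpins(ref))[
    match(ma$hairpin_id, names(hairpins(ref)))]
  expect_true(all(hp_len - ma$end >= 4))
  # decoy flanks start with G or C: simulated NTA-U/A are non-templated
  decoys <- ma[grepl("^miR-sim", ma$mirna_id), ]
  for (i in seq_len(nrow(decoys)))
    expect_true(templatedSuffix(ref, decoys$hairpin_id[i],
                                decoys$end[i], 1) %in% c("G", "C"))
  # seeds change the decoys but never the fixtures
  ref2 <- makeToyReference(seed = 2, n_mirnas = 12)
  expect_identical(canonicalSequence(ref2, "miR-375"),
                   canonicalSequence(ref, "miR-375"))
  expect_false(identical(as.character(hairpins(ref2)),
                         as.character(hairpins(ref))))
})

test_that("cohort generation is byte-identical under a fixed seed", {
  cfg <- simConfig(n_control = 2, n_cancer = 3, n_mirnas = 8,
                   reads_per_sample = 5000, seed = 5)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  co1 <- simulateCohort(cfg, fastq_dir = d1)
  co2 <- simulateCohort(cfg, fastq_dir = d2)
  expect_identical(co1$counts, co2$counts)
  expect_identical(co1$truth_rpm, co2$truth_rpm)
  expect_identical(co1$clinical, co2$clinical)
  expect_identical(unname(tools::md5sum(co1$fastq)),
                   unname(tools::md5sum(co2$fastq)))
  # truth is the same whether or not reads are emitted
  co3 <- simulateCohort(cfg)
  expect_identical(co3$counts, co1$counts)
  expect_null(co3$fastq)
})

test_that("a 4-vs-9 config emits 13 FASTQ files with adapters appended", {
  cfg <- simConfig(n_mirnas = 5, reads_per_sample = 2000, seed = 7)
  dir <- file.path(tempdir(), "sim13")
  co <- simulateCohort(cfg, fastq_dir = dir)
  expect_length(co$fastq, 13L)
  expect_true(all(file.exists(co$fastq)))
  first <- readLines(co$fastq[[1]], n = 4)
  expect_match(first[2], "TGGAATTCTCGGGTGCCAAGG")
})

test_that("emitted read proportions converge to the sampled isoform split", {
  # Poisson emission: at 1e5 reads the multinomial noise is ~1e-3
  cfg <- simConfig(n_control = 1, n_cancer = 1, n_mirnas = 4,
                   reads_per_sample = 100000, dispersion = 0,
                   planted_effects = list(), seed = 8)
  co <- simulateCohort(cfg)
  for (s in colnames(co$counts)) {
    for (m in unique(co$features$mirna_id)) {
      rows <- co$features$mirna_id == m
      truth_p <- co$truth_rpm[rows, s] / sum(co$truth_rpm[rows, s])
      emp_p <- co$counts[rows, s] / sum(co$counts[rows, s])
      expect_lt(max(abs(emp_p - truth_p)), 0.02)
    }
  }
})

test_that("planted effects shift exactly the designated isoforms", {
  cfg <- simConfig(n_control = 40, n_cancer = 40, n_mirnas = 6,
                   reads_per_sample = 50000, dispersion = 0, seed = 9)
  co <- simulateCohort(cfg)
  ctrl <- co$groups == "control"
  mean_fc <- function(key)
    mean(co$truth_rpm[key, !ctrl]) / mean(co$truth_rpm[key, ctrl])
  expect_equal(mean_fc("miR-21-5p|0|-2|"), 0.25, tolerance = 0.15)
  expect_equal(mean_fc("miR-204-5p|0|1|"), 3, tolerance = 0.45)
  # the miR-204 canonical isoform stays put (RPM drifts only via the
  # renormalization over all planted effects)
  expect_equal(mean_fc("miR-204-5p|0|0|"), 1, tolerance = 0.15)
})

test_that("a planted isoform its hairpin cannot template is a hard error", {
  # mature flush with the hairpin 3' end: +1 elongation unconstructible
  ref <- ReferenceSet(c(hp = "AAAAUAGCUUAUCAGACUGAUGUUGA"),
                      data.frame(mirna_id = "miR-z", hairpin_id = "hp",
                                 start = 4L, end = 26L, arm = "5p"))
  cfg <- simConfig(n_control = 2, n_cancer = 2, n_mirnas = 3,
                   reads_per_sample = 1000,
                   planted_effects = list(list(mirna = "miR-z",
                                               isoform = "elong1",
                                               fold = 3)),
                   seed = 3)
  expect_error(simulateCohort(cfg, ref = ref), "miR-z elong1")
})

test_that("simulated Ct values are affine in log2 expression when noise-free", {
  cfg <- simConfig(n_control = 3, n_cancer = 3, n_mirnas = 6,
                   reads_per_sample = 50000, ct_noise_sd = 0, seed = 10)
  co <- simulateCohort(cfg)
  q <- simulateQpcr(co)
  assays <- panelAssays()
  for (r in seq_len(nrow(q$ct))) {
    i <- match(q$ct$assay_id[r], assays$assay_id)
    truth <- co$truth_rpm[assays$key[i], q$ct$sample_id[r]]
    expect_equal(q$ct$ct[r], cfg$ct_intercept - log2(truth + 1),
                 tolerance = 1e-10)
  }
  # the delta-Ct pipeline then recovers true log fold changes exactly
  ref_ct <- pooledReference(q$ct, co$clinical$sample_id[co$clinical$label == 0])
  expr <- normalizeDeltaCt(q$ct, ref_ct)
  i <- which(expr$sample_id == "case01" &
               expr$assay_id == "UAGCUUAUCAGACUGAUGUU")
  key <- assays$key[match("UAGCUUAUCAGACUGAUGUU", assays$assay_id)]
  ctrl_ids <- co$clinical$sample_id[co$clinical$label == 0]
  truth_ln <- mean(log(co$truth_rpm[key, "case01"] + 1)) -
    mean(log(co$truth_rpm[key, ctrl_ids] + 1))
  # reference pooling averages Ct (log2 scale), so compare on that scale
  expect_equal(expr$ln_expr[i],
               log(2) * (log2(co$truth_rpm[key, "case01"] + 1) -
                           mean(log2(co$truth_rpm[key, ctrl_ids] + 1))),
               tolerance = 1e-10)
})

test_that("matched PSA distributions make the PSA-only model uninformative", {
  cfg <- simConfig(n_control = 30, n_cancer = 40, n_mirnas = 5,
                   reads_per_sample = 20000,
                   psa_lognormal = c(mu0 = log(8), mu1 = log(8), sigma = 0.9),
                   seed = 12)
  co <- simulateCohort(cfg)
  q <- simulateQpcr(co)
  p <- loocvProbabilities(cbind(lnpsa = log(q$clinical$psa)),
                          q$clinical$label)
  auc <- rocCurve(p, q$clinical$label)$auc
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})
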