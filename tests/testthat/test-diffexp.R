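# small simulated matrices; group layout mirrors a 4-vs-9 cohort
null_nb <- function(G, phi, seed, n1 = 4L, n2 = 9L, mu_meanlog = 5) {
  set.seed(seed)
  mu <- exp(rnorm(G, mu_meanlog, 1.5))
  n <- n1 + n2
  Y <- if (phi > 0)
    matrix(rnbinom(G * n, mu = rep(mu, n), size = 1 / phi), G)
  else matrix(rpois(G * n, rep(mu, n)), G)
  rownames(Y) <- paste0("f", seq_len(G))
  list(Y = Y,
       groups = factor(rep(c("control", "cancer"), c(n1, n2)),
                       levels = c("control", "cancer")),
       offsets = rep(log(1e5), n))
}

test_that("dispersion estimation recovers the simulated overdispersion", {
  sim <- null_nb(600, phi = 0.2, seed = 11)
  d <- estimateNBDispersions(sim$Y, sim$groups, offsets = sim$offsets)
  expect_gte(commonDispersion(d), 0.15)
  expect_lte(commonDispersion(d), 0.25)
  expect_true(all(tagwiseDispersion(d) > 0, na.rm = TRUE))
  expect_identical(sum(is.na(tagwiseDispersion(d))),
                   sum(rowSums(sim$Y) == 0))

  simp <- null_nb(600, phi = 0, seed = 12)
  dp <- estimateNBDispersions(simp$Y, simp$groups, offsets = simp$offsets)
  expect_lte(commonDispersion(dp), 0.02)

  # constant matrix with equal offsets: no overdispersion detectable
  Yc <- matrix(50L, 100, 13, dimnames = list(paste0("f", 1:100), NULL))
  dc <- estimateNBDispersions(Yc, sim$groups, offsets = rep(0, 13))
  expect_lte(commonDispersion(dc), 1e-4)

  g_bad <- factor(rep(c("a", "b"), c(1, 12)))
  expect_error(estimateNBDispersions(sim$Y, g_bad, offsets = sim$offsets),
               ">= 2 samples")
})

test_that("the LRT is exact under the null identity and finds planted effects", {
  # identical counts in both groups, equal offsets -> no evidence
  Y <- matrix(rep(c(10L, 40L, 200L), 13), 3, 13,
              dimnames = list(c("a", "b", "c"), NULL))
  g <- factor(rep(c("control", "cancer"), c(4, 9)),
              levels = c("control", "cancer"))
  d <- estimateNBDispersions(Y, g, offsets = rep(0, 13))
  tab <- lrtTest(Y, g, d, offsets = rep(0, 13))
  expect_true(all(tab$p_value >= 0.99))
  expect_equal(tab$log2FC, rep(0, 3), tolerance = 1e-8)

  # planted 4-fold difference, large counts, tiny dispersion
  set.seed(21)
  G <- 200
  mu <- rep(2000, G)
  fold <- rep(1, G); fold[1:20] <- 4
  Y <- cbind(matrix(rnbinom(G * 4, mu = mu, size = 100), G),
             matrix(rnbinom(G * 9, mu = mu * fold, size = 100), G))
  rownames(Y) <- paste0("f", 1:G)
  d <- estimateNBDispersions(Y, g, offsets = rep(0, 13))
  tab <- lrtTest(Y, g, d, offsets = rep(0, 13))
  expect_true(all(tab$log2FC[1:20] > 1.8 & tab$log2FC[1:20] < 2.2))
  expect_true(all(tab$p_value[1:20] < 1e-4))

  # an all-zero feature is flagged untested and excluded from the FDR
  Y[5, ] <- 0L
  d <- estimateNBDispersions(Y, g, offsets = rep(0, 13))
  tab <- lrtTest(Y, g, d, offsets = rep(0, 13))
  expect_false(tab$tested[5])
  expect_true(is.na(tab$fdr[5]))
})

test_that("exchanging group labels negates fold changes and keeps p-values", {
  sim <- null_nb(150, phi = 0.2, seed = 31)
  d <- estimateNBDispersions(sim$Y, sim$groups, offsets = sim$offsets)
  t1 <- lrtTest(sim$Y, sim$groups, d, offsets = sim$offsets)
  flipped <- factor(sim$groups, levels = rev(levels(sim$groups)))
  t2 <- lrtTest(sim$Y, flipped, d, offsets = sim$offsets)
  expect_equal(t2$log2FC, -t1$log2FC, tolerance = 1e-8)
  expect_equal(t2$p_value, t1$p_value, tolerance = 1e-6)
})

test_that("NB test results track an independent edgeR analysis", {
  skip_if_not_installed("edgeR")
  sim <- null_nb(400, phi = 0.2, seed = 41)
  fold <- rep(1, 400); fold[1:30] <- 4
  sim$Y[, 5:13] <- matrix(
    rnbinom(400 * 9, mu = rep(exp(5) * fold, 9), size = 5), 400)
  d <- estimateNBDispersions(sim$Y, sim$groups, offsets = sim$offsets)
  tab <- lrtTest(sim$Y, sim$groups, d, offsets = sim$offsets)

  y <- edgeR::DGEList(counts = sim$Y, group = sim$groups,
                      lib.size = rep(1e5, 13))
  y <- edgeR::estimateDisp(y, model.matrix(~sim$groups))
  fit <- edgeR::glmFit(y, model.matrix(~sim$groups))
  et <- edgeR::glmLRT(fit)$table
  keep <- tab$tested
  expect_gt(cor(-log10(tab$p_value[keep]), -log10(et$PValue[keep]),
                method = "spearman"), 0.9)
  expect_gt(cor(tab$log2FC[keep], et$logFC[keep]), 0.95)
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(0.37), 0.37)
  expect_identical(bhAdjust(numeric(0)), numeric(0))
  set.seed(51)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(bhAdjust(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("candidate selection applies both published threshold presets", {
  tab <- data.frame(
    feature_id = c("a", "b", "c", "d"),
    log2FC = c(2.1, 0.5, -1.4, 1.2),
    lr_stat = 1, p_value = c(0.001, 0.001, 0.015, 0.04), fdr = NA,
    mean_rpm = c(1500, 2000, 50, 800),
    variant_class = c("trimming", "mature", "NTA-U", "elongation"),
    tested = TRUE, stringsAsFactors = FALSE)
  got <- selectCandidates(tab)
  expect_identical(got$feature_id, c("a", "c", "d"))
  # b is dropped for effect size despite its p-value
  expect_false("b" %in% got$feature_id)
  # stricter preset used in the candidate-screen stage
  pre <- candidatePreset("results")
  got2 <- selectCandidates(tab, min_abs_log2fc = pre$min_abs_log2fc,
                           max_p = pre$max_p, inclusive = pre$inclusive)
  expect_identical(got2$feature_id, c("a", "c"))
  # an RPM floor removes low-abundance candidates
  got3 <- selectCandidates(tab, min_rpm = 1000)
  expect_identical(got3$feature_id, "a")
})

test_that("the occurrence table counts significant features per variant class", {
  tab <- data.frame(
    feature_id = letters[1:5],
    log2FC = c(2, -1.5, 1.2, 0.2, -3),
    lr_stat = 1, p_value = c(0.01, 0.02, 0.03, 0.001, 0.2), fdr = NA,
    mean_rpm = 100,
    variant_class = c("trimming", "trimming", "NTA-U", "mature", "mature"),
    tested = TRUE, stringsAsFactors = FALSE)
  occ <- isoformOccurrence(tab)
  expect_identical(occ[["trimming"]], 2L)
  expect_identical(occ[["NTA-U"]], 1L)
  expect_identical(occ[["mature"]], 0L)  # d fails fold, e fails p
  tab$p_value <- 0.9
  expect_true(all(isoformOccurrence(tab) == 0L))
})
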