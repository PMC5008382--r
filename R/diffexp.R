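# ---- internal NB machinery -------------------------------------------------
# NB parameterization: variance = mean + phi * mean^2, size = 1/phi.
# Models are log-linear with fixed per-sample offsets (log miRNA-mapped
# totals), so each group mean is a single parameter per feature and can be
# profiled out by vectorized Fisher scoring across all features at once.

.PHI_FLOOR <- 1e-8

# fit per-feature intercept beta for mu = exp(beta + off), NB(phi).
# Y: features x samples matrix; off: offsets; phi: scalar or per-feature.
.nbFitIntercept <- function(Y, off, phi, maxit = 30L, tol = 1e-10) {
  beta <- log((rowSums(Y) + 0.5) / sum(exp(off)))
  for (it in seq_len(maxit)) {
    mu <- exp(outer(beta, off, "+"))
    denom <- 1 + phi * mu
    score <- rowSums((Y - mu) / denom)
    info <- rowSums(mu / denom)
    step <- score / pmax(info, 1e-12)
    step <- pmin(pmax(step, -5), 5)
    beta <- pmin(pmax(beta + step, -50), 50)
    if (max(abs(step)) < tol) break
  }
  beta
}

.nbLogLik <- function(Y, off, beta, phi) {
  mu <- pmax(exp(outer(beta, off, "+")), 1e-12)
  phi <- pmax(phi, .PHI_FLOOR)
  ll <- stats::dnbinom(Y, size = 1 / phi, mu = mu, log = TRUE)
  rowSums(ll)
}

# per-feature adjusted profile log-likelihood at dispersion phi: group
# means profiled out within each group, with the Cox-Reid adjustment
# -0.5*log det(X'WX) (here one intercept per group, so the determinant is
# the scalar Fisher information) to remove the downward small-sample bias
# that plugging in the estimated means would otherwise cause
.nbProfileLL <- function(Y, off, groups, phi) {
  ll <- numeric(nrow(Y))
  for (g in levels(groups)) {
    j <- which(groups == g)
    beta <- .nbFitIntercept(Y[, j, drop = FALSE], off[j], phi)
    mu <- exp(outer(beta, off[j], "+"))
    info <- rowSums(mu / (1 + phi * mu))
    ll <- ll + .nbLogLik(Y[, j, drop = FALSE], off[j], beta, phi) -
      0.5 * log(pmax(info, 1e-10))
  }
  ll
}

.asCounts <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    x <- SummarizedExperiment::assay(x, "counts")
  as.matrix(x)
}

# ---- exported operations ---------------------------------------------------

#' Estimate common, trended and tagwise NB dispersions
#'
#' Three layers of negative-binomial overdispersion, allowing for extra
#' inter-library variability beyond Poisson noise:
#' \describe{
#'   \item{common}{one `phi` maximizing the summed per-feature profile
#'     log-likelihood (group means profiled out at fixed library-size
#'     offsets).}
#'   \item{trend}{a sliding-window (default 21 features, ranked by average
#'     log2 RPM) common-`phi` curve, so `phi` may vary with abundance.}
#'   \item{tagwise}{per-feature `phi_g` maximizing
#'     `ll_g(phi) + prior_weight * mean(ll_window(phi))`, a weighted-
#'     likelihood shrink of each feature toward its abundance
#'     neighbourhood.}
#' }
#' All-zero features are excluded from estimation and get `NA` tagwise
#' values.  Optimization is over a fixed log-spaced `phi` grid (trend,
#' tagwise) with a continuous refinement for the common value.
#'
#' @param counts Count matrix (features x samples) or a
#'   `SummarizedExperiment` with a `counts` assay.
#' @param groups Two-level factor of sample groups, each with >= 2 samples.
#' @param offsets Log library-size offsets; default
#'   `log(colSums(counts))` (log miRNA-mapped totals).
#' @param window Sliding-window size for trend/tagwise (default 21).
#' @param prior_weight Weight of the window likelihood in the tagwise
#'   objective (default 10).
#' @param phi_grid Dispersion grid; default 60 log-spaced values in
#'   `[1e-4, 4]`.
#' @return A [DispersionSet-class].
#' @export
estimateNBDispersions <- function(counts, groups, offsets = NULL,
                                  window = 21L, prior_weight = 10,
                                  phi_grid = exp(seq(log(1e-4), log(4),
                                                     length.out = 60L))) {
  Y <- .asCounts(counts)
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L)
    stop("groups must have exactly two levels")
  if (any(table(groups) < 2L))
    stop("each group needs >= 2 samples to identify a dispersion")
  if (is.null(offsets)) offsets <- log(colSums(Y))
  used <- rowSums(Y) > 0
  Yu <- Y[used, , drop = FALSE]
  if (!nrow(Yu)) stop("no non-zero features")

  # common: continuous profile-likelihood maximization
  obj <- function(lphi) -sum(.nbProfileLL(Yu, offsets, groups, exp(lphi)))
  opt <- stats::optimize(obj, interval = log(c(1e-6, 10)))
  common <- exp(opt$minimum)

  # profile log-likelihood of every used feature on the grid
  pll <- vapply(phi_grid,
                function(p) .nbProfileLL(Yu, offsets, groups, p),
                numeric(nrow(Yu)))

  ab <- rowMeans(log2(sweep(Yu + 0.5, 2L, exp(offsets), "/") * 1e6))
  ord <- order(ab)
  half <- (as.integer(window) - 1L) %/% 2L
  n <- nrow(Yu)
  cs <- rbind(0, apply(pll[ord, , drop = FALSE], 2L, cumsum))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  win_sum <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  win_mean <- win_sum / (hi - lo + 1L)

  trend_o <- phi_grid[max.col(win_sum, ties.method = "first")]
  tag_obj <- pll[ord, , drop = FALSE] + prior_weight * win_mean
  tag_o <- phi_grid[max.col(tag_obj, ties.method = "first")]

  trend_u <- tag_u <- numeric(n)
  trend_u[ord] <- trend_o
  tag_u[ord] <- tag_o
  full <- function(v) {
    out <- rep(NA_real_, nrow(Y))
    out[used] <- v
    stats::setNames(out, rownames(Y))
  }
  ab_full <- full(numeric(n))
  ab_full[used] <- ab
  new("DispersionSet", common = common, trend = full(trend_u),
      tagwise = full(tag_u), abundance = ab_full,
      prior_weight = as.numeric(prior_weight), window = as.integer(window))
}

#' NB likelihood-ratio test for a two-group effect
#'
#' Per feature, fits a negative-binomial log-linear model with fixed
#' log miRNA-mapped-total offsets at the feature's tagwise dispersion:
#' the full model has one mean per group, the null model a single mean.
#' The p-value comes from referring twice the log-likelihood difference to
#' a chi-square with 1 degree of freedom.  The reported log2 fold change
#' (second group level versus first) uses offset-normalized group means with
#' a +0.5-count moderation so zero counts never yield infinite ratios.
#'
#' @param counts Count matrix or `SummarizedExperiment` (features x
#'   samples).
#' @param groups Two-level factor; the *first* level is the reference
#'   (e.g. control) and fold changes are second vs first.
#' @param dispersions A [DispersionSet-class] from [estimateNBDispersions()];
#'   features lacking a tagwise value fall back to the common dispersion.
#' @param offsets Log library-size offsets; default `log(colSums(counts))`.
#' @param variant_class Optional per-feature class labels carried into the
#'   result (for the isoform-occurrence summary).
#' @param mean_rpm Optional per-feature mean RPM; default computed from
#'   `counts` and `offsets`.
#' @return `data.frame` ("DiffTable") with columns `feature_id, log2FC,
#'   lr_stat, p_value, fdr, mean_rpm, variant_class, tested`.  All-zero or
#'   non-converged features are flagged `tested = FALSE` with `NA`
#'   statistics and are excluded from the FDR computation.
#' @export
lrtTest <- function(counts, groups, dispersions, offsets = NULL,
                    variant_class = NULL, mean_rpm = NULL) {
  Y <- .asCounts(counts)
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L)
  if (is.null(offsets)) offsets <- log(colSums(Y))
  phi <- tagwiseDispersion(dispersions)
  if (!is.null(names(phi)) && !is.null(rownames(Y)))
    phi <- phi[rownames(Y)]
  phi[is.na(phi)] <- commonDispersion(dispersions)
  phi <- pmax(phi, .PHI_FLOOR)

  tested <- rowSums(Y) > 0
  g1 <- which(groups == levels(groups)[1L])
  g2 <- which(groups == levels(groups)[2L])

  ll_full <- ll_null <- rep(NA_real_, nrow(Y))
  b1 <- .nbFitIntercept(Y[, g1, drop = FALSE], offsets[g1], phi)
  b2 <- .nbFitIntercept(Y[, g2, drop = FALSE], offsets[g2], phi)
  b0 <- .nbFitIntercept(Y, offsets, phi)
  ll_full <- .nbLogLik(Y[, g1, drop = FALSE], offsets[g1], b1, phi) +
    .nbLogLik(Y[, g2, drop = FALSE], offsets[g2], b2, phi)
  ll_null <- .nbLogLik(Y, offsets, b0, phi)
  stat <- pmax(2 * (ll_full - ll_null), 0)
  p <- stats::pchisq(stat, df = 1L, lower.tail = FALSE)

  # per-group normalized means with a +0.5 moderation on the *average*
  # count, so identical groups give exactly zero regardless of group size
  m1 <- (rowMeans(Y[, g1, drop = FALSE]) + 0.5) / mean(exp(offsets[g1]))
  m2 <- (rowMeans(Y[, g2, drop = FALSE]) + 0.5) / mean(exp(offsets[g2]))
  log2fc <- log2(m2 / m1)
  if (is.null(mean_rpm))
    mean_rpm <- rowMeans(sweep(Y, 2L, exp(offsets), "/") * 1e6)

  out <- data.frame(
    feature_id = if (is.null(rownames(Y))) as.character(seq_len(nrow(Y)))
                 else rownames(Y),
    log2FC = ifelse(tested, log2fc, NA_real_),
    lr_stat = ifelse(tested, stat, NA_real_),
    p_value = ifelse(tested, p, NA_real_),
    fdr = NA_real_,
    mean_rpm = mean_rpm,
    variant_class = if (is.null(variant_class)) NA_character_
                    else as.character(variant_class),
    tested = tested,
    stringsAsFactors = FALSE)
  out$fdr[tested] <- bhAdjust(out$p_value[tested])
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"` (monotone
#' step-up, capped at 1); empty input yields empty output.
#'
#' @param p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted values in the original order.
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  stats::p.adjust(p, method = "BH")
}

#' Candidate-selection presets
#'
#' Two named filters are in use for candidate selection and are not
#' reconciled here: the `"methods"` preset (|log2FC| >= 1 and p <= 0.05)
#' and the stricter `"results"` preset (fold change >= 2, i.e.
#' |log2FC| >= 1, and p < 0.02).
#'
#' @param name `"methods"` or `"results"`.
#' @return List of arguments for [selectCandidates()].
#' @export
candidatePreset <- function(name = c("methods", "results")) {
  switch(match.arg(name),
         methods = list(min_abs_log2fc = 1, max_p = 0.05, inclusive = TRUE),
         results = list(min_abs_log2fc = 1, max_p = 0.02, inclusive = FALSE))
}

#' Select differential candidates from a DiffTable
#'
#' @param tab A `data.frame` from [lrtTest()].
#' @param min_abs_log2fc Minimum absolute log2 fold change (default 1).
#' @param max_p P-value threshold (default 0.05).
#' @param min_rpm Minimum mean RPM (default 0).
#' @param inclusive Compare p with `<=` (default) or strict `<`.
#' @return The qualifying rows, sorted by p-value then decreasing
#'   |log2FC|.
#' @export
selectCandidates <- function(tab, min_abs_log2fc = 1, max_p = 0.05,
                             min_rpm = 0, inclusive = TRUE) {
  keep <- tab$tested &
    abs(tab$log2FC) >= min_abs_log2fc &
    (if (inclusive) tab$p_value <= max_p else tab$p_value < max_p) &
    tab$mean_rpm >= min_rpm
  keep[is.na(keep)] <- FALSE
  out <- tab[keep, , drop = FALSE]
  out[order(out$p_value, -abs(out$log2FC)), , drop = FALSE]
}

#' Isoform-occurrence summary of significant changes
#'
#' Counts, per variant class, how many features changed at least
#' `fold_threshold`-fold with `p <= max_p` — the per-type roll-up showing
#' which kind of 3'-end processing (truncation, elongation, NTA, ...)
#' discriminates the groups.
#'
#' @param tab A `data.frame` from [lrtTest()] with `variant_class` filled.
#' @param fold_threshold Minimum fold change (default 2).
#' @param max_p P-value threshold (default 0.05).
#' @return Named integer vector over all variant classes present in `tab`
#'   (zero counts included).
#' @export
isoformOccurrence <- function(tab, fold_threshold = 2, max_p = 0.05) {
  if (all(is.na(tab$variant_class)))
    stop("variant_class not available in this table")
  classes <- sort(unique(stats::na.omit(tab$variant_class)))
  sig <- tab$tested &
    abs(tab$log2FC) >= log2(fold_threshold) &
    tab$p_value <= max_p
  sig[is.na(sig)] <- FALSE
  counts <- table(factor(tab$variant_class[sig], levels = classes))
  stats::setNames(as.integer(counts), classes)
}
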