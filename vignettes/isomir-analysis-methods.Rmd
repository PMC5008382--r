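---
title: "Methods: isomiR calling, differential abundance and panel diagnostics"
author: "isomiRdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isomiR calling, differential abundance and panel diagnostics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isomiRdx)
```

# Scope and model of the data

Mature miRNAs are annotated as single ~22-nt sequences, but deep sequencing
of biofluids shows each miRNA as a family of 3′-end length variants
(isomiRs): templated trimmings and elongations of the precursor (hairpin)
sequence, and non-templated additions (NTA) — most prominently 3′
uridylation and adenylation — laid down by ribonucleotidyl transferases.
In urine extracellular vesicles (EVs) the *relative composition* of these
variants can differ between prostate-cancer patients and controls even
when the summed miRNA abundance does not, which is why a mature-sequence
qPCR assay can fail to validate a sequencing hit while an isomiR-directed
assay succeeds.

`isomiRdx` implements that analysis end to end:

1. read preprocessing (adapter trimming, length filter, collapsing),
2. template-based isomiR classification against hairpin references,
3. isoform- and summed-miRNA quantification in reads per million
   miRNA-mapped reads (RPM),
4. negative-binomial (NB) differential abundance with common / trended /
   tagwise dispersion and a likelihood-ratio test (LRT),
5. ΔCt normalization of stem-loop RT-qPCR panels, and
6. five-model LOOCV logistic classification with ROC / operating-point
   reporting against a serum-PSA baseline.

A synthetic cohort generator with planted composition shifts makes every
stage testable without external data.

# Reference model and the isomiR taxonomy

A `ReferenceSet` holds hairpin sequences (RNA alphabet; `T` is accepted on
input and stored as `U`) plus mature-arm annotations in 0-based half-open
coordinates on the hairpin's 5′→3′ strand. The canonical mature sequence is
*defined* as the hairpin substring `[start, end)`; a miRBase-style GFF3
reader (`readMirbaseGff3()`) converts genomic 1-based-inclusive coordinates
into this convention.

Each read is anchored by its 5′ seed: the first `seed_len = 16` nt must
match the hairpin with at most one mismatch at a start within ±5 nt of an
annotated mature start. Seed (rather than full-length) alignment is
essential: a read with a long non-templated tail would otherwise fail to
map precisely because it is the molecule of interest. Among candidate
anchors the caller minimizes `(mismatches, |5′ offset|)`, breaking residual
ties by lexicographic miRNA id so multi-mapping reads are assigned
deterministically.

Classification is **template-first**: the templated span is the maximal
read prefix matching the hairpin (≤ 1 internal mismatch, never *ending* on
a mismatch); whatever follows is the NTA tail. Consequently a 3′ addition
that matches the hairpin continuation is a *templated elongation*, not an
NTA, and mismatches are never attributed to the tail — a tail mismatch *is*
the NTA signal. Variant classes are mutually exclusive under the
precedence

> 5′ modification ≻ NTA-A/U/G/C/other ≻ trimming / elongation ≻ mature,

because the occurrence summary counts each read once; the full
`(d5, d3, tail)` record is always retained so alternative roll-ups remain
possible. The length identity
`length = canonical − d5 + d3 + |tail|` holds for every call and is
asserted in the tests against an exhaustive decomposition oracle.

The bundled three-hairpin toy reference embeds the canonical miR-21-5p,
miR-204-5p and miR-375 sequences with 4-nt flanks, so the published panel
isomiR sequences classify as: miR-21-5p 2-nt trimming (20 nt), miR-204-5p
+1 templated elongation (23 nt), miR-375 1-nt trimming (21 nt).

# Preprocessing

Adapter search is exact-prefix match (first `min_overlap = 8` adapter
bases, zero mismatches, leftmost occurrence); the default adapter is the
standard Illumina small-RNA 3′ adapter and is configurable. Reads without
an adapter hit are *retained* by default (the insert may fill the read);
`discard_untrimmed` flips this. Reads shorter than 15 nt are deleted and
the survivors collapsed to unique sequences with counts. Collapsing is
order-invariant and conserves reads: `n_raw = n_pass + n_short`.
Quality-score filtering is out of scope.

# Quantification

Two levels are quantified: isoform-level features keyed by the full
`(mirna, d5, d3, tail)` identity (so `NTA-U` and `NTA-UU` are distinct),
and summed-miRNA features adding all reads of a miRNA. RPM normalization
divides by the sample's **miRNA-mapped** total — never the raw yield — so
the value is independent of sequencing depth and of the relative frequency
of other small-RNA classes (tRNA/rRNA/Y-RNA fragments, which this package
does not model). Isoform RPMs of a miRNA add up exactly to its summed-level
RPM, and every complete column sums to 10^6.

# Differential abundance

Counts are modeled as NB with `variance = mean + φ·mean²` in a log-linear
model with fixed `log(miRNA-mapped total)` offsets — consistent with the
RPM definition; with a two-level group factor the group means separate, so
each is a single intercept fitted by vectorized Fisher scoring.

Dispersion is estimated in three layers:

* **common** — one φ maximizing the summed per-feature profile likelihood,
  with a Cox–Reid adjustment (−½·log of the per-group Fisher information).
  The unadjusted profile MLE is biased low by roughly `(n−2)/n` (0.17 for a
  true 0.2 at n = 13), which inflates the null type-I error of the LRT to
  ~0.073; the adjusted estimator — the REML analogue for dispersions — is
  centered (φ ≈ 0.2, empirical null rejection 4.7–6.2% across seeds).
* **trend** — a sliding-window (21 features, ranked by average log2 RPM)
  common-φ curve, letting φ vary with abundance.
* **tagwise** — per-feature φ_g maximizing
  `ℓ_g(φ) + w·ℓ̄_window(φ)` with prior weight `w = 10`, shrinking each
  feature toward its abundance neighbourhood. Trend and tagwise maximize
  over a fixed 60-point log-spaced grid on `[10⁻⁴, 4]` (resolution ~8%,
  well below the sampling noise of a per-feature dispersion); the common
  value is refined continuously. The lower grid bound doubles as the
  no-overdispersion floor.

This estimator family is this package's own design; numerical equivalence
with other NB frameworks is not targeted, though an independent edgeR
analysis of the same simulated data agrees closely in ranking and fold
change (checked in the test suite).

The LRT compares one-mean-per-group against a single mean at the tagwise
φ, with p from χ²₁. All-zero features are flagged untested and excluded
from the Benjamini–Hochberg FDR. Reported log2 fold changes (cancer vs
control) use offset-normalized group means moderated by +0.5 on the
*average* count — so identical groups give exactly zero and zero counts
never produce infinite ratios.

Two candidate-selection presets are exposed and deliberately not
reconciled, mirroring the two filters in circulation for this analysis:
`"methods"` (|log2FC| ≥ 1, p ≤ 0.05) and the stricter screen `"results"`
(fold ≥ 2, p < 0.02). The isoform-occurrence summary counts, per variant
class, the features changed ≥ 2-fold at p ≤ 0.05.

# RT-qPCR normalization

The pooled-control reference is emulated as the per-assay arithmetic mean
of control Ct values (a physical cDNA pool approximates the mean on the
cycle scale; a geometric alternative differs only by convention and can be
supplied as the aggregation function). With
`ΔCt = Ct_sample − Ct_reference`, the reported natural-log expression is
`ln_expr = −ΔCt·ln 2`, i.e. the natural log of the fold change
`2^(−ΔCt)`: one fewer cycle raises `ln_expr` by exactly `ln 2`, the
reference sample sits at 0, and the whole map is affine in Ct with slope
−ln 2. The direction of the natural-log transform is a convention; it only
rescales logistic coefficients downstream and never reorders LOOCV
probabilities. No endogenous-control gene and no amplification-efficiency
correction are applied.

# Diagnostics

Five logistic models are compared: PSA alone; the 3 mature-miRNA assays;
mature + PSA; the 3 isomiR assays; isomiR + PSA. PSA enters as `ln(PSA)`
by default — serum PSA spans ~1–400 ng/ml and would otherwise dominate by
leverage; raw PSA is a switch. Fitting is damped IRLS with a fixed tiny
ridge (10⁻⁸) so perfectly separated data converge to large finite
coefficients with a warning rather than diverging.

Each model is evaluated by leave-one-out cross-validation: exactly one
out-of-fold probability per sample, deterministic and order-invariant.
ROC curves use the fixed threshold grid 0.01–0.99 (step 0.01, a choice of
this package), classifying "disease" when probability ≥ threshold (ties
are measure-zero on continuous probabilities); AUC is the trapezoidal
integral with (0,0) and (1,1) appended — it tracks the Mann–Whitney AUC
within the 0.02 discretization bound. The operating point maximizes
Youden's J with ties broken toward higher specificity, then the higher
cutoff; note that with completely uninformative (all-equal) probabilities
both degenerate corners reach J = 1 and this rule returns the
all-negative corner (PPV is then undefined/NaN). PPV and NPV come from the
confusion table at the chosen cutoff.

# The synthetic cohort generator

`simulateCohort()` generates the structure the analysis assumes, not a
sequencing-error model: per-miRNA lognormal baseline abundance (sdlog 1.5
across miRNAs), per-sample Dirichlet isoform splits over
(mature, −1 and −2 trimming, +1 elongation, NTA-U, NTA-A) with
concentrations (30, 10, 6, 8, 4, 2), NB counts
(`variance = mean + φ·mean²`, default φ = 0.2; φ = 0 gives exact Poisson
emission), a global 0.7× miRNA-yield decrease in cancer, and lognormal PSA
(meanlog log 6 vs log 12, sdlog 0.9 — large-n PSA-alone AUC ≈ 0.7,
matching what PSA achieves in practice). Reads, when emitted, carry the 3′
adapter and constant Phred-40 qualities. Decoy hairpins get 8-nt flanks
whose 3′ flank starts with G or C, so simulated NTA-U/NTA-A isoforms are
always genuinely non-templated and the truth labels match the
template-first caller. The default depth of 10⁶ miRNA-mapped reads per
sample corresponds to a typical small-RNA run of this design
(~2 M raw reads/sample of which ~44% are miRNA).

The paper-like planted effects are: +1-elongated miR-204-like isoform ×3
in cancer (mature miR-204 unchanged — the composition shift that moves the
modal read length from 22 to 23 nt), 2-nt-trimmed miR-21-like and
1-nt-trimmed miR-375-like isomiRs ×0.25, and weak (×0.6) decreases of the
miR-21/miR-375 mature isoforms. The last two make the mature panel weakly
informative rather than pure noise — without them the isomiR panel sits at
an AUC ceiling (~0.95) where a PSA covariate cannot add value, which is
not the regime the validation-phase comparison is about. Simulated Ct
values are `38 − log2(RPM + 1)` plus Gaussian noise of 2.5 cycles,
standing in for the large inter-patient biological spread of biofluid-EV
qPCR; this calibration places the panel AUCs near their empirically
observed range (isomiR panel ≈ 0.78, +PSA ≈ 0.82, mature ≈ 0.5–0.6,
PSA ≈ 0.65 at n = 74) and was fixed once, before the test expectations
were frozen.

What the generator does **not** emulate — and therefore what passing tests
do not show about real data: sequencing errors and quality variation,
non-miRNA small-RNA background classes, cross-hybridizing qPCR assays,
5′ heterogeneity beyond the ±5 shift window, multi-locus miRNA families,
and batch effects.

# Numerical choices and degenerate inputs

* Dispersion floor 10⁻⁸ (Poisson limit); intercepts clamped to ±50;
  Fisher-scoring steps clamped to ±5; LRT statistics floored at 0.
* Logistic Newton steps are damped to max-norm 10; separation is detected
  from residuals (all fitted probabilities within 10⁻⁴ of the labels) and
  warned about, never an error.
* Zero-total samples are a hard error in RPM normalization (named);
  assays without any control Ct, missing panel assays, one-class label
  vectors and LOOCV folds that would lose a class are hard errors too.
* Missing Ct values propagate as `NA`; they are never imputed.
* All simulation randomness flows from a single integer seed;
  regeneration is byte-identical, and derived streams (e.g. qPCR noise)
  use an additive offset modulo 2³¹−1 so user seeds near the integer
  limit remain valid.

# Problem sizes used by the test suite

The suite runs on simulated data sized for tight feedback: dispersion
recovery on 600 features, the null-calibration check on 2000 features
(4 vs 9 samples, φ = 0.2), planted-effect recovery on 2004 features with
50 planted 4-fold changes at the default depth, FASTQ-backed end-to-end
discovery on 20 miRNAs at 3×10⁴ reads/sample, and validation on the
26 vs 48 preset. These sizes are the package's own choices; the same code
paths scale to full-size references by swapping in `loadReference()`.

# Known limitations

* 5′ NTAs and internal (e.g. A-to-I) editing are not modeled; a read with
  an edited seed may fail to anchor or anchor with one mismatch.
* Multi-mapping across miRNA families is resolved deterministically, not
  probabilistically.
* The NB model assumes a two-group design; no covariates or multi-factor
  designs.
* LOOCV AUC of weakly informative panels is biased below 0.5 (out-of-fold
  anti-correlation); the report shows what cross-validation actually
  yields rather than a corrected estimate.
* Patient-cohort results from the original study cannot be reproduced
  here because its raw sequencing and qPCR data are not public; all
  quantitative checks run on the synthetic generator.
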