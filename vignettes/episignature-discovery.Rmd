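---
title: "Methods: episignature discovery, validation and MVP classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episignature discovery, validation and MVP classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical methods: the
models each stage fits, the assumptions behind them, the tunable
parameters and their defaults, what the synthetic-data generator does and
does not emulate, and the numerical and design choices made where the
procedure left room for judgement.

# The setting

An episignature is a reproducible pattern of DNA methylation in peripheral
blood that is specific to a genetic disorder. Discovery cohorts are small
— here the emulated design has eight affected cases — so the analysis
leans on three ideas: information sharing across probes (empirical-Bayes
variance moderation), aggressive but reproducible feature selection, and
validation schemes (unsupervised clustering, leave-one-out
cross-validation, a large matched negative set) chosen to expose
overfitting rather than hide it.

The central data object is a `MethylExperiment`, a
`RangedSummarizedExperiment` whose `beta` assay holds methylation
fractions β ∈ [0, 1] (probes × samples), with per-probe genomic
coordinates and QC exclusion flags in `rowRanges` and the sample sheet in
`colData`.

# Quality control

`filterProbes()` removes probes that are (in precedence order) allosomal,
SNP-affected, cross-reactive, or that exceed the detection p-value
threshold `detpAlpha = 0.01` in **any** sample. The aggregation rule
matters: a per-probe detection failure in a single sample is enough to
drop the probe. This is the strictest reading of a "detection p above
0.01" filter and matches common array-QC practice; it makes the retained
matrix complete (no missingness handling downstream). The precedence
ordering exists only so the removal counts in the `QcReport` are
well-defined when a probe matches several reasons.

`pcaOutlierScreen()` (components = 2, threshold = 3 SD of the component
scores) reports outlying samples; it never drops them. Exclusion is an
explicit caller decision (`excludeOutliers` in the pipeline config)
because an "outlier" in a disease cohort can be the most informative
sample. Components with zero variance flag nothing, and the flag set is
invariant under the sign ambiguity of principal components.

# M-values and the linear model

β values are heteroscedastic: variances shrink near the boundaries.
`betaToM()` maps β to M = log2(β/(1 − β)) after clamping β into
[1e−6, 1 − 1e−6]; the clamp keeps M finite at degenerate values and is
invertible (`mToBeta()`). Models are fitted on M; effect sizes are
reported as Δβ on the β scale, where a "5 % methylation difference" has
its familiar meaning.

`fitProbeModels()` fits, per probe, ordinary least squares of M on an
intercept, a case indicator, and one column per estimated cell-type
proportion (optionally batch and array type; off by default since the
matching step already balances them). Cell composition is the dominant
known confounder of blood methylation, which is why the proportions enter
the model rather than being "corrected" out of the matrix.

## Cell-type deconvolution

`estimateProportions()` implements the reference-based (Houseman)
estimator: for each sample, minimise ‖β − Rw‖² over the reference probes
subject to w ≥ 0 and Σw ≤ 1. The inequality form (projection) is the
default; Σw = 1 is available via `sumToOne = TRUE`. The quadratic program
is solved by non-negative least squares with the simplex constraint
encoded as a heavily weighted equality row plus a non-negative slack
variable — at the NNLS optimum the slack absorbs any shortfall exactly, so
interior solutions are unperturbed and boundary solutions satisfy the
constraint to ~1e−10. Tests verify exact recovery of noiseless mixtures
(1e−6) and optimality against an exhaustive feasible grid.

## Variance moderation

With eight cases, per-probe variance estimates are unstable.
`estimateModerationPrior()` fits a scaled-inverse-χ² prior (d₀, s₀²) to
the residual variances by moment matching on the log scale: under the
prior, Var(log s²) = trigamma(d/2) + trigamma(d₀/2), so the excess of the
observed dispersion of log s² over the χ² sampling noise determines d₀
through the inverse trigamma function (Newton iteration), and the mean
determines s₀² with the corresponding digamma bias term. When the
observed dispersion does not exceed the sampling noise, d₀ = ∞ and s₀² is
the geometric mean of the variances — every probe is then shrunk fully to
the common value, and the moderated statistic is referred to the normal
distribution. `moderateStatistics()` forms s̃² = (d₀s₀² + d s²)/(d₀ + d)
and t̃ = β̂/(c·s̃) on d₀ + d degrees of freedom.

Tests check the estimator two ways: parameter recovery on 20,000
variances simulated from a known prior (d₀ within 15 %, s₀² within 5 %),
and agreement with an independent implementation of the same
moment-matching idea (`limma::squeezeVar`) used purely as a cross-check
oracle. Null simulations confirm uniform moderated p-values
(Kolmogorov–Smirnov).

# Feature selection

`selectFeatures()` is the three-step procedure:

1. keep the `nRank = 1000` probes with the highest rank score
   |Δβ| · (−log₁₀ p) (p floored at 1e−300 so the score stays finite);
2. keep the `nAuroc = 250` of those with the most discriminative AUROC;
3. walking the survivors from the top, drop any probe whose β correlation
   with an already-kept probe exceeds `corrThreshold = 0.9` within the
   case group **and** within the control group.

Three decisions here were genuinely open:

- **Absolute vs signed ranking (step 1).** The rank score uses |Δβ|: a
  probe hypomethylated in cases is as informative as a hypermethylated
  one. `signedRank = TRUE` restores the signed variant.
- **AUROC direction (step 2).** The AUROC with cases as positives ranks a
  perfectly discriminating hypomethylated probe near 0, not 1. Ranking by
  the raw value would silently discard one effect direction, which
  contradicts both the purpose of step 2 (keep the most discriminative
  probes) and the behaviour expected on data with sign-randomised effects.
  Step 2 therefore ranks by max(AUROC, 1 − AUROC); the raw AUROC is still
  reported per probe.
- **"Both groups" pruning (step 3).** A correlated-within-one-group-only
  pair is kept: redundancy is declared only when the correlation exceeds
  the threshold in cases *and* controls. This is the conservative reading
  of per-group pruning (it preserves probes whose co-behaviour differs
  between conditions); `bothGroups = FALSE` gives the "either" variant.

All orderings use probe id as the final tie-break, so selection is fully
deterministic. The signature records the selection parameters, the
per-probe direction and group means, and provenance (dataset hash, step
sizes, the step-2 probe set).

# Unsupervised validation

`wardCluster()` is agglomerative clustering with Ward's minimum-variance
criterion on Euclidean distances (`hclust`, `ward.D2`), reported with a
two-cluster cut. `mdsEmbed()` is classical (Torgerson) scaling: double
centring of the squared-distance matrix, top-2 eigenpairs; planar
configurations embed exactly, coordinates are defined up to
rotation/reflection, and degenerate inputs (all-identical samples, fewer
than two positive eigenvalues) return zero/reduced coordinates with a
warning rather than failing.

`runLoocv()` runs one fold per case: the held-out case is excluded, the
differential model is refit and probes re-selected on the remaining cases
and all matched controls, every sample is embedded by MDS on the fold's
probes, and the held-out case is assigned to the nearer group centroid in
the embedding. The centroid rule exists to make "clusters with the cases"
assertable rather than visual. A fold with an empty signature is marked
failed and the run continues.

# MVP classification

`trainClassifier()` fits a linear-kernel SVM (cost 1) on β at the
signature probes, standardised by training mean/SD. The training set is
the discovery cases against the matched controls plus 75 % of the
other-control pool and 75 % of each confounder-disorder cohort
(stratified, seed-deterministic split); the held-out 25 % forms the test
set. The kernel, cost, and calibration are not dictated by the procedure
being emulated; a linear kernel with unit cost is the standard choice for
p ≫ n methylation features, and inverse-frequency class weights prevent
the 8-vs-~200 imbalance from collapsing the fit to the trivial
all-negative classifier. Platt sigmoid calibration turns the margin into
the MVP score in [0, 1], classified at `cutoff = 0.5`.

The fitted machine is collapsed to its weight vector, intercept, sigmoid
coefficients and scaling constants — a pure linear-plus-sigmoid scorer
that round-trips through JSON with no binary state. The sign conventions
of the underlying solver are canonicalised at training time by comparing
against its own predictions, and `scoreSamples()` refuses to score inputs
with missing signature probes (no silent imputation).

One stability caveat is documented by test: duplicating a training sample
leaves the separating hyperplane essentially unchanged (< 1e−3 relative)
but perturbs the Platt recalibration by a few 1e−3 in score, because both
the class weights and the internal calibration folds depend on n.

# Differentially methylated regions

`findDmrs()` chains positionally sorted probes per chromosome into
candidate regions wherever consecutive gaps are ≤ `window = 1000` bp
(total-span grouping via `chain = FALSE`), requires ≥ `minCpgs = 3`
probes and |mean Δβ| ≥ `minDelta = 0.05` (a per-probe variant is
available), combines the per-probe p-values by Fisher's method
(X² = −2Σln pᵢ, df = 2k) and applies Benjamini–Hochberg across the
candidates, reporting regions with adjusted p < `alpha = 0.01`. The
"Fisher's multiple-comparison p < 0.01" phrasing common in this
literature conflates the combination and the correction; both steps are
implemented explicitly and reported separately (`p_fisher`, `p_adj`).

`findSignatureRegions()` is the descriptive companion rule on the
selected probes only: runs of **more than two** signature probes in
direct vicinity (same 1 kb default, the procedure names no number) with
identical Δβ sign, no test. Output is a `GRanges` (1-based, inclusive);
the BED writer converts to 0-based half-open.

# The synthetic cohort generator

`simulateCohort()` emulates the statistical structure the analysis
assumes, with defaults that define the study conditions used throughout
the tests and the acceptance script:

| parameter | default | rationale |
|---|---|---|
| `nProbes` | 20,000 | large enough for honest 1000/250 selection and ~18,500 clean probes, small enough for minutes-scale runs; real arrays have ~40× more |
| `nCases` / `controlRatio` | 8 / 7 | the emulated discovery design (8 cases, 56 matched controls) |
| `nSignatureProbes` | 300 | planted effect set; comfortably exceeds the 250 retained at step 2 |
| `effectLogit` | 1.5 | case shift on logit(β); ~5 noise SDs — a clearly penetrant episignature |
| `noiseSd` | 0.3 | within-group logit-scale SD, typical of blood array replicates |
| `nCellTypes` | 6 | CD4T, CD8T, NK, monocytes, granulocytes, B cells |
| `nVusLike` | 3 | samples from the control model labelled `test` (VUS analogues) |
| `nOtherDisorders` × `samplesPerDisorder` | 8 × 8 | confounder cohorts, each with its own disjoint 100-probe planted set |

Each sample's β is composed as a mixture of cell-type reference profiles
with Dirichlet-drawn proportions (concentration ~ adult blood
composition), plus a per-(batch, probe) offset (SD 0.15), the planted case
shift (sign randomised per probe and recorded in the truth), and Gaussian
noise — all on the logit scale, back-transformed and clamped to
[1e−6, 1 − 1e−6]. Baseline probe means are drawn from a two-component
mixture concentrated near β = 0.1 and 0.9, reproducing the bimodality of
array methylation that makes AUROC and correlation behave realistically.
Ages (2–50, skewed young), sex (~46 % female), batch and array type are
drawn to exercise the matching step. QC flags and detection failures are
injected at configurable rates; flags avoid the planted and reference
probes so the ground truth survives QC by construction, while detection
failures may hit any probe.

What the generator does **not** emulate: Infinium I/II probe chemistry
and dye bias, raw-intensity backgrounds (inputs are taken as already
normalised), spatial/genomic autocorrelation of methylation beyond the
planted sets, age- or sex-dependent methylation drift, and realistic
correlation structure among disorder episignatures. Consequently, green
tests demonstrate that the *procedure* is implemented correctly and
behaves as designed under its own assumptions — not that the pipeline
would achieve full sensitivity and specificity on real patient data,
where effects are weaker, confounding richer, and probes correlated.

`simulateConfounders()` shares the deterministic probe "world" (manifest,
baselines, profiles, planted sets) with `simulateCohort()` for the same
config, so the two objects combine seamlessly; sampling uses separate
seed streams derived from the config seed.

# Numerical choices and degenerate inputs

- β clamping at 1e−6 everywhere a logit/M transform occurs; p-values
  floored at 1e−300 before logs.
- Ties: probe id is the universal tie-break in selection; matching breaks
  cost ties on lexicographic sample id and is invariant to pool order.
- AUROC uses midranks, so ties count one half (`computeAuroc` equals
  brute-force pair counting, verified on small instances).
- `estimateModerationPrior` drops zero variances from the moment
  equations and errors only when all variances vanish.
- Zero-variance features receive unit scale in the classifier
  standardisation; zero-variance PCA components never flag outliers;
  all-identical samples embed at the MDS origin.
- The pipeline writes artifacts as `.partial` files, promotes them on
  success, and hashes the finals into `manifest.json`; the config hash
  excludes output paths so determinism is checkable across directories.

# Problem sizes

The default analyses in the tests and the acceptance script use the
generator defaults above (20,000 probes, 191 samples across cohorts);
unit tests use scaled-down cohorts (hundreds to a few thousand probes)
with the same structure. These sizes were chosen as the smallest at which
every procedural count (1000, 250, 56, 8 folds) is exercised honestly,
with the whole suite running in minutes on one CPU.

# Known limitations

- The moderated model assumes exchangeable probe variances around one
  prior; methylation arrays are better described by mean–variance trends,
  which the moderation here does not model.
- The matching cost (age normalised by pooled range; unit penalties for
  sex and array mismatches) is a reasonable but invented weighting; the
  emulated procedure names only the matched variables.
- Greedy per-case matching is order-dependent by design (cases in id
  order); it is deterministic but not globally optimal.
- DMR detection is the stated windowed-run rule, not a kernel-smoothed
  region statistic; gene annotation of regions is out of scope.
- Calibrated MVP scores inherit the instabilities of Platt scaling on
  small positive classes; the 0.5 cut-off, not the score's second
  decimal, is the supported decision boundary.
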