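---
title: "Models and methods behind adductQC"
author: "adductQC authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind adductQC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adductQC)
```

# The problem

Untargeted DNA adductomics measures trace-level covalent DNA modifications
by LC-HRMS. After peak detection, alignment, grouping and gap filling, the
analyst holds a feature table — peak areas for thousands of features across
a run sequence — that still carries several layers of unwanted variation:

* **signal drift**: a systematic, injection-order-dependent and often
  feature-dependent change in response (source contamination, column
  ageing, temperature cycles);
* **batch effects**: step offsets after column changes or instrument
  maintenance;
* **missing cells**: predominantly low-intensity signals censored near the
  detection limit;
* **loading differences**: each sample contributes a different amount of
  DNA to the injection.

`adductQC` implements the downstream workflow — filtering, imputation, six
drift-correction strategies, batch alignment, robust quality metrics and
comparison statistics — together with a simulator that generates run
sequences with exactly these artefacts and returns the ground truth, so
every stage is testable without instrument data.

# Data model

`AdductExperiment` wraps a `SummarizedExperiment`: one assay `peakArea`
(features × runs, `NA` = missing; zero is a *measured* intensity and is
never treated as missing, because gap filling upstream distinguishes absent
peaks from low signal), run metadata in `colData` (`injectionIndex`,
`runType` ∈ {sample, iqc, eqc, tech\_replicate}, `batch`,
`dnaConcentration` in ng/µL for samples) and feature annotations `mz` (Da)
and `rt` (s) in `rowData`. Feature identity is the row name; m/z and RT are
annotations, never keys. Column order is injection order: readers re-sort
by `injectionIndex` and say so.

The run-type vocabulary mirrors pooled-QC practice: external QCs (eQC)
bracket the sequence, internal QC pairs (iQC) are interleaved with the
samples, and the second vial of each pair is labelled `tech_replicate`.
The replicate vial is used for *evaluation* (replicate RSD\*, D-ratio
numerator); by default it also contributes to QC-derived correction
factors, which keeps factor estimates stable on sparse designs — users who
want strictly held-out evaluation can pass `qcTypes = "iqc"` to any
QC-dependent method.

# The simulator

`simulateAdductTable()` draws, per feature $i$ and run $j$ of $N$:

$$\mathrm{obs}_{ij} = a_{ij}\; d_i(j)\; b_{i,\mathrm{batch}(j)}\;
  s_j\; \varepsilon_{ij},$$

* $a_{ij}$: for samples, $\mu_i e^{\sigma_b Z}$ with baseline $\mu_i$
  log-uniform over `intensityRange` and $\sigma_b$ = `biologicalCv` (an
  optional fraction of features gets its variance multiplied by
  `highBioMultiplier`, emulating analytes present in only part of a
  cohort); for every QC run, `qcDilution` × the feature's realized mean
  sample abundance (one pooled extract); for internal standards, exactly
  $\mu_i$ in every run.
* $d_i(j) = 1 + a_i \sin(2\pi j/P_i + \phi_i) + s_i j/N$, clipped at 0.05:
  multiplicative drift, matching the divide-by-factor contract of all six
  corrections. Defaults: amplitude 0.1–0.3, period 40–110 injections,
  trend ±15 % across the sequence. The period cap near the sequence length
  is deliberate: slower behaviour is statistically indistinguishable from
  the linear-trend term within one sequence, so modelling it as a longer
  period would only create an identifiability overlap.
* $b$: per-feature per-batch lognormal offsets (`batchEffectSd` on the log
  scale); batches are contiguous spans of near-equal size.
* $s_j$: sample runs are scaled by their DNA amount relative to the
  population mean (lognormal, mean `dnaConcMean` = 50 ng/µL, CV 0.3); QCs
  are pooled after extraction and are not scaled. This makes
  DNA-concentration correction testable and gives internal standards a
  sample-run variance component that the correction removes exactly.
* $\varepsilon$: lognormal technical noise, `techCv` = 0.05 by default.
* Censoring: a cell is missing with probability
  $\mathrm{logit}^{-1}(\texttt{missingSteepness}\,(\texttt{lod} -
  \mathrm{obs}))$ — low values vanish more often, which is why
  half-minimum imputation is the appropriate counterpart.

The sequence layout is fixed by the design the field uses: `nEqc` external
QCs, blocks of `blockSize` (default 10) samples each followed by an iQC
pair whose second vial is the technical replicate, `nEqc` external QCs at
the end. With the defaults this yields one QC injection per six sample
injections on average. Identical configurations (including the seed) give
bit-identical output; `SimTruth` carries the latent abundances, the drift
surface, the batch factors and the internal-standard ids.

What the simulator does **not** emulate: retention-time shifts (alignment
is upstream), correlated noise between co-eluting features, heteroscedastic
detector noise, and non-multiplicative drift. Tests passing on simulated
data therefore certify the *algorithms* under the stated noise model, not
instrument behaviour beyond it.

# Preprocessing

* `filterMissing()`: a feature is removed iff its missing fraction **among
  sample runs** exceeds the threshold (default 0.5, strict inequality — a
  feature missing in exactly half the samples is kept). QC runs never
  enter the fraction; filtering precedes imputation.
* `imputeHalfMin()`: each missing cell of feature $i$ is an independent
  draw from $U(\min_i/2, \min_i)$, where $\min_i$ is the smallest observed
  value across **all** runs — the narrower reading (samples only) is not
  taken because the minimum is a detection-limit proxy, which QC runs
  inform equally. Draws are seeded; observed cells are never touched.
* `dnaConcCorrect()`: sample-run areas are divided by the run's DNA
  concentration and multiplied by the arithmetic-mean concentration over
  sample runs; QC runs (pooled after extraction) are unchanged.
* `pcaTransform()`: log2, per-feature centering and unit scaling, then SVD
  with runs as observations. Zero-variance features are dropped with a
  message; component signs are fixed by making each component's
  largest-magnitude loading positive, so score plots are reproducible.

# The six corrections and their common contract

Every method computes strictly positive factors and applies
$$\mathrm{corr}_{ij} = \frac{\mathrm{raw}_{ij}}{f_{ij}} \cdot
  \mathrm{median}(f),$$
the median over runs for sample-based methods (TIC, median) and over the
feature's own factors for feature-based ones (FBSC-B, lomec, LMBSC,
QC-RLSC). The rescale keeps corrected data on the original intensity scale
so relative dispersion statistics stay interpretable, and makes the round
trip `corrected × factor / rescale = raw` an invariant the tests assert to
1e-9.

* **TIC / median**: one factor per run — the run's total or median
  intensity.
* **FBSC-B**: per feature, the mean over the bracketing iQC pairs (nearest
  pair before and after the run, four values when both sides exist, the
  run's own pair for QC runs) divided by the feature's grand QC mean. The
  exact bracket definition is this package's; pairs are detected as
  maximal blocks of consecutive injection indices in the QC set.
* **lomec**: per feature, the mean over the `windowK` (default 4) QC runs
  nearest in injection index (ties toward earlier injections) divided by
  the grand QC mean. With `windowK` = all QCs the factors collapse to 1.
* **LMBSC**: per feature, OLS of QC intensity on injection index; only
  when the slope's two-sided t-test gives p < α (default 0.05) is the
  feature corrected by the ratio of the fitted line to its value at the
  mean QC index. Caveat: back-to-back QC vials are not independent
  observations of the drift process; on dense paired designs the slope
  test can over-trigger. On the default design (pairs every 12
  injections) the corrected fraction under drift with no linear component
  stays near α.
* **QC-RLSC**: per feature, a LOESS curve (tricube weights, degree 2 by
  default, `stats::loess` with direct surface evaluation) is fitted to QC
  intensity vs injection index; the span is chosen from a grid
  (0.20–0.95 by 0.05) by generalized cross-validation
  $\mathrm{GCV} = n\,\mathrm{RSS}/(n - \mathrm{tr}\,L)^2$, with the
  smoother trace computed exactly up to n = 200 points and by loess's
  approximation above. The factor is the fitted curve at each run's
  injection index; outside the QC range the boundary fitted values extend
  as constants (the drift estimate is not extrapolated). The smoother is
  evaluated directly at sample positions rather than interpolated
  linearly between QCs. Ties in GCV resolve to the first (smallest) span
  in the grid.

Numerical safeguards: fitted factors below $10^{-6}\times$ the feature
median are clamped to that epsilon with a warning tally rather than
erroring, because one pathological feature should not abort a
5,000-feature run; genuinely non-positive factors elsewhere raise an error
naming the feature and run.

`batchAlignMean()` (applied after within-batch normalization when several
batches are declared) scales each batch, per feature, by
grand-mean / batch-QC-mean. Batch membership is always declared by the
user, never inferred from score plots. Applied to a `NormalizationResult`,
the alignment folds into the stored factor surface so the round-trip
invariant keeps holding.

# Quality metrics and retention

RSD\* is the robust coefficient of variation
$1.4826\,\mathrm{MAD}/|\mathrm{median}|$; the 1.4826 constant makes it
comparable to an ordinary CV for Gaussian data, so the usual retention
thresholds carry over. The D-ratio is
$\mathrm{MAD}_\mathrm{rep}/\mathrm{MAD}_\mathrm{sample}$ (the constant
cancels). `evaluateFeatures()` computes RSD\* over the technical-replicate
vials, the D-ratio against sample runs, applies **strict** thresholds and
retains features passing both. Degenerate features (zero replicate median,
zero sample MAD) receive `NA` metrics and fail — a feature with no sample
dispersion carries no usable biological signal. For internal-standard
evaluation the same RSD\* is computed over sample runs via
`featureRsd(x, "sample")`; imputed cells are included, and the per-feature
imputed-cell counts are kept in the object metadata so users can audit
their influence.

A known caveat the package's tests reproduce: sample-based factors (TIC,
median) carry the biological variation of dominant features into every
other feature. For quiet features this inflates the sample MAD more than
the replicate MAD — sample RSD\* rises *and* the D-ratio falls, so a
D-ratio filter can silently reward the very method that injected variance.
The acceptance suite asserts this jointly on a drift-free simulation where
10 % of features carry 10× biological variance; drift is switched off
there so the leakage is the only unwanted-variation source being measured.

# Comparison statistics

`durbinConover()` implements the pairwise comparison for balanced complete
block designs (blocks = internal standards, treatments = normalization
methods): within-block ranks, the Durbin statistic $T_1$, and the Conover
t statistic on rank-sum differences with $(b-1)(k-1)$ degrees of freedom.
The implementation is validated against an exhaustive within-block
permutation oracle on 3 × 3 toys; on such tiny designs the permutation
null is coarse (216 arrangements), so agreement is asserted on fixtures
where the discrete null resolves the t reference, and the test's size is
additionally checked globally (type-I rate 0.05 ± 0.02 over 2,000 null
datasets). `dunnAllPairs()` uses joint midranks with the standard tie
correction; for two groups its z² equals the Kruskal–Wallis H, which the
tests assert to 1e-10. Holm adjustment delegates to `stats::p.adjust` and
is re-verified against the step-down formula. All p-values are two-sided;
star labels use the conventional cut levels (0.05, 0.01, 0.001, 1e-4).

# Peak-picking advisor

Operating on plain EIC summaries (run, target, rt, mz, intensity), the
advisor estimates: the **ppm spread** as the maximum pairwise m/z
difference among apex-region points (≥ 50 % of each trace's apex — a proxy
for a restricted window with one mass peak per spectrum) over the median
m/z; **peak-width bounds** as the min/max over traces of the width at 5 %
of the baseline-subtracted apex (baseline = median of the lowest intensity
quartile, crossings linearly interpolated, floored at one scan interval);
and a **minimum grouping fraction** `safety × min(detection rates)`,
rounded down to two decimals and floored at 0.01, so the rarest known
target still forms a feature. The measured ppm spread is reported next to
a configurable instrument floor (default 5 ppm) — instruments drift over a
study, so the advisor reports both and leaves the choice explicit.

# Reproducibility and problem sizes

Every stochastic step (simulation, imputation) takes an explicit seed, and
`runWorkflow()` writes a config echo plus a JSON summary that is
byte-identical across reruns of the same configuration. The test-suite and
acceptance problem sizes — 500 features × 128 runs for drift recovery,
200 × 74 over 20 seeds for the inflation direction, 2,000 replicates for
test calibration — were chosen as the smallest designs at which the
assessed quantities are stable to well within the asserted margins.

# Limitations

* Drift is modelled (and corrected) as multiplicative; additive baseline
  drift is out of scope.
* The LOESS span grid and degree default to sensible values but are not
  optimized per study; extremely sparse QC designs (< 5 QCs) refuse
  QC-RLSC rather than degrade silently.
* Batch membership must be declared; no data-driven batch discovery.
* The Durbin–Conover test supports the balanced complete design only, the
  case that arises when every internal standard is measured under every
  normalization method.
* No alternative imputation families (kNN, probabilistic PCA) or
  variance-stabilizing transforms; the scope is the pooled-QC workflow.
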