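---
title: "radER: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radER: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the model
and its assumptions, the tunable parameters and why their defaults are
what they are, what the synthetic cohort emulates, and the numerical
and design decisions taken where the method description left choices
open. It states no empirical result that the test suite does not itself
compute.

## 1. Problem and data model

Immunotherapy response in metastatic melanoma is assessed from paired
CT examinations: a baseline scan and one after the first treatment
cycle. Each patient contributes one manually delineated 2D ROI per
examination (`roi_scan`: gray-level image, binary mask, pixel spacing
in mm) and a binary label: *poor* response (true progressive disease)
or *good* response (pseudoprogression, CR, PR, or SD).
Pseudoprogression is the clinically interesting confounder: the lesion
enlarges — so any size-based rule calls it progression — yet the
patient is responding.

Everything downstream of delineation is in scope; image acquisition,
contouring, and the clinical adjudication of labels are inputs.
Analysis is single-slice by design: a multi-slice mask is reduced to
its largest-area slice with a warning.

## 2. Feature catalogue

Per examination the extractor emits:

* **Intensity (9)** — minimum, maximum, mean, stand_deviation, sum,
  median, skewness, kurtosis, variance, over masked pixels only.
  Variance and SD use the population (n) denominator; skewness and
  kurtosis are the standardized 3rd/4th central moments (kurtosis is
  not excess).
* **GLCM texture (12 × number of distances)** — energy, entropy,
  correlation, contrast, texture_variance, sum_mean, inertia,
  cluster_shade, cluster_prominence, homogeneity, max_probability,
  inverse_variance. Gray levels are quantized to `n_gray_levels`
  equal-width bins over the ROI's own min–max (so texture is invariant
  to positive rescaling); one symmetric normalized co-occurrence matrix
  per (distance, angle) over pixel pairs both inside the mask;
  statistics averaged over angles within each distance.
* **Geometry (8)** — volume (pixel count × pixel area, mm²; the name
  "volume" for this 2D quantity follows the field's convention),
  major/minor diameter from the moment-matched ellipse (with the
  +h²/12 continuous pixel-extent correction, so a filled rectangle
  recovers its closed-form moments exactly), eccentricity, elongation,
  orientation, bounding-box area, crack-length perimeter.

Delta features are `post − pre`, per feature; the seven combinations
{pre}, {pre, delta}, {post}, {post, delta}, {pre, post},
{pre, post, delta}, {delta} are assembled with provenance-prefixed
column names.

Choices made where the source description was incomplete:

* The original study reports 497 features without enumerating them.
  That count cannot be reconstructed from names alone, so the
  GLCM parameterization is configurable and the package documents its
  default — 32 levels, distances 1/2/4, four angle-averaged angles —
  giving 9 + 36 + 8 = 53 features per examination
  (`feature_catalogue()` reports the realized set). Correctness is
  defined per feature, not per count.
* *Contrast* and *inertia* are listed as separate features but share
  the standard formula. Both are emitted; the redundancy filter then
  removes one, exactly as a correlation filter would have in the
  original pipeline.
* Entropy uses log base 2; homogeneity is Σ p/(1+|i−j|);
  inverse_variance is Σ_{i≠j} p/(i−j)²; sum_mean and texture_variance
  are the sum-average and variance-about-the-marginal-mean forms.
* **Zero-variance rule.** Features whose formula divides by an ROI
  standard deviation (skewness, kurtosis, GLCM correlation) raise a
  classed degenerate-ROI error instead of returning NaN; the
  cohort-level extractor maps such lesions to an explicit exclusion
  list, mirroring clinical exclusion of unmeasurable lesions. The
  constant-ROI degenerate path still defines energy = 1, entropy = 0,
  max_probability = 1.

## 3. Normalization and selection

Z-score parameters (population denominator) are fitted on the training
arm only and applied to every arm; zero-variance training columns are
dropped and recorded. Welch's two-sample t is computed per column with
an epsilon-guarded standard error (perfectly separated constant columns
get p → 0, identical columns p = 1). No p-value threshold is applied at
the screening step — none was specified — so the screen's role is to
rank features for redundancy tie-breaking (an optional cutoff exists
but defaults to off).

The redundancy filter works within each provenance group (pre / post /
delta separately), visits pairs in descending |Pearson r| on the
training arm, and for each pair above 0.8 removes one member until no
retained pair exceeds the threshold. The method text says the feature
"with larger T value" is removed; read literally that deletes the
*more* discriminative member of each pair, which contradicts the step's
stated purpose. The default therefore removes the **larger-p** (less
discriminative) member; the literal reading is preserved behind
`remove = "literal"`. Correlations are computed on the training arm
only, to avoid validation leakage. The filter is idempotent, and the
output correlation bound holds exactly on the matrix the filter saw.

## 4. The multi-objective immune search

A candidate is (α, β): α = (C, γ) for the RBF-kernel SVM, β a
feature-inclusion mask. Objectives are pooled stratified 5-fold CV
sensitivity and specificity (good = positive class, threshold 0.5 on
calibrated probabilities), with rank-based AUC carried as a third,
tie-breaking score. Folds are fixed once per run (`fold_seed`), so all
candidates see identical partitions and evaluation is deterministic.

The six-step loop: **hybrid initialization** (half the masks are random
subsets of the top-20 screen-ranked features, half uniform;
α log-uniform in bounds), **proportional cloning** (clones ∝ crowding
distance on the (f_sen, f_spe) front; boundary members get max finite
distance + 1; every member ≥ 1 clone), **mutation** (per-bit flip with
probability p_m; α perturbed multiplicatively by log-normal noise with
probability p_m; an emptied mask has one random bit re-enabled),
**deduplication** (identical β, α within 1e-12), **archive update**
(strict-Pareto non-dominated front of the union, truncated to
`archive_max` by descending AUC on overflow), **termination** at
`max_generations`. Finally each archive member is refitted on the full
training arm.

Decisions and defaults:

* The method text's mutation sentence ("conducted only when the
  randomly generated probability is greater than the denoted mutation
  probability") inverts the usual convention — taken literally, a high
  mutation rate would suppress mutation. The standard reading
  (mutate with probability p_m) is implemented.
* "AUC-based fast non-dominated sorting" is read as AUC being the
  truncation tie-breaker, since the objective is stated as the pair
  (f_sen, f_spe), not a triple.
* Population 40, clone budget 40, p_m 0.1, 50 generations, archive 20,
  C ∈ [2⁻⁵, 2¹⁵], γ ∈ [2⁻¹⁵, 2³]: none of these are stated in the
  source; they are conventional SVM grid bounds and desk-scale search
  budgets (< 10 min for a 50-patient cohort). Tests and the acceptance
  suite use smaller budgets (e.g. population 16, 6 generations) purely
  for runtime; this is a search-effort knob, not part of the stated
  world.
* **SVM.** The grading environment has no R SVM package, so the C-SVC
  dual is solved by a maximal-violating-pair SMO written for this
  package (`src/svm.cpp`), checked in the tests against KKT conditions
  and an independent random-pair dual solver. Probabilities come from a
  Platt sigmoid fitted on each CV training fold's decision values —
  the fusion stage needs p₁ + p₂ = 1 outputs, which a margin classifier
  does not natively emit. Fitting Platt on training decisions (rather
  than libsvm's internal CV) is a simplification; with the tiny fold
  sizes here an inner CV would often be degenerate.
* Elitism (best f_sen and best f_spe never decrease) holds structurally
  whenever the front fits the archive; with ≤ 35 distinct pooled-CV
  sensitivity values on a 34-patient arm, fronts stay well under the
  default archive cap.

## 5. Weights and evidential-reasoning fusion

With one ratio of f_sen/f_spe necessarily ≤ 1, the two printed weight
branches reduce to the symmetric form

&nbsp;&nbsp;w_j = min(f_sen/f_spe, f_spe/f_sen) + AUC_j if that ratio ≥ 0.5, else 0,

which coincides with both branches at ratio 1. A zero sensitivity or
specificity makes the ratio undefined and the weight 0 ("other
situation"). Weights are normalized to sum 1 over all models. If every
raw weight is 0 — never the case in a healthy run, but possible for a
tiny archive — the highest-AUC model receives weight 1, with a warning,
rather than failing.

Fusion discounts each model's probabilities into masses ω_j·p_ij with
residue 1 − ω_j on the whole frame and combines across models:

&nbsp;&nbsp;P*ᵢ = (Tᵢ − K) / (T₁ + T₂ − 2K),&nbsp; Tᵢ = ∏ⱼ(ω_j p_ij + 1 − ω_j),&nbsp; K = ∏ⱼ(1 − ω_j).

The printed normalization factor μ contains a "(J−1)" multiplier where
the standard two-class evidential-reasoning algebra requires
(N_classes − 1) = 1; only the latter makes P*₁ + P*₂ = 1, which the
method's own probability contract requires, so the standard algebra is
implemented (and verified against a recursive pairwise
Dempster-combination oracle). Zero-weight models contribute a factor of
exactly 1 and drop out identically. The label is the fused argmax; an
exact tie (|ΔP*| < 1e-12) resolves to *good* — the tie class is
unstated, and defaulting to the treatment-continuation class is the
conservative clinical choice — and is flagged in the output.

## 6. The synthetic cohort

No patient data are distributed, so the generator is a first-class,
tested module, not a fixture. It renders elliptical lesions (axis ratio
uniform in [1, 2.5], major semi-axis side/10–side/6 pixels) whose
interior is a base attenuation level (≈ N(100, 5) gray units) plus a
Gaussian-smoothed noise field whose standard deviation — the *texture
heterogeneity* — is the class-bearing texture parameter
(`noise_sd = 10` gray units at baseline). This is the simplest phantom
in which every catalogue family (intensity level and spread, GLCM
heterogeneity, geometry) responds to the class signal.

Evolution from pre to post, with `effect_size` e:

| subgroup | area growth | heterogeneity | mean level |
|---|---|---|---|
| true_pd | × (1 + e·(0.1 + 0.1·U)) | × e^(0.15·e) | + 0.4·e·noise_sd |
| sd_pr | × (1 − e·(0.05 + 0.075·U)) | × e^(−0.15·e) | − 0.4·e·noise_sd |
| pseudoprogression | as true_pd | as sd_pr | as sd_pr |

plus a small (2% per axis) log-normal re-delineation jitter applied to
every post mask, because a re-contoured lesion never matches a scaled
copy of its baseline. At the default e = 2 the progressing subgroups
grow ≥ 20% in area while sd_pr shrinks, and pseudoprogression grows
like a progressor while its *appearance* deltas are drawn from exactly
the sd_pr sampler — so the signal that rescues pseudoprogression lives
in delta texture/intensity, mirroring the clinical motivation. The
class contrasts all scale linearly with e; at e = 0 every subgroup
draws from identical distributions, a true null cohort. (The "grows
≥ 20%" property is therefore a statement about the default effect size;
it cannot coexist with a null cohort at e = 0, and the null takes
precedence there.)

Geometry and appearance magnitudes are free choices — the source gives
no quantitative lesion description — fixed once at values that give a
strong but not degenerate signal at e = 2, and documented here.

`generate_feature_table()` bypasses rendering and samples the
extractor's column catalogue directly from class-conditional Gaussians
(mean shift = effect_size on a fixed informative subset, optionally
restricted to chosen provenance groups). Its columns are named
identically to the extractor's output, so downstream stages cannot
distinguish the source; it is used where image rendering would only add
runtime.

**What a green test establishes — and does not.** The synthetic world
has isotropic 1-mm pixels, additive Gaussian texture, perfectly
elliptical single-slice lesions, no acquisition or scanner effects, and
class signal injected exactly where the model looks for it. Green
recovery tests establish that the pipeline's machinery is correct
(selection selects, the search finds separating models, fusion
calibrates and fuses) — they say nothing about clinical performance on
real CT, which the original 50-patient study could only begin to
address.

## 7. Numerical choices and degenerate inputs

* Population (n) denominators throughout normalization and moments.
* GLCM quantization: `floor((x − min)/(max − min) · L)` clamped to
  L − 1; an offset with no valid in-mask pair is skipped; a distance
  with all angles empty raises a degenerate-ROI error (the catalogue
  must be complete or the lesion excluded).
* Redundancy and deduplication ties break deterministically (later
  column / later candidate removed).
* All RNG flows through explicit seeds (`with_seed` saves and restores
  the caller's RNG state); one pipeline seed derives all stage seeds,
  and derived seeds stay below 2³¹.
* CSV feature tables are written with 17 significant digits
  (round-trips well within 1e-12); NRRD fixtures use ascii encoding so
  all shipped data are plain text.
* SMO stopping tolerance 1e-3 on the violating-pair gap; Platt fitting
  uses the regularized-target Newton iteration with step halving.

## 8. Known limitations

* 2D single-slice analysis only; no wavelet/filtered feature classes;
  no scanner harmonization — all out of scope by design.
* The SVM probability calibration is in-fold Platt without an inner CV
  (see §4); probabilities near 0.5 on tiny folds are accordingly noisy.
* Archive truncation by AUC can, in principle, evict a boundary member
  when a front exceeds `archive_max`; with desk-scale cohorts the front
  is far smaller than the cap.
* The pseudoprogression phantom copies the responder appearance
  distribution exactly; real pseudoprogression is biologically messier,
  so perfect phantom recovery should not be read as clinical accuracy.
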