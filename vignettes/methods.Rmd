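---
title: "Generative anomaly detection and worklist triage for head CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative anomaly detection and worklist triage for head CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Emergency head CT triage asks a question that supervised lesion detectors
answer poorly: *is anything at all wrong with this scan?*  Supervised models
cover only the entities they were trained on; an emergency department sees
everything from hemorrhage and infarction to mass lesions, hydrocephalus,
and rarities.  The approach implemented here inverts the problem: a deep
generative model is trained **only on normal scans**, so that any query
image can be projected onto the manifold of normal anatomy.  Whatever the
model cannot reproduce — the residual between the image and its *closest
normal-style reconstruction* — is evidence of abnormality, usable both as a
scalar triage score and as a lesion attention map.

## Model components

The backbone is a style-based generator/encoder/discriminator triple:

* **G** (generator): a synthesis network that grows a learned 4×4 constant
  through progressively upsampled levels.  Each level has two style
  layers; each layer modulates its input channels with a per-layer style
  vector, convolves, injects a per-layer spatial noise map scaled by a
  learned per-channel gain, and applies a leaky ReLU (slope 0.2).
* **E** (encoder): follows the discriminator architecture, with the final
  dense layer widened to emit the full extended latent code — one style
  vector per synthesis layer (the W+ convention) — followed by a leaky
  ReLU of slope 0.2.  At full scale (512 px, 16 layers × 512 dims) the code
  is 8192-dimensional; at reduced scale it is `n_layers * style_dim`.
* **D** (discriminator): a standard convolutional critic.

### Two-phase training

1. **Phase 1** trains G and D adversarially (non-saturating logistic loss,
   R1 gradient penalty on real images applied on every 16th step).
2. **Phase 2** freezes G and trains E and D with three losses: a perceptual
   reconstruction distance between `x` and `G(E(x))`, a *domain-guided*
   L1 consistency between `E(x)` and `E(G(E(x)))` that pulls codes into the
   region of latent space whose reconstructions re-encode to themselves,
   and the adversarial loss through the frozen G.  Random erasing of the
   encoder input forces E to learn normal-anatomy semantics by inpainting.

Adam is used throughout with β₁ = 0, β₂ = 0.99, ε = 1e-8.  The full-scale
regime (160k + 200k iterations, minibatch 32, learning rates 1e-5 for E and
1e-6 for D) is impractical and unnecessary at desk scale; with ~2000 total
iterations the defaults are `lr_e = 1e-3`, `lr_d = 5e-4` (phase 2) and
2e-3 (phase 1).  These are scale-dependent settings, not tuning knobs: at
1e-5, two thousand steps cannot displace freshly initialized weights by
more than a fraction of a percent of their scale.

### Desk-scale architecture economies

Everything runs on a single CPU in plain R (the linear algebra is BLAS).
Three economies make that feasible, all configurable back to the faithful
full-scale layout:

* channel counts shrink with resolution (32 → 2 at 64 px);
* the encoder/discriminator trunk uses one convolution per resolution
  level;
* the top one or two levels use pointwise (1×1) convolutions
  (`point_levels`); spatial detail at those scales comes from upsampling
  and the noise maps, which the inversion stage optimizes per pixel anyway.

### Input normalization

Images are clipped to a brain window (`hu_window`, default [-20, 120] HU)
and mapped affinely to [-1, 1] before entering any network; outputs are
mapped back to HU, and **all masks and thresholds operate in HU**.  A wide
window (e.g. [-100, 1000]) would make the 5 HU mask threshold 0.45% of the
dynamic range and demand unrealistic reconstruction precision; the brain
window makes it ~3.6%.  Skull and air clip to the window edges, which is
immaterial because brain extraction removes them from every residual.

### Perceptual distance

No pretrained VGG-style feature network is available offline, so the
perceptual distance is an injectable interface whose default is a
deterministic multi-scale Gaussian-pyramid mean-squared distance: both
images are resampled to a working resolution (half the image resolution,
mirroring the full-scale choice of 256 px for 512-px images), then compared
across a blur-and-decimate pyramid down to 4×4.  It is symmetric, zero only
for identical inputs, differentiable, and needs no downloaded weights.

## Gaussianized latent space

Every normal training slice is encoded and the sample mean μ and covariance
Σ of the codes are accumulated **per slice order and per layer**
(block-diagonal across layers; the full 8192×8192 covariance is neither
supported by the text nor estimable).  Σ is shrunk by `eps·I` with
`eps = 1e-4 · trace(Σ)/d`, guaranteeing positive definiteness at small
sample counts.  The deviation of a code from this model is the per-layer
Mahalanobis distance, summed over layers.

## Inference

For each axial slice (a scan holds up to 32, bottom to top):

1. **Latent optimization.** Initialize `w ← E(x)` and the noise maps from a
   seeded standard normal.  Optimize `w` by Adam for 100 epochs under
   L1 + perceptual + a *conditional* in-domain term: the Mahalanobis
   deviation is penalized only while it exceeds that of the reference
   in-domain code `E(G(E(x)))`, and what is penalized is the dimensionless
   excess `dev/dev_ref − 1`.  Two numerical points matter here (both were
   found the hard way): penalizing the raw deviation makes the objective
   jump discontinuously when the condition switches on, which freezes
   best-iterate selection at the initial code; and measuring the deviation
   in absolute Mahalanobis units makes its gradient hundreds of times the
   data-term gradients whenever the empirical latent Gaussian is tight,
   which permanently distorts Adam's second-moment state.  The excess form
   is continuous at the boundary and the reference-level normalization
   keeps the two gradient scales comparable.  The best-loss iterate is
   returned (optimization is non-monotone, and this makes the "no worse
   than the initialization" contract exact).
2. **Masked noise optimization.**  With `w*` fixed, 100 Adam iterations on
   the noise maps.  At each step a binary mask M is recomputed: the
   brain-extracted absolute residual is median-filtered (window 17 px at
   512-px resolution, scaled as `round_to_odd(17·width/512)` otherwise) and
   thresholded at 5 HU, then intersected with all previous steps' masks, so
   |M| is non-increasing.  The optimization target is
   `M ⊙ G(w*, n_init) + (1-M) ⊙ x`: the model is forced to reconstruct the
   normal region alone, and can never fit the suspected lesion.  The final
   mask is the lesion attention map.

On the hot path the filter-then-threshold step uses an exact equivalence:
the median of an odd window exceeds t iff more than half the window's
entries do, which reduces the operation to a box count of the binarized
residual.  The literal median filter is kept and cross-checked in the
tests.

Brain extraction thresholds to soft tissue (HU in (-50, 150)), keeps the
largest connected component, and fills holes.  Phantoms carry exact region
labels, so tests can compare against ground truth.

One stated ambiguity: the scored reconstruction could use the optimized or
the initial noise maps.  The default scores `G(w*, n*)` (config
`recon_noise = "init"` for the alternative); with the mask excluding the
lesion, both choices leave the masked error dominated by the same residual.

## Anomaly score

The per-slice error is the binary-masked L1 density error
`R(x_i) = ||M ⊙ (x_i - G(w, n))||₁` in HU (the text calls it a density
error and uses L1 everywhere else; L2 is a config switch).  On a held-out
normal calibration cohort (1000 scans at full scale; 20 at desk scale) the
per-slice-order mean R_μ and SD R_σ are estimated, with an SD floor of
`1e-6·max(R_μ, 1)` against degenerate perfect reconstruction.  The scan
score is the sum of `(R(x_i) - R_μ)/R_σ` over the scan's present slices —
scans shorter than 32 slices sum over what they have, with no imputation
(a documented score-scale caveat).  By construction the calibration cohort
itself has per-order z-mean 0, z-SD 1, and mean score 0.

## Threshold tuning and uncertainty

Positive calls are `score ≥ threshold`; candidate thresholds are midpoints
between adjacent sorted unique scores plus ±∞.  The default operating point
maximizes Youden's J on a tuning cohort (ties resolve to the lowest
threshold, i.e. the higher-sensitivity side); fixed-sensitivity policies
(0.95, 1.00) return the largest threshold whose tuning sensitivity reaches
the level.  AUC is computed as Mann–Whitney concordance with ties counted
one half (identical to the trapezoidal ROC area), and confidence intervals
use a seeded percentile bootstrap (10,000 case resamples at full scale),
with degenerate single-class resamples redrawn under a retry cap.

## Worklist triage simulation

The randomized crossover design: cases are shuffled and split near-equally
into groups A and B (larger group first; 1795 cases split 898/897), each
group cut into blocks of 23 with the remainder absorbed into the final
block (898 → 39 blocks, the last of 24).  One block is one radiologist's
worklist at one time.  In session 1, group A is read without triage and
group B with it; session 2 crosses over; block reading order is permuted
independently per session.  Triage moves flagged cases (score at or above
threshold) to the front of their block in descending score order, leaving
the rest in original relative order.

Within a block, cases are opened back-to-back from the block opening at
t = 0.  Wait time is case opening minus block opening; turnaround time is
report filing minus block opening; reading time is closing minus opening.
Two modeling decisions the source leaves open: every case's report time
equals its closing time (turnaround is then defined for non-emergency cases
too), and the two readers are pooled as independent reader-case
observations (per-reader output remains available).  The simulated reader
draws log-normal reading times with median 30 s and log-SD 0.28, matching
the scale and spread of expert reading times (median ~30 s, IQR ~11 s);
summaries use linear-interpolation quartiles, Wilcoxon signed-rank tests
for paired pre/post contrasts and rank-sum tests between subgroups.
Externally recorded per-case times (columns
`case_id, group, reader, session, arm, WT, TAT, RT`) can be loaded and
summarized by the same code path.

## The phantom module: what it does and does not establish

The synthetic head-CT generator emulates exactly the statistical structure
the method assumes: a *learnable normal class* — elliptical skull ring
(~800–1200 HU), parenchyma (~22–48 HU) with smooth low-frequency texture
and mild pixel noise, air at ≈ -1000 HU, near left-right symmetric
geometry, and paired ventricles (~0–12 HU) whose area **grows monotonically
with slice order**, so per-slice-order calibration is exercised
non-trivially — plus density-deviating lesions with exact ground-truth
masks.  Hyperdense lesions add +40…+80 HU on a disc (hemorrhage-like),
hypodense lesions -15…-30 HU (infarct-like), and mass lesions additionally
displace surrounding tissue laterally by 2–4 px.  Severity
(|ΔHU|·radius²) separates immediate from urgent cases; emergency
prevalence defaults to 0.11, the screening-cohort scale.  Non-mass lesions
are constant offsets, so injection is exactly invertible — that makes the
footprint contract (`mask == changed pixels`) bit-testable.

A green desk-scale run establishes that the *pipeline* — training, latent
statistics, inversion, masking, calibration, scoring, tuning, simulation —
behaves as designed on data with the assumed structure.  It does not
establish clinical performance: phantoms have no scanner physics, no
anatomical variability beyond the parameterized geometry, no benign-vs-
pathological ambiguity, and lesions that are geometrically simple.  The
published real-data operating characteristics (AUC ≈ 0.85–0.87 on ED
cohorts) require the hospital datasets, which are not distributable.

## Numerical choices

* All stochastic entry points take explicit seeds; training, phantom
  generation, inversion and bootstrap are bit-reproducible at fixed seed
  and thread count.
* The R1 parameter gradient is computed exactly by a tangent
  (double-backward) pass through the network's local linearization — valid
  almost everywhere because the networks are piecewise linear — rather
  than by finite differences.  Bias gradients of the penalty are
  identically zero and are set so.
* Adam runs vectorized over flattened parameter trees.
* Covariance shrinkage, the SD floor in calibration, and the odd-window
  constraint on the median filter are the three guards against degenerate
  inputs; each is unit-tested.
* When forming Σ⁻¹ for whitening, eigenvalues are floored at
  `cond_floor = 1e-2` times the global mean code variance: at desk-scale
  sample counts some encoder layers collapse to near-constant codes, and
  near-null sample directions are statistical artifacts whose uncapped
  inverses explode the whitened gradients.  The reported Σ itself stays
  the (shrunk) sample covariance.
* The in-domain weight defaults to 0.005, chosen so that at the switch
  boundary the term's gradient is on the order of the data-term gradients
  (a gradient-balance rule, not a tuned constant).

## Known limitations

* The perceptual default is a fixed pyramid, not a learned feature space;
  with pretrained weights available, a drop-in feature extractor can be
  injected.
* Desk-scale pointwise top levels limit very-fine-detail synthesis; set
  `point_levels = 0` (and widen channels) when compute allows.
* Scans are processed slice-wise; no 3-D coupling beyond the slice-order
  statistics.
* Scan archives use a gzipped-CSV + JSON-sidecar format; NIfTI IO is out
  of scope here because no NIfTI reader exists in the supported dependency
  set and hand-rolling the binary format was judged worse than documenting
  the restriction.
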