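---
title: "Quantifying the retinal microvasculature in en-face OCTA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the retinal microvasculature in en-face OCTA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octaquant)
```

```{r demo, eval = FALSE}
# minimal end-to-end run: simulate a small cohort, quantify, analyse
cfg <- run_config(out_dir = "demo_out", seed = 1,
                  cohort = cohort_spec(n_control = 6, n_brvo = 4, n_crvo = 4))
res <- run_pipeline(cfg)
res$comparisons[res$comparisons$metric == "vd", c("layer", "contrast", "beta", "p_value")]
```

## The measurement problem

Optical coherence tomography angiography (OCTA) produces en-face maps of
retinal blood flow without dye injection. In retinal venous occlusion (RVO),
capillaries drop out — sectorally when a branch vein is blocked (BRVO),
diffusely when the central vein is blocked (CRVO) — and the surviving
capillary bed dilates. `octaquant` turns a single-channel en-face angiogram
of a 3×3 mm fovea-centered field into four scalars:

* **VD (vessel density)** — the fraction of the image area classified as
  perfused after binarization. A healthy macular plexus sits near 0.43.
* **SD (skeletal density)** — the fraction of the image area occupied by the
  one-pixel-wide skeleton of the binarized map. Because every skeleton pixel
  contributes unit length, SD proxies total vessel length independent of
  caliber (healthy ≈ 0.1).
* **FD (fractal dimension)** — the box-counting dimension of the skeleton,
  quantifying branching complexity (healthy macular vasculature ≈ 1.7; a
  single vessel would give 1, a solid sheet 2).
* **VDI (vessel diameter index)** — vessel pixel count divided by skeleton
  pixel count, i.e. the average caliber in pixels (healthy ≈ 4.4 at the
  native device scale).

Three retinal slabs are handled: the superficial (SRL) and deep (DRL)
vascular plexuses and the nonsegmented whole retina (NS-RL). The package
consumes already-segmented per-layer en-face images; segmentation of OCT
volumes and projection-artifact removal are out of scope.

## The per-image chain and its numerical choices

`quantify()` composes `binarize()` → `skeletonize()` → the four metrics.

**Binarization.** The default chain applies a white top-hat (grayscale
opening with a disc of radius `tophat_radius = 15` px subtracted from the
image) to flatten slowly varying background, then a global Otsu threshold on
256 levels. The top-hat makes the chain invariant to constant intensity
offsets, and the global threshold is recorded in `threshold_used` for audit.
Alternatives (`mean-sd`, `adaptive` moving-average) are exposed because the
binarization stage is the least standardized step in published OCTA
pipelines; on noiseless two-level images all of them must and do recover
the ground-truth raster exactly. Constant images raise a degenerate-image
error rather than returning an empty mask: excluding an unanalyzable image
is recoverable, silently feeding zeros into cohort statistics is not.

**Skeletonization.** Guo–Hall two-subiteration parallel thinning, followed
by a sequential cleanup that deletes simple pixels (Hilditch crossing
number 1) from any residual fully-set 2×2 block; the thin + cleanup cycle
repeats to a fixed point. The contract — skeleton ⊆ mask, no 2×2 block,
8-connected component count preserved, idempotence — is enforced by
property tests rather than by trusting the algorithm choice. Skeleton
*length* is the plain pixel count, not a √2-weighted path length; this
convention makes `VDI = VD / SD` hold as an exact algebraic identity and
reproduces the familiar magnitude of the healthy ratio 0.43 / 0.099 ≈ 4.4.

**Box counting.** Box sides are powers of two from 2 px up to a quarter of
the smaller image dimension, one grid anchored at the origin, ordinary
least squares on log N(s) vs log(1/s). At least four sizes are required.
The fit's R² is reported and a warning is raised below 0.99 — periodic or
near-degenerate patterns are flagged rather than silently summarized. A
single anchored grid keeps the estimate deterministic; multi-offset or
sliding-box schemes reduce variance slightly but would add a tuning
parameter with no bearing on group contrasts.

## The synthetic angiogram generator

There is no public image set attached to this problem, so the generator is
a first-class module, not a fixture. `grow_network()` grows trunk vessels
from the field edge as tortuous random walks with stochastic branching,
then fills space with short capillary segments until the *rasterized*
coverage reaches the target (closed loop against the same rasterizer used
for rendering, so a coverage target of 0.40 yields a measured VD of
0.40 ± 0.03). No centerline enters the foveal avascular zone (default
radius 0.3 mm). `apply_pathology()` implements the two occlusion patterns:
BRVO removes capillaries whose midpoint falls inside an angular wedge with
probability `dropout_fraction`, leaving the opposite hemifield untouched;
CRVO applies the same dropout globally; surviving segments dilate by
`survivor_dilation_factor`. `render_angiogram()` rasterizes each segment as
a stroke of its physical width (a pixel is set iff its center lies within
the half-width of the sampled centerline — a deterministic,
resolution-consistent rule; sub-pixel calibers clamp to one pixel with a
warning), then applies log-normal multiplicative speckle to vessel pixels
and additive Gaussian noise to background. The noiseless stroke mask is the
ground truth, which is exactly recoverable by the binarizer when noise is
switched off.

The default canvas is 1024×1024 px over 3 mm, giving ≈ 2.9 µm pixels so a
10 µm capillary is ≈ 3 px wide. The generator does **not** model OCT
speckle physics, projection artifacts between plexuses, motion artifacts,
or the merging of plexuses at the foveal rim; passing tests therefore
demonstrate that the *chain* is correct and sensitive to density/caliber
changes, not that it is validated on device images.

## The synthetic cohort

`generate_cohort()` reproduces the reference study composition by default:
26 control subjects (one eye), 20 BRVO and 14 CRVO subjects (affected +
fellow eye), ages normal per group (60.9 ± 9.6, 63.3 ± 9.2, 67.0 ± 8.1,
truncated to 40–95 years), group-specific female proportions and edema
probabilities. Between-eye correlation is a single interpretable knob: a
per-subject latent severity scalar `u` is shared by both eyes, each eye
sees `e = sqrt(rho) * u + sqrt(1 - rho) * noise`, and metrics shift along
`e`. The default `rho = 0.5` matches the clustering the GEE is asked to
absorb.

Two modes trade realism against cost. *Images mode* grows two plexus
networks per eye (NS-RL is the pixelwise maximum of the rendered SRL and
DRL — an en-face projection stand-in that avoids 3-D modeling), applies the
group's pathology and actually quantifies the rendered images. *Metrics
mode* draws the four parameters directly from the latent-severity model
calibrated to the reference group means and SDs (`metric_calibration()`),
and is the path used for Monte-Carlo studies of the statistics, where
hundreds of cohorts are needed. Fellow eyes are drawn at a configurable
fraction (`fellow_shift`, default 0.1) of the distance from the control
toward the affected-group mean, emulating the sub-clinical fellow-eye
changes reported in occlusion patients without asserting their size. Edema
is modeled only as an optional Gaussian blur plus the edema flag — enough
to exercise the edema-subgroup code path, with no biophysical claim.

## Cohort statistics

**GEE.** `fit_gee()` implements Gaussian generalized estimating equations
with identity link and an exchangeable (or independence) working
correlation, fitted by iteratively reweighted estimating equations to a
1e-8 relative tolerance, with moment estimates of the dispersion and of the
exchangeable α (pairwise residual products with a p-degree-of-freedom
correction, bounded to [0, 0.99] for numerical stability). Inference uses
the robust sandwich covariance; Wald 95% CIs use the normal quantile, which
is standard GEE practice at ≥ 26 clusters. With one observation per cluster
the estimates equal OLS to machine precision, which the tests use as an
oracle.

**QIC.** `qic()` follows the quasi-likelihood-under-independence criterion
with the unit-scale Gaussian convention: −2Q is the residual sum of squares
and the penalty is `2 tr(X'X V_R)` — about twice the parameter count times
the residual variance, i.e. the clustered analogue of Mallows' Cp. The
alternative convention that plugs the model's own dispersion estimate into
Q collapses −2Q to `n − p` for Gaussian models and cannot rank mean models,
so it was rejected.

**Trend tests.** `jonckheere_terpstra()` computes the ordered-alternative
statistic from pairwise Mann–Whitney counts (ties counted half), the
tie-corrected asymptotic variance, and an optional seeded permutation
p-value. Both orderings of interest are reported by `trend_report()`:
occlusion type (control → BRVO → CRVO) and eye status (control → fellow →
affected).

**Reporting.** `compare_groups()` builds `metric ~ group + age + gender`,
clusters on subject, and reports β with robust CI and p. Because the
nonparametric reading of the published analysis is ambiguous, a
rank-transformed regression p (`p_rank`) is reported next to the GEE Wald p
rather than choosing one. No multiple-testing correction is applied
(α = 0.05 throughout), and this is recorded in the report attributes.
Covariates that are constant within a contrast subset are dropped from the
design (they carry no information and would break the fit in small
simulated cohorts). `snellen_to_logmar()` uses log10(denominator /
numerator); counting fingers and hand motion default to logMAR 2.0 and 3.0
— values in that range are conventional, the exact assignments are not
standardized, so they are configurable.

## Problem sizes used by the test suite

The suite checks the statistics at the study's group sizes (26/20/14) over
200 metric-mode cohorts for effect recovery (−0.073 on VD, ρ = 0.5;
mean β̂ within ±10%, CI coverage 0.91–0.99) and trend power (p < 0.001 in
≥ 95% of runs for FD/VD/SD), 2,000 null simulations for the trend test's
size, and one full images-mode cohort at 192 px for the end-to-end severity
ordering; image-level properties use 192–256 px canvases and the fractal
checks a 729² Sierpinski carpet. These sizes were chosen so the whole suite
runs in a few minutes on one core while keeping every Monte-Carlo margin
wide relative to its binomial noise.

## Known limitations

* The binarization default is a reasonable, auditable chain, not a
  re-implementation of any specific published vendor pipeline; absolute
  metric values depend on this choice even though group contrasts are
  robust to it.
* Metrics are reported in pixel units on the full frame; no sub-region
  cropping or artifact masking is performed.
* The latent-severity cohort model is calibrated to *marginal* group means
  and SDs; it does not model the joint distribution of the four metrics
  beyond a shared severity factor.
* The fellow-eye shift and the lesion geometry parameters (wedge extent,
  dropout fractions, dilation factors) are free modeling knobs chosen for
  plausibility, not estimates of any particular patient population.
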