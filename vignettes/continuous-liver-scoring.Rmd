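---
title: "Continuous Kleiner-Brunt scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous Kleiner-Brunt scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hepatoscore` turns a whole-slide liver biopsy image into continuous scores
on the four Kleiner–Brunt scales (ballooning 0–2, lobular inflammation 0–3,
macrovesicular steatosis 0–3, fibrosis 0–4) and the NAFLD activity score
(their partial sum, 0–8). This vignette documents the model, every tunable
parameter that matters, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the problem was genuinely
open.

## The two-stage model

**Stage 1 — local tile classification.** The slide raster (0.44 µm/px) is
cut into adjacent, non-overlapping 299 px tiles; edge remainders are
discarded rather than padded, so tile extents are the half-open intervals
`[x, x+299)` on a 0-based, top-left-origin pixel grid. Ballooning,
inflammation and steatosis are read at this native scale (tile side
131.56 µm ≈ 132 µm); fibrosis is a mesoscopic feature and is read from a
1:3 area-average downscale (1.32 µm/px, side 394.68 µm ≈ 395 µm).
Area averaging was chosen for the downscale because it is the least
aliasing-prone of the standard kernels. Each feature has its own
classifier whose classes follow the grading vocabulary: ballooning
presence (0/1), inflammation focus-density classes (0, 1–2, ≥3 clusters
per tile), steatosis vacuole-area bins of 5% width ([0,5), [5,10), …,
[65,70), [70,100] — the bins above the illustrated range are a convention),
and fibrosis stages 0–4. Every head carries an additional *ignore* class
for glass, fragment edges, pen marks and other non-liver structure.

Tiles whose tissue fraction (share of pixels with HSV saturation above
`sat_threshold = 0.08`) falls below `min_tissue = 0.05` are recorded as
ignore without running the classifier; tiles the classifier itself assigns
to ignore are treated identically downstream. Doing both — skipping early
*and* classifying residual artifacts — covers the two plausible readings of
how background should be handled.

**The backbone.** The only concrete backbone in this package is a small
4-block CNN (3×3 convolution, ReLU, 2×2 max-pool per block; channels
8/16/32/32; global pooling; softmax head), implemented in compiled code
and trained with minibatch Adam (default `lr = 1e-3`, batch 32) on
flip/rotation-augmented tiles — histology has no canonical orientation, so
the dihedral group is the safe augmentation set. Tiles are center-cropped
to the largest multiple of the input side and area-averaged down; the same
deterministic path is used at training and inference. The input side is
64 px for steatosis — an area-fraction cue that survives coarse
downscaling — and 128 px for the structure-sensitive features, where the
defining morphology (a single ballooned cell, a lymphocyte cluster, fine
perisinusoidal collagen) would otherwise vanish. The head pooling also
follows the class semantics: density-like classes use global *average*
pooling, while ballooning — a presence-of-one-object class — uses global
*max* pooling, because averaging dilutes one small cell over the whole
tile (the classic multiple-instance argument). Class imbalance is
handled by per-class weighted sampling of the training order, and the
model returned is the one from the epoch with the best validation
accuracy — the learning curves plateau with late-epoch wobble, and the
plateau model, not the last minibatch, is the model.

Training sets deserve one further remark. The hardest negatives for a
presence class are tiles dense in *other* features — on a severely fatty
slide, a pink tissue island between white droplets with an adjacent
nucleus and a crossing collagen arc is a convincing fake ballooned cell.
`synthetic_training_tiles()` therefore supports hard-negative mining
(`hard_negative_frac`): a share of the lowest-class tiles is rendered
with deliberately severe co-pathology. This mirrors the annotate–train–
review loops used in practice, where annotation effort is focused on the
most challenging cases. Likewise, training tiles draw their nuisance
co-pathology from the cohort distribution (including collagen structures
entering the tile as fragments of larger blocks, and objects cut by tile
borders), because a classifier deployed on whole slides must be trained
on what slides actually contain. A large
Inception-style backbone is *not* implemented: no deep-learning runtime
exists in the supported R stack, so the backbone is built from first
principles at a size a CPU can train, and requesting `inception_v3` fails
with an explanatory error. Consequently "ImageNet" initialization cannot
mean literal ImageNet weights; `pretrained_mode = "imagenet"` and
`"imagenet+domain"` both warm-start from a user-supplied checkpoint
(backbone only, or backbone plus a shape-compatible head respectively),
reproducing the *mechanism* of transfer learning — a warm start on related
tiles should never be worse than a cold start under a tight epoch budget,
and the test suite asserts exactly that ordering.

**Class activation maps.** With global average pooling feeding the softmax
head, the gradient of a class logit with respect to channel *k* of the
final convolutional stage is the head weight `w_kc` (up to the constant
pooling factor), so the gradient-weighted map reduces to
`relu(Σ_k w_kc A_k)`, bilinearly upsampled and min–max normalized; a
spatially constant map is normalized to all zeros by convention.

**Stage 2 — aggregation and scoring.** A feature map with K numeric
classes is reduced to a `2K + 1` vector: average ignore-renormalized class
probabilities over usable tiles, the mean per-tile weighted class
`Σ_c value(c)·p̃_c` (a tile is flagged missing when its ignore mass
exceeds 0.5 — renormalizing smaller ignore mass away keeps tile scores on
the pathologist scale), and one spatial entropy per class. "Entropy per
class" is interpreted as the normalized Shannon entropy of *where* that
class's probability mass sits: `q_t = p_c(t)/Σ_t p_c(t)`,
`H_c = −Σ_t q_t ln q_t / ln T` over the T usable tiles (0 when T = 1 or
the class carries no mass). Low entropy means focal disease, high entropy
diffuse disease — the one reading that yields exactly one number per class
and captures the spatial pattern a pathologist uses. It is isolated behind
`class_entropy()` so an alternative definition can be swapped in.

The scoring network per feature is a two-hidden-layer perceptron (widths
16/8, ReLU) with a scaled-logistic output `s_max·σ(z)` that confines every
prediction to the feature's score range by construction. It is trained
full-batch with Adam (`lr = 0.01`, 400 epochs) on the MSE against the
discrete truth, with slide-level 4-fold cross-validation stratified by the
truth score (round-robin dealing per level, so rare levels reach every
fold). Hidden sizes and optimizer settings are package defaults chosen for
an input dimension of at most 31, not published facts. Slides with fewer
than 5 usable tiles are flagged low-confidence: needle biopsies can be
tiny and aggregation variance explodes.

Ground truth for steatosis may come either from recorded observer scores
or from the classical vacuole-area pipeline mapped through the Kleiner
thresholds; the area route exists because human steatosis scores carry a
known systematic bias, and manifests track which source was used.

## Classical baseline

Collagen area percent is computed by Beer–Lambert optical density
`OD = −log10((I+1)/256)` per channel, least-squares unmixing onto 2–3 unit
stain vectors, thresholding the collagen channel at `od_threshold = 0.15`,
and normalizing by tissue area. Two stain models ship: published
Masson-trichrome triplets (`stain_model_masson()`; stain vectors are
lot-dependent and meant to be overridden per batch) and a model derived
from the synthetic palette (`stain_model_synthetic()`). The group
comparison of per-stage measurements against stage-0 controls uses
two-sample Wilcoxon rank-sum tests with Holm correction — the measurements
are non-normal and the grouping ordinal; the test is configurable.

The Kleiner threshold rules are implemented with closed-below/open-above
boundary semantics (5% → score 1, 33% → 1, 66% → 2; 2 foci → 2, 4 foci
→ 2), since the printed intervals share their endpoints.

## Evaluation conventions

MAE is computed on the *continuous* predictions — the continuous scale is
the method's point — while κ and precision/recall/F1 need categories, so
predictions are discretized by rounding half-up with clipping. Quadratic
κ weights are normalized by S²; the normalization cancels between
numerator and denominator, and the test suite asserts agreement with an
unnormalized brute-force oracle. Support-weighted recall equals overall
accuracy (an identity of support weighting) and is also asserted. NAS
rows use truth = sum of discrete component truths and AI = sum of the
continuous component scores, discretized on 0–8 for the categorical
metrics.

## The synthetic-histology generator

The generator renders Masson-like tissue: a pink-beige base with
multiplicative speckle, scattered hepatocyte nuclei (placed between fat
droplets — a nucleus painted onto a droplet would mimic a ballooned
cell), white elliptical macrovesicular droplets placed greedily until a
target area fraction is met (droplet radii shrink near the target so the
overshoot stays below ~0.3%), dense lymphocyte clusters (18–30 dark
cells within a ~20 µm radius) for inflammatory foci, enlarged pale
hepatocytes with rarefied faintly basophilic cytoplasm, a distinct
membrane and a central nucleus for ballooning, and blue-green collagen
with stage-dependent topology: compact portal-tract masses (stage 0
background), widely spaced parallel perisinusoidal strands along
sinusoid tracks (stage 1 — the ~10 µm inter-sinusoid period is what
keeps the stripes resolvable after the 1:3 downscale instead of
aliasing into a smudge), periportal rims (stage 2), rims plus bridging
streaks connecting two portal anchors (stage 3), and closed rings
enclosing nodules (stage 4).
Collagen is chromatically separate from the cytoplasm so the
color-deconvolution baseline has signal. Everything is rendered at the
0.44 µm/px base resolution; coarser tiles are rendered at integer-factor
size and area-averaged down, so CNN training tiles and slide-derived tiles
are statistically identical by construction. Fibrosis topology is rendered
per 897 px block — one low-resolution tile — so each low tile carries the
slide's stage.

Deliberate calibrations:

* **Stage-1 fibrosis adds < 1% collagen area** on top of a stage-0
  baseline that itself varies between slides (uniform 0.2–1.2%), while
  stage ≥ 2 adds 2% or more. An area-only measurement therefore cannot
  separate stage 1 from stage 0, but the texture is distinctive — exactly
  the mechanism that motivates learned scoring over collagen
  morphometry.
* **A 200× field is modeled as a 660 µm square**; the field area is not
  standardized anywhere authoritative, so this is a recorded, configurable
  convention. Focus and ballooned-cell counts are realized
  *deterministically* from the generative density (count = ⌈density ×
  area⌉ for nonzero density) rather than Poisson-sampled: like fixing one
  fibrosis topology class per slide, this keeps slide-level ground truth
  an exact function of the generative parameters, which is what
  parameter-recovery tests need. Poisson dispersion would only add label
  noise that real cohorts express through observer variability, which is
  modeled separately.
* **Ballooning "few" vs "many"** is quantified as 1–3 vs > 3 ballooned
  cells per mm² — the verbal scale has no numbers, so the generator fixes
  a monotone convention.
* **Observer noise** perturbs recorded scores by ±1 with probability
  `2·Φ(−0.5/σ)` (a normal reading error that rounds to a neighboring
  score), clipped to range.
* Cohort slides default to 1794 × 1794 px (0.79 mm², a 6×6 high-resolution
  grid and a 2×2 low-resolution grid) — large enough that focus and
  ballooned-cell counts distinguish adjacent grades, small enough to
  render and score in about two seconds each.

What the generator does **not** emulate: nuclei-level biological fidelity,
stain variability across laboratories and scanners, H&E appearance,
microsteatosis, sub-stages of early fibrosis, and the long-tailed artifact
zoo of clinical archives. Tests passing on synthetic cohorts therefore
demonstrate that the pipeline's machinery — tiling, classification,
aggregation, bounded regression, evaluation — recovers known generative
structure; they do not certify accuracy on clinical material, which is
bounded by training-data variety rather than by the algorithm.

## Numerical choices and degenerate inputs

* TIFF resolution metadata is written in pixels per centimeter as a
  rational with denominator 1000; `load_slide()` recovers µm/px to better
  than 1e-6 and refuses files with neither metadata nor an override.
* The 95/5 tile split allocates the validation quota across classes by
  largest remainder, so the overall fraction is exact; classes with fewer
  than two tiles stay whole in training, with a warning.
* Quadratic-weighted κ with both raters constant and equal (zero expected
  disagreement) is defined as 1; per-level zero divisions in
  precision/recall resolve to 0.
* Bounded-activation training targets of exactly 0 or `s_max` are
  approached asymptotically; 400 Adam epochs bring a constant-0 target
  below MSE 0.01.
* All stochastic stages (generation, splits, sampling order, weight
  initialization, fold assignment) consume seeds derived from a single
  user seed via a fixed 32-bit linear map, so every artifact is
  reproducible from (config, seed, inputs); compiled code contains no
  randomness.

## Problem sizes used by the test suite

The parameter-recovery and group-separation suites train all four tile
classifiers (60–200 synthetic tiles per class plus extra coverage of the
subtle fibrosis 0/1 boundary; 14–28 epochs each) and score a noiseless
120-slide cohort with uniform score mixes (24 slides per fibrosis stage,
of which the first 20 per stage form the comparison groups). These sizes
were chosen so the whole suite, including training, runs in about twenty
minutes on a single CPU while leaving the recovery targets (steatosis
MAE ≤ 0.3 out-of-fold, Spearman ρ > 0.9 between AI scores and generative
burden) attainable by a correct implementation and clearly failed by a
broken one.

## Known limitations

* The small backbone saturates well below the discrimination ceiling of a
  modern large CNN; its role is to make the pipeline's claims testable,
  not to set accuracy records.
* Slide rasters are loaded whole; pyramid-aware streaming of multi-GB
  clinical WSIs is out of scope (vendor formats must be converted to
  TIFF/BigTIFF at known µm/px upstream).
* The spatial-entropy aggregation discards all geometry beyond the
  per-class mass distribution; periportal versus centrilobular *location*
  is only visible to the fibrosis classifier, not to the aggregator.
* Continuous scores inherit the ambiguities of the underlying scale —
  transitions between some fibrosis stages are not conceptually
  continuous, and values near bin boundaries should be read with that in
  mind.
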