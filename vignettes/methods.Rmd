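---
title: "Models and methods behind httscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind httscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(httscreen)
```

`httscreen` analyses two-channel fluorescence images of *Drosophila*
primary neuronal cultures expressing RFP-tagged Huntingtin: a morphology
channel (membrane GFP in all neurons) and a reporter channel (Htt-RFP,
which aggregates into bright puncta when the polyglutamine tract is
expanded). This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic data generator does and does not
emulate.

## The measurement model

### Aggregation

Aggregates are far brighter than soluble reporter, so the per-image
aggregation measure is simply the number of reporter pixels with intensity
*strictly above* a threshold. The threshold is not a free constant: it is
calibrated per screen as the `q = 0.999` quantile of pooled reporter pixels
from vehicle Htt15Q wells, which are biologically aggregate-free. By
construction this yields near-zero counts on the calibration controls
(about 0.1% of pixels per field exceed their own 0.999 quantile) and large
counts wherever puncta exist. Calibration is global per screen by default;
per-plate calibration is a matter of passing per-plate reference images.

### Morphology segmentation

The morphology pipeline is deliberately classical and parameter-light:

1. **Background subtraction.** A median-filter background estimate
   (window 95 px) is subtracted. The window must comfortably exceed the
   largest neuromere diameter (~50 px at the default conditions), otherwise
   the filter flattens the objects being measured; 95 px satisfies this
   with margin. For speed the median runs on a 4x down-sampled copy with a
   proportionally scaled window and is resized back — the background varies
   over much larger scales, so this is lossless in practice.
2. **Binarisation.** Otsu's threshold computed over the image's own
   intensity range (256 bins), which makes segmentation exactly invariant
   to uniform intensity rescaling. A fixed threshold is available.
3. **Soma/neurite separation.** Morphological opening with a disc of
   radius 4 px removes thin structures; opened components of at least
   50 px are neuromeres. Neuromere areas are reported in µm²
   (pixel count x `pixel_size_um`²; default calibration 897/1392 µm/px from
   the acquisition geometry, 1392x1040 px = 897x670 µm).
4. **Neurite skeleton.** The neurite mask (binary mask minus the
   neuromeres dilated by 2 px) is thinned to a 1-px skeleton (Zhang–Suen),
   split at junction pixels, and each piece measured as a path length with
   orthogonal steps counting 1 px and pure diagonal steps √2 px, plus 1 px
   for pixel extent. Segments shorter than 5 px are discarded as noise.

Two numerical choices deserve a note. *Junctions* are defined by crossing
number (at least three distinct skeleton arms meeting at the pixel), not by
a raw neighbour count: on diagonal staircases a raw count misclassifies
interior path pixels as junctions and shatters segments into sub-threshold
fragments. And *small-object bias*: a neuromere whose radius is near the
opening radius loses a boundary ring to the opening, so areas at the
detection limit are underestimated by a few percent and objects below
~64 px are not detected at all. This is a fixed detection limit, not a bug;
under the mutant condition (deliberately small neuromeres) a few percent of
planted objects fall below it.

### The eight-feature profile

Log2-transformed neuromere areas are well described by a three-component
normal mixture (small/medium/large); neurite segment lengths are grouped
short/medium/long by K-means. Per field, bin counts are converted to
percentages of that field's own totals — this controls for well-to-well
cell-number variation from pipetting — and object-level means complete the
profile: three neuromere percentages, mean neuromere area, three neurite
percentages, mean neurite length.

The binning models are fitted once per screen on objects pooled from all
vehicle wells of both genotypes and then frozen for treated wells, so bin
boundaries are comparable across treatments. The mixture is fitted by EM
with deterministic initialisation (means at the 1/6, 3/6, 5/6 sample
quantiles, equal weights, common sd; tolerance 1e-8 on the log-likelihood,
500 iterations, sd floor 1e-3), so the fit depends only on the data —
permuting input order changes nothing, and the `seed` argument exists only
for interface symmetry. Components are reported sorted by mean, and bin
assignment is maximum posterior with ties to the smaller bin. K-means uses
Lloyd's algorithm initialised at the 10th/50th/90th percentiles, again
deterministic; assignment is nearest-centre with midpoint ties to the
shorter group. Fewer than three distinct values is a degenerate-input
error. Fields without neuromeres cannot be profiled and are excluded
upstream as lacking cell profiles; fields without neurites contribute
zero-valued neurite features and a `zero_neurites` flag rather than being
dropped, because dropping them would bias the profile toward healthy
fields. "Mean neuromere area" averages over objects, not over bins.

## The statistical model

All tests operate on per-field values (the field image is the sampling
unit; well-level averaging is a trivial aggregation of the feature table).

- **Welch t-test, two-sided.** Used for every comparison; the
  unequal-variance form is a robust default. Identical samples give
  t = 0, p = 1 — this is what makes the vehicle self-comparisons exact
  identities (aggregation p = 1, morphology combined p = 1, log2 ratio 0).
  Two zero-variance samples with different means return the p-value floor
  rather than an error.
- **Fisher combination.** X = −2 Σ ln pᵢ referred to χ² with 2k degrees of
  freedom (k = 8 features). Inputs below the floor `p_floor = 1e-300` are
  clipped first for log-safety. Stored p-values keep full precision;
  display formats values below 1e-15 as 0.
- **Aggregation suppression.** log2(mean treated / mean in-plate DMSO
  Htt138Q counts), Welch p, and the direction of the mean difference. The
  screen-wide hit line sits at m = 2 sample standard deviations below the
  mean log2 ratio of the screen.
- **Two-stage hit calling.** Stage 1 requires p < α (default 0.05) *and* a
  negative direction *and* ratio ≤ cutoff under the default `"and"` rule.
  The two stage-1 criteria (p-value and 2-SD line) are used jointly in the
  screen but their exact conjunction is a design choice, so `"or"` and
  `"p"` (the footnote convention of tabulated per-compound results) are
  available. Stage 2 re-evaluates only suppressed treatments: combined
  p > α is a full reversion (`DUAL_HIT`); combined p in
  `[rescue_floor = 1e-6, α]` is a partial reversion, flagged but classified
  `AGG_SUPPRESSOR_ONLY` (published validated-hit lists contain both
  regimes, with partial-reversion p-values as low as 1e-6, which is why the
  band is closed at the floor); a suppressed treatment whose profile
  diverges from control even more than the untreated-mutant baseline, with
  worse feature means, is `EXACERBATING`. No multiple-testing correction
  across treatments is applied in the decision rule; a Benjamini–Hochberg
  column is emitted as clearly-extra output.
- **Exclusion rules.** Fields are excluded when out of focus (variance of
  the Laplacian of the min–max-normalised image below a threshold, default
  0.25x the median focus score of the vehicle wells — the screen's notion
  of "out of focus" is operational, and this is a standard surrogate) or
  when no neuromere is found. Treatments with fewer than 6 usable images,
  pooled over duplicate wells (3 sites x 2 wells), are excluded with
  recorded reasons; whether the rule pools duplicates is configurable
  because either reading is defensible.

## The synthetic-culture generator

The generator exists so that every stage has a ground-truth oracle. Per
field it plants: Poisson-many neuromeres as non-overlapping filled discs
with log2 areas from the three-component mixture; per blob, Poisson-many
neurites as 2-px-wide persistent random walks (heading jitter sd 0.12
rad/step) with gamma lengths, forking with a per-step branch probability;
reporter puncta as discs at random neuronal positions with intensities in
a band around 24000 counts — several-fold above any soluble level, so a
separating threshold exists by construction — over diffuse soluble
reporter; then a Gaussian PSF blur (sd 1 px) and Gaussian read noise
(sd 150 counts) on a 400-count background with a 12000-count neuronal
signal, 16-bit range.

The two genotype parameter sets encode the phenotype contrast: the control
has no aggregates, bright soluble reporter (0.5x signal), long neurites
(gamma shape 5, scale 14 µm; mean 70 µm), rare branching (0.01/step) and
area-mixture means 6.0/7.5/9.0 log2 µm²; the mutant has ~30 puncta per
field, dim soluble reporter (0.12x), short neurites (scale 6; mean 30 µm),
more branching (0.04/step) and a down-shifted, small-heavy mixture
(means 5.0/6.5/8.0, weights 0.55/0.33/0.12). These effect sizes are not
published quantities — the source model reports the phenotype only
qualitatively — so they are free parameters chosen once to produce clear
but not caricatured separation, and are exposed in `culture_params()`.
`rescue` in [0, 1] interpolates every phenotype parameter linearly from
mutant to control, so `rescue = 1` reproduces the control exactly. Screen
generation applies planted effects (`AGG_SUPPRESSOR` scales only the
aggregate rate; `DUAL_RESCUER` adds rescue of the morphology parameters;
`TOXIC` pushes areas and lengths below mutant levels), and every well/site
draws from an independent RNG substream derived by a stable hash of
(seed, plate, well, site), so outputs do not depend on generation order.

Ground truth records what was actually planted *and visible*: neurite
length counts only walk steps rendered outside soma blobs (a neurite
passing through a blob is occluded there), split at forks and occlusions.
With noise and PSF disabled this truth is an exact oracle: detected
neuromere counts equal planted counts (control condition, all objects above
the detection limit) and total measured neurite length agrees with planted
length to within ~7%, the residual coming from dilation margins at neurite
roots, junction pixels, sub-threshold fragments, and the digital-line
length metric.

What the generator does **not** emulate: realistic optics (a Gaussian PSF
is not a microscope PSF), glia and debris, uneven illumination, focus
drift, saturation, well-edge effects, or spatially correlated noise.
Passing tests therefore demonstrate the pipeline's correctness and
calibration on data matching its assumptions — not robustness to every
artefact of real screens.

## Problem sizes and runtime

Synthetic fields default to 256x256 px (the full 1392x1040 geometry is one
`culture_params()` override away); a 96-well screen at 3 sites per well
(8 vehicle wells per genotype, 40 treatments in duplicate) generates and
analyses in about half a minute. The test suite's calibration study runs 20
such null screens (~800 null treatments) and checks that the stage-1 hit
fraction stays below α and the 2-SD flag rate sits in the binomial
confidence band of the normal-tail expectation (~2.3%); the planted-effect
study uses 10 dual rescuers (rescue 1, aggregate factor 0.2) in one screen;
the dose-monotonicity study spans rescue ∈ {0, 0.25, 0.5, 0.75, 1} over 5
replicates. These sizes were chosen as the smallest at which the binomial
and rank statistics are meaningful.

## Known limitations

- Area and count accuracy degrade for neuromeres near the 50-px minimum /
  4-px opening radius (see above); shrink `soma_opening_radius_px` and
  `min_neuromere_area_px` together for cultures with genuinely small somata.
- Fisher's method assumes independent per-feature p-values; the eight
  features are correlated (percentages sum to 100), so combined p-values
  are calibrated for ranking and thresholding rather than as exact tail
  probabilities. The self-comparison identity (combined p = 1) is exact
  regardless.
- With a large planted-effect fraction (e.g. a quarter of wells active) the
  empirical 2-SD line migrates toward the actives; the `"p"` stage-1 rule
  is then the appropriate gate, as in validated-hit tables.
- One plate per run: multi-plate screens are analysed plate-by-plate (the
  log2 ratio is defined against the in-plate DMSO wells by design).
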