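# httscreen

High-content screening analysis for Huntingtin (Htt) aggregation and
neurite morphology in *Drosophila* primary neuronal cultures.

## The problem

Primary neurons expressing pathogenic polyglutamine-expanded Huntingtin
(Htt138Q) form bright cytoplasmic aggregates of the RFP-tagged reporter and
develop dysmorphic neurites — smaller cell-body clusters (*neuromeres*),
shorter processes, more branching — compared to non-pathogenic Htt15Q
controls. A compound or RNAi screen against this model therefore needs two
readouts per well: how much reporter aggregation there is, and whether the
culture's morphology looks like the healthy control. `httscreen` implements
that analysis as a reusable, tested pipeline for two-channel fluorescence
images (membrane-GFP morphology + Htt-RFP reporter) of multiwell plates,
and ships a synthetic-culture image generator with ground truth so the
whole pipeline is testable without microscope data.

## The method

Per field (one imaged site of one well):

- **Aggregation** — the number of reporter-channel pixels with intensity
  strictly above a threshold calibrated as a high quantile (default 0.999)
  of pooled vehicle-Htt15Q reporter pixels, which carry no aggregates.
- **Morphology** — neuromeres and neurites are segmented from the
  background-subtracted, thresholded morphology channel (morphological
  opening separates somata from thin processes; the neurite mask is
  skeletonised and split at junctions into segments). The log2 neuromere
  areas are binned small/medium/large by a three-component Gaussian
  mixture fitted by EM; segment lengths are grouped short/medium/long by
  K-means. Bin counts become percentages of the field's own totals
  (controlling for cell-number variation), giving the eight-feature
  profile: `pct_small/medium/large_neuromere`, `mean_neuromere_area`,
  `pct_short/medium/long_neurite`, `mean_neurite_length`.

Per treatment (pooled over replicate wells, vs in-plate vehicle controls):

- **Stage 1, aggregation suppression** — the log2 ratio of mean aggregate
  pixels (treated / DMSO-Htt138Q), a two-sided Welch t-test over per-field
  counts, and a screen-wide cutoff at 2 standard deviations below the mean
  log2 ratio. Treatments with p < α, a negative direction and a ratio at or
  below the cutoff suppress aggregation.
- **Stage 2, morphology reversion** — only suppressed treatments are
  re-evaluated: one Welch test per feature against the Htt15Q vehicle
  profile, combined by Fisher's method,

  X = −2 Σᵢ ln pᵢ,  X ~ χ²(2k) under the joint null (k = 8),

  so a **high** combined p means the treated morphology is statistically
  indistinguishable from the healthy control: a dual hit.

Wells with fewer than 6 usable images (out-of-focus or lacking cell
profiles) are excluded with recorded reasons.

## Worked example

```r
library(httscreen)

# a 96-well synthetic screen: 8 vehicle wells per genotype, 40 treatments
# in duplicate on the Htt138Q background, 3 fields imaged per well;
# 10 treatments are planted dual rescuers
planted <- sprintf("cmpd%03d", 1:10)
effects <- setNames(
  lapply(planted, \(id) list(label = "DUAL_RESCUER", rescue = 1, factor = 0.2)),
  planted)
scr <- generate_screen(effects = effects, seed = 1)
res <- run_screen(scr, stage1_rule = "p")
screen_report(res$hits, n_top = 3)
```

```
Screen cutoff (mean - 2 sd of log2 ratios): -1.5317
Classification counts:
  INACTIVE             28
  AGG_SUPPRESSOR_ONLY  4
  DUAL_HIT             8
  EXACERBATING         0
  EXCLUDED             0
Top suppressed treatments (up to 3):
  cmpd003      log2 ratio   -1.692  agg p 3.16862e-07 morph p 0.769137   DUAL_HIT
  cmpd008      log2 ratio   -1.568  agg p 2.01749e-07 morph p 0.021485   AGG_SUPPRESSOR_ONLY
  cmpd001      log2 ratio   -1.394  agg p 7.85415e-05 morph p 0.0634675  DUAL_HIT
```

All ten planted rescuers suppress aggregation (their counts drop to ~20%
of the in-plate DMSO mean, Welch p ≪ 0.05) and eight of them are called
`DUAL_HIT`: their eight-feature profiles are statistically similar to the
Htt15Q control (Fisher-combined p > 0.05). The other two planted rescuers
land just below the 0.05 line (e.g. cmpd008, morph p = 0.021) and are
reported as partial reversions (`partial_rescue` flag) — the expected
behaviour of a Fisher combination over eight correlated features at this
sample size, and the same pattern the published validated-hit tables show.
`autoplot(res$hits)` draws the log2-ratio scatter with the cutoff line;
`tidy(res$models$areas)` exposes the fitted area bins.

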