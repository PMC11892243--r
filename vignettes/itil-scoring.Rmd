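---
title: "Automated iTIL scoring: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated iTIL scoring: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itilscore)
```

## The problem and the score

Tumour-infiltrating lymphocytes (TILs) visible on routine H&E sections are
prognostic in colorectal cancer: patients with dense intraepithelial TIL
(iTIL) infiltrates relapse less and survive longer. Manual scoring counts
TILs in a handful of circular high-power fields (HPFs, diameter 0.55 mm)
and is slow and rater-dependent. This package implements a fully automated
alternative that works at pixel granularity in three stages, each behind a
pluggable backend contract:

1. **Broad cancer segmentation** at 4 microns per pixel (MPP, roughly 2.5×
   magnification): separates broadly cancerous tissue from normal tissue
   and background.
2. **Tumour/stroma/necrosis (TSN) segmentation** at 0.5 MPP (20×), applied
   only inside broadly cancerous tissue.
3. **TIL detection** at 0.25 MPP (40×): a heatmap regression model decoded
   into confidence-scored point detections.

Detections are assigned to a compartment by looking up their coordinate in
the TSN mask; tumour-compartment points are the iTILs. Scoring then lays
non-overlapping square fields with the same area as a 0.55 mm circular HPF
(side $1000 \cdot (d/2)\sqrt{\pi} \approx 487.4$ µm) over the tumour
bounding box. A field is eligible if at least 10% of its area is segmented
tumour. For eligible field $i$ with iTIL count $L_i$ and tumour area $T_i$
(mm²), the patient's **AI iTIL score** is

$$\mathrm{median}_{i=1}^{F} \; L_i / T_i$$

pooled over all eligible fields of all the patient's slides. Patients are
called **TIL-High** when the score reaches 17 iTILs per mm² tumour, else
**TIL-Low**; TIL-High is the good-prognosis group. The 17 per-mm² cut-off
is consistent with the manual criterion of 2 TILs per HPF: at a typical
40–60% tumour content per field, 2 TILs/HPF corresponds to 14–21 per mm²
tumour, with 17 at 50% (`hpf_equivalent_density()`).

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| stage resolutions | 4 / 0.5 / 0.25 | MPP | context vs detail trade-off per stage |
| tile size | 512 | px | network input size; edge tiles are clipped, not padded |
| detection tile overlap | 64 | px | a ~8 µm TIL near a seam is fully visible in at least one tile |
| heatmap σ | 2.0 | µm | ~quarter of the 8 µm TIL nucleus diameter; configurable |
| confidence gate | 0.35 | – | F1-optimal gate for the detector; `confidence_sweep()` reproduces the selection procedure |
| min separation / NMS radius | 4 | µm | half the average TIL diameter; also the evaluation match radius |
| HPF diameter | 0.55 | mm | the manual protocol's field |
| field eligibility | 10% | tumour fraction | excludes fields with too little tumour to normalise reliably |
| cut-off | 17 | iTILs/mm² | risk dichotomisation threshold |
| Macenko β, angle percentile, scale percentile | 0.15 / 1 / 99 | OD, % | standard Macenko settings; exposed in config |

Flagging defaults (all configurable via `flag_criteria()`): tumour area
< 1 mm², fewer than 5 eligible fields (mirroring the 5-HPF manual
practice), cancerous fraction of detected tissue < 5%, or any stain
normalisation failure. Flagged slides still receive scores; the flag
recommends review.

## Numerical and design choices

* **Coordinate frame.** 0-based pixel indices, origin top-left, half-open
  pixel intervals; a pixel's micron position is its top-left corner. All
  three resolutions share one micron frame, so cross-resolution lookups
  (TSN at 0.5 MPP queried from 0.25 MPP detections, broad mask at 4 MPP
  queried from either) are plain nearest-neighbour index maps.
* **Reconstruction seams.** Segmentation inference uses zero overlap, so
  reconstruction is exact. If tiles do overlap, later tiles in row-major
  order win; the policy only matters for the optional overlapped paths.
* **Heatmap codec.** Point-to-heatmap encoding combines Gaussians by
  pixel-wise maximum rather than sum, so the peak value doubles as the
  detection confidence and stays in [0, 1] — which is what the 0.35 gate
  thresholds. Decoding extracts local maxima within the minimum-separation
  window and then applies greedy point NMS; ties are broken by (y, x)
  order for reproducibility. Peak positions are reported at pixel centres:
  at 0.25 µm quantisation, sub-pixel refinement is pointless against the
  4 µm evaluation radius.
* **Stain normalisation** follows Macenko: stain vectors from the angular
  extremes (1st/99th percentile) of the OD cloud projected on its top two
  principal directions, concentrations rescaled at the 99th percentile to
  reference maxima. A white or single-stain tile raises a classed
  condition (`itil_stain_failure`) which the pipeline counts and converts
  into a flag criterion. Whether normalisation is fit per tile or per
  slide is an open choice; the default is per tile against a fixed
  literature reference, which keeps tiles independent.
* **Field grid anchoring.** The grid is anchored at the tumour bounding
  box's top-left corner and the field side is snapped to a whole pixel
  count at the scoring resolution (975 px at 0.5 MPP; area error < 0.2%),
  which makes per-field tumour areas exact pixel sums. A fixed anchor is
  deterministic; the choice of anchor is not prescribed by the method.
* **Median convention.** Even field counts average the two central order
  statistics. The boundary convention is score ≥ cut-off → TIL-High; the
  method itself does not dictate what happens at exactly 17.0, so the
  convention is documented and configurable.
* **Necrosis and unassigned points** are recorded but excluded from both
  $L_i$ and $T_i$; stromal points are retained in outputs for future
  stromal metrics but never scored.
* **Cut-off search.** "Most significant stratification" is operationalised
  as the minimal log-rank p-value over the cut-off grid (default integers
  1–100 per mm²), with ties broken by larger absolute log hazard ratio and
  then by the smaller cut-off. The five-group split is seeded and
  stratified by event status; the split is keyed to patient identifiers so
  row order cannot change the result. When the five repeats disagree, the
  modal optimum is reported and marked non-unanimous.
* **Proportional hazards** fits use the survival package's default Efron
  tie handling.

## What the synthetic generator emulates — and what it does not

`generate_layout()` builds slides as unions of smooth random blobs of
cancerous tissue inside a normal-tissue rim on a white background, with the
TSN partition cut from a smooth random field at within-cancer quantiles so
realised fractions track the requested ones (default 60/35/5%).
`plant_tils()` plants per-compartment homogeneous Poisson point processes
thinned to a 6 µm hard core, so planted densities are known and the codec's
separation assumptions hold by construction. `slide_source()` renders any
requested window at any stage resolution from a fixed palette with a small
deterministic per-pixel jitter (a hash of global pixel coordinates, so
overlapping tiles agree bit-exactly); TIL markers are painted as 3 µm disks
at the detection resolution only, so segmentation-resolution colours remain
unambiguous. The toy backends are the palette's inverse: colour-rule
classifiers and a disk matched filter. `generate_cohort()` draws log-normal
scores (median at the cut-off) and exponential survival with a hazard step
of ratio 2 at the planted cut-off plus independent uniform censoring,
giving roughly 60–70% events within follow-up.

Passing tests on these fixtures demonstrates that the *plumbing* —
geometry, codec, restriction rules, scoring arithmetic, survival machinery
— is correct, and that the pipeline recovers planted densities and risk
structure when its inputs behave. It does **not** demonstrate segmentation
or detection accuracy on real H&E appearance: nuclei texture, staining
variability, mucin, tangential sectioning and scanner differences are all
outside what the palette renderer emulates. Real deployments plug trained
networks into the same backend contracts.

## A statistical property of the median score worth knowing

Per-field iTIL counts are integers, so at low densities the per-field
expected count $\lambda T_i$ is small (at $\lambda = 5$ per mm² and a full
field, about 1.2) and the median of $L_i/T_i$ sits systematically below
$\lambda$ — the median of a Poisson with mean near 1 is 0 or 1. In our
end-to-end recovery runs the deviation is about −8% at $\lambda = 5$,
within ±5% at $\lambda = 17$, and smaller still at $\lambda = 60$. This is a property of
the score itself (median of integer counts over finite fields), not of the
implementation; around the clinically relevant cut-off (expected counts
≈ 4 per field) it is modest.

## Problem sizes used by the test-suite

The deterministic suites use desk-scale fixtures (rasters up to ~2000 px,
hundreds of points, 100–1000 randomised instances per oracle comparison).
The end-to-end recovery runs score three synthetic 4.4 × 4.4 mm slides
(≈ 60 eligible fields each) through all three stages at full working
resolution; the survival recovery suites use 50 cohorts of n = 1000 for
the hazard-ratio check and 20 cohorts of n = 400 for the cut-off search.
These sizes were chosen so every recovery claim is measured on at least
the field/patient counts the corresponding analysis assumes.

## Known limitations

* No WSI container decoding (SVS/NDPI): inputs are plain rasters or a
  `slide_source`-style lazy renderer with declared MPP.
* No stromal-TIL or combined metric; stromal points are carried through
  but unscored. No mucin class.
* The toy TIL backend detects colour-coded disks, not nuclei; detection
  metrics on real slides are a property of the plugged-in model.
* Field eligibility is assessed against the full field area, including for
  edge fields extending past the tumour bounding box.
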