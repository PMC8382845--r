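---
title: "Methods: segmentation, quantification and screen statistics in tauHCS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, quantification and screen statistics in tauHCS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, parameter choices and design decisions
behind `tauHCS`, in the spirit of a methods section: what each stage
assumes, which knobs matter, and what the synthetic validation does and
does not demonstrate.

## The measurement model

Each field carries four co-registered intensity grids: DNA stain
(nuclei), beta-III-tubulin (neuronal morphology), total tau, and
phospho-tau. All quantities are computed per compartment:

* the **neurite field** — every neurite pixel on the field, pooled; and
* **cell bodies** — soma pixels, pooled per field.

A compartment *mean* is always total intensity over total compartment
area, not an average of per-cell averages. The phospho/total ratio is the
ratio of the two compartment means. This pooled-pixel construction is the
natural reading of a total-over-total-area measure; a per-cell export
would weight small cells up and is deliberately not the default. Fields
whose quantification region is empty carry undefined (NA) means and are
excluded from aggregation rather than imputed as zero.

## The synthetic field generator

The simulator is the package's ground-truth instrument, not a fixture: it
renders live neuronal nuclei (discs, radius 8–11 px) with somata
(12–16 px) and branching neurite trees, non-neuronal nuclei (DNA only),
dead nuclei, and clumps, then composes per-channel clean images from a
channel × compartment intensity table (a pixel under several compartments
takes the maximum), applies treatment effects, and finally noise.

Decisions that matter:

* **Exact truth.** Neurites are integer-width pixel strokes with
  anti-aliasing off, so true areas are exact pixel counts and mask
  recovery can be scored by IoU without sub-pixel ambiguity. Trees start
  just inside the soma boundary and terminate at the field border, so
  every tree is 8-connected to its soma before noise.
* **Major vs minor neurites.** A configurable fraction of trees (default
  0.25) is *minor*: 1 px wide at roughly half the major intensity,
  emulating the dim thin processes that are hardest to separate from
  background.
* **Dead nuclei** are strictly smaller (4–5.5 px radius vs 8–11), three
  times brighter in DNA, and rendered as alternating-spike star polygons
  (12 vertices, ±50% radial modulation) whose solidity stays below ~0.82;
  the three defining properties (small, bright, rugged) are therefore all
  true by construction and recoverable.
* **Clumps** are groups of 3–5 nuclei placed within ~1.3 nucleus radii of
  a cluster center, with 1.5× brighter DNA (stacked cells in projection)
  and an elevated local background halo. The halo disc is the true clump
  region.
* **Noise** is Poisson shot noise on the clean signal followed by
  additive Gaussian read noise (sd 10), both toggleable — the standard
  fluorescence detection model.
* **Effects** are multiplicative: `p_tau_scale_neurite` and
  `p_tau_scale_soma` scale the phospho-tau channel of those compartments;
  `neurite_area_scale` scales total tree path length. DMSO wells use
  multipliers of 1.
* **Seeding.** A plate derives one substream seed per (well, field) from
  the master seed by a fixed integer hash, so plates of any size are
  reproducible field by field and bit-identical across runs.

What the simulator does *not* emulate: optics (no PSF beyond optional
blur), uneven illumination, focus drift, staining gradients, or the
continuous intensity variation of real neurites. Passing recovery tests
on synthetic fields therefore demonstrates the pipeline's logic and its
noise robustness, not instrument-grade performance on real plates.

## Segmentation

**Nuclei.** Edge detection (Sobel gradient magnitude on a lightly
smoothed DNA grid) outperforms global intensity thresholding in dense
cultures, so candidate nuclei are closed edge contours, filled and
labelled with 8-connectivity. The edge cutoff is a fraction (0.2) of the
99.9th gradient percentile; a field whose top gradients do not stand at
least 8 robust SDs above the gradient noise is treated as empty, which
keeps blank and pure-noise fields from producing objects. Each object is
then refined to the half-maximum support of its own intensity profile
(on a lightly smoothed grid, so rugged outlines survive), and area, mean
DNA intensity and solidity (area over rasterized convex hull area) are
measured there. Classification is object-level, not threshold-level: an
object is a dead nucleus only if it is simultaneously small
(≤ 100 px²), bright (≥ 1.5× the median DNA mean of size-qualified
candidates) and rugged (solidity ≤ 0.85). The numeric cutoffs are
calibrated on the simulator and exposed in the configuration; the
direction of each criterion is what the assay defines.

**Cell bodies** grow from each live nucleus into pixels where tubulin
*and* total tau both exceed 3× their channel medians. The candidate map
is opened at a scale wider than a neurite (disc of 2×major width + 1)
first — without this, body growth leaks along bright neurite strokes and
steals neurite area. Contested pixels go to the nearest nucleus
(`EBImage::propagate`); growth is capped at 20 px from the nucleus.
Objects outside 200–4000 px² or with less than 60% dual-channel coverage
emit no soma and their nucleus is re-classed non-neuronal — a nucleus
with no contiguous cytoskeletal signal is not a neuron.

**Neurites.** The ridge response is a white top-hat (disc radius
`major_width + 2`) on the per-pixel maximum of tubulin, total tau and
phospho-tau — all three stains outline processes, and the maximum keeps a
process visible when any one stain is dim. No pre-smoothing is applied:
the strokes' widths are preserved exactly and the robust cutoff absorbs
pixel noise. Extraction runs 10 passes with a geometric cutoff schedule
relaxing from 1.0 to 0.4 of the base cutoff (20 robust noise SDs of the
response). Each pass may only add pixels 8-connected to the accumulated
mask or to a soma, so early passes lock in bright thick majors and later
passes extend dim thin minors along them; the mask grows monotonically
with pass number by construction. Detached segments (not touching a
soma) then face the minor-segment test: mean intensity at least 1.2× the
local background annulus *and* skeleton length ≥ 15 px, which removes
antibody-background speckle without a separate background map. Gap
closing is directional, never distance-only: skeleton endpoints within
8 px are bridged only when both local tangents agree within 0.35 rad and
point toward each other, and bridging is idempotent.

**Clumps** are contiguous high-DNA regions (≥ 0.3× the median
live-nucleus DNA mean) that either contain ≥ 3 detected nucleus
centroids or exceed 1.3× the top of the live-nucleus area range while
containing at least one — tightly fused nuclei are detected as a single
object, which is why the area alternative exists. Clump regions are
dilated by 8 px and excluded from both quantification masks; nuclei whose
centroid falls inside are re-classed `clumped_excluded`.

**Final masks.** Image-math subtraction: the neurite quantification mask
is the total neurite mask minus cell bodies minus clumps; cell-body
quantification is restricted to soma areas not crossed by neurites, minus
clumps. The two quantification regions are disjoint by construction and
this invariant is asserted in the test suite. Where the neurite path over
a soma is ambiguous, the plain intersection of the neurite mask with the
soma is subtracted.

Throughout, stringency is tuned toward false-positive reduction: a
pure-noise field at default parameters segments less than 0.1% of pixels
as neurite. All intensity cutoffs are relative to robust per-field
statistics, so a global gain change leaves the segmentation essentially
unchanged; the only intended run-to-run knobs are the three global
cutoff multipliers (`nucleus`, `soma`, `neurite`).

## Screen statistics

* **Responsiveness (rule a).** A plate is analysed only if the ratio of
  raw DMSO to positive-control mean phospho-tau neurite intensity is at
  least 1.3.
* **Field exclusion (rules b, c).** Within each well, fields with a
  neurite area below the lower 95% confidence bound of that well's
  fields are excluded; likewise fields below the bound of all pooled
  DMSO fields. Two readings of "lower 95% CI" are implemented. The
  default is the empirical lower-tail percentile of the field values,
  which excludes only the outlying low-area images (~2.5% of a clean
  group). The t-based bound of the *mean* (`mean − t·SD/√n`,
  `ci_method = "mean"`) is also available, but it sits just below the
  group mean — with n pooled DMSO fields it converges *to* the mean —
  and therefore removes roughly a third of perfectly ordinary fields
  and can void entire wells, which is incompatible with a workflow that
  reports per-compound area effects and field-level SEMs; hence it is
  not the default. Both rules are evaluated on the original field set
  and the union of exclusions is taken, so their order is immaterial.
* **Toxicity before exclusion.** The neurite-area fold change — the
  cell-health readout — is computed on all non-degenerate fields,
  *before* rules b and c. This is deliberate: a strongly neurotoxic
  compound produces exactly the low-area fields those rules remove, so a
  post-exclusion area fold change could never fire the > 20%-decrease
  flag, yet the waterfall reports an area effect for every compound.
  Intensity fold changes use fully QC-passed fields.
* **Normalization.** Fold changes divide by the mean over all pooled
  DMSO fields of the plate, which maximizes reference stability and
  makes DMSO normalize to exactly 1 in expectation.
* **Z′-factor** is computed on well-level means (one value per control
  well), matching the well-count framing of screening QC, not on
  field-level values.
* **Hits** require a phospho-tau fold change below the positive-control
  fold change in *both* compartments, no toxicity flag, and QC pass.
  Compounds below the control in the neurite compartment only are
  reported as neurite-selective, not as hits. No multiple-testing
  correction is applied: the threshold is the measured positive-control
  effect, not a p-value.
* **Dose–response.** The 4PL family
  `y = bottom + (top − bottom)/(1 + 10^((logIC50 − x)·h))` with
  `x = log10(dose)` is fitted by Levenberg–Marquardt least squares
  (`minpack.lm`) from a 30-point multi-start grid over Hill slopes
  (±0.5, ±1, ±2) and the observed log-dose range, with `top` bounded in
  [0.5, 1.5] and `bottom ≥ 0` by default (responses are fold changes).
  Constant responses are rejected as "no dose dependence" rather than
  fitted.

## Numerical and I/O choices

Pixels are indexed on the image grid with no sub-pixel geometry; masks
share the grid exactly. 8-connectivity is used everywhere (diagonal 1-px
neurites stay connected); since the underlying labeller is
4-connectivity, components are united across diagonal adjacencies by
union-find. Skeletons come from Zhang–Suen thinning. Label masks are
written as 16-bit single-plane TIFFs (error above 65535 labels) and
intensity fields as 16-bit multi-plane TIFFs; integer intensities
round-trip bit-exactly and are never rescaled on read. Metrics CSVs are
written at 17 significant digits so read-back agrees to 1e-12 relative.
Ties between somata competing for a pixel resolve by nucleus proximity.
Empty compartments yield NA means, never 0.

## Validation scale

The test suite and the acceptance script run the pipeline at desk scale:
segmentation recovery on 512×512 fields with 30 neurons (the default
1024×1024 grid halved, with density preserved), effect recovery on
320×320 well pairs, and an end-to-end screen on a 48-well plate
(4 DMSO, 4 positive-control, 40 compound wells with 3 planted actives
and one neurite-selective compound) at the assay's full 25 fields per
well on small (192×192) fields. The 25-field layout is not negotiable
for the screen: the neurite-area readout carries ~19% field-to-field
sampling variation, and only the 25-field well mean (CV ≈ 4%) gives the
20%-decrease toxicity rule its margin — with 3–4 fields per well the
rule fires on sampling noise. Field sizes were chosen so a full
validation completes in minutes on one CPU while keeping per-field
object counts in the regime the assay images.

## Known limitations

* Soma/neurite separation at the soma boundary inherits the generator's
  crisp geometry; on real images the transition is gradual and the
  20 px growth cap and opening scale would need recalibration.
* The clump detector keys on DNA fusion and brightness; clumps of
  non-neuronal debris without elevated DNA would be missed.
* The mean-CI reading of the field-exclusion bound removes a substantial
  fraction of low-area fields when field-to-field variability is small;
  the percentile alternative is provided for that regime.
* Dose–response fitting reports, but does not resolve, the sign
  ambiguity of the Hill slope for non-monotone data; multi-start plus
  bounds make the noiseless fit exact and the noisy fit stable.
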