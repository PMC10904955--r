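---
title: "Methods: cell classification and measurement in microfluidic-chip fields"
author: "chipcyte"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell classification and measurement in microfluidic-chip fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcyte)
```

## The problem

Organ-on-chip co-culture experiments image two cell populations growing in
the gel channel of a three-channel microfluidic device: typically
GFP-tagged tumour cells invading towards endothelial cells, with all cells
stained by phalloidin and nuclei by DAPI, or two populations carrying GFP
and RFP tags. Each chip is imaged as five to six fields of view at 20x,
with one grayscale plane per fluorescence channel; trapezoidal PDMS posts
(100 µm base, 100 µm apart) appear as dark regions at the channel margins.
The analysis question is per-population: how many cells of each class are
in each field, how much area do they cover, where are they (the X position
measures invasion depth), and what shape are they.

`chipcyte` implements this as two declarative protocols over a small set
of operators, and adds a synthetic field generator with ground truth so
that every stage can be tested quantitatively without microscopy data.

## Pipeline anatomy

Both protocols share the same skeleton:

1. **Seed detection** (`segmentObjects`): kernel-based detection of a
   small bright punctum at the brightest part of each nucleus in the
   nuclear channel (kernel 15 px, sensitivity 50), then binary erosion
   with a width-16 disc and an area sieve retaining objects larger than
   20 px² — leaving one compact seed per nucleus.
2. **Nuclear segmentation** (`segmentNuclei`): each seed grows into a
   nucleus candidate (minimum target area 600 px², sensitivity 15).
   Because growth starts from the seeds, touching nuclei are split by
   construction — the "clump breaking on seeds" step of the protocol is
   realised inside the seeded growth rather than as a second pass.
3. **Cell-target segmentation** (`segmentIntensity`): per-channel
   intensity-range thresholding (inclusive on both bounds, no size
   limit), followed by erosion, nuclei-seeded clump breaking
   (`breakClumps`), hole filling and two area sieves.
4. **Population algebra** (`maskSubtract`): in the GFP/phalloidin
   protocol the marker-negative population is all cells minus the
   GFP-positive cells.
5. **Nucleation linking** (`linkByOverlap`): a cell object is kept only
   if a nucleus lies at least 80% within it, which removes anucleate
   fragments; each kept object records its nucleus.
6. **Measurement** (`measureObjects`, `summarizeFields`): per-object
   area, centroid (x = column, 0-based, origin top-left), perimeter,
   form factor and eccentricity; per-field counts and areas; across-field
   sums (fields are summed, never stitched).

## Declared operator conventions

The vendor software the protocols were designed in documents its
parameters but not its algorithm internals, so the package fixes explicit,
configurable conventions.

**Sensitivity of object segmentation.** Sensitivity is defined as a
minimum object brightness-to-background ratio. We compute a local
foreground estimate (box mean of width $k$) and a local background
estimate (median filter of radius $3k$ — wide enough that a kernel-scale
object cannot dominate the window), and accept pixels where

$$\frac{\mu_k - f}{\max(\beta_{3k} - f,\ 1)} \ \ge\ 1 + \frac{100 - s}{50},$$

with $f$ the global plane minimum. Sensitivity $s = 50$ therefore demands
a 2:1 local contrast ratio and higher sensitivity demands less. The
global-floor subtraction makes the criterion exactly invariant to a
constant intensity offset (camera pedestal), which a raw intensity ratio
would not be.

**Nuclear growth.** Growth from seeds is nearest-seed assignment (exact
Euclidean distance to the seed region) restricted to the region where the
lightly smoothed plane exceeds $b\,(1 + (100-s)/100)$, with $b$ the plane
median (at least 1, so an all-zero plane yields no nuclei). Each candidate
keeps only its seed-connected part, is opened once with a radius-2 disc
(the rounded-object constraint), and must reach the minimum target area.
The default 3×3 pre-smoothing was chosen against the package's noise
model: at the default noise level it brings the fraction of background
pixels above the growth threshold from roughly 20% down to below 1%,
without biasing the nucleus boundary by more than a pixel.

**Clump breaking.** "Segmentation at equal distances between nuclei" is
realised as the generalised Voronoi partition of the mask: every pixel of
a component that contains nuclei is assigned to its nearest nucleus
(distance to the nearest pixel of the nucleus region by default; centroid
distance is available), ties to the lower label. Components containing no
nucleus keep a single fresh label. The assignment is computed from exact
integer squared distances, so it is bit-reproducible and testable against
a per-pixel brute-force oracle.

**Sieve direction.** "Greater than 20 px" is read as *retain* objects
strictly greater than the threshold (the seed sieve removes small debris);
`less_than` retains strictly smaller objects. Both directions are exposed.

**Overlap rule.** The protocol states the rule two ways that disagree on
the denominator ("cell object that does not overlap with a nucleus by at
least 80%" vs "80% of primary target within secondary target" with the
nucleus as primary). The parameter listing wins: the fraction is
(nucleus pixels inside the cell) / (nucleus pixels), inclusive, and the
other reading is available via `denominator = "secondary"`. The comparison
is done in integers (`|n∩c|·10⁶ ≥ round(f·10⁶)·|n|`) so that a nucleus at
exactly 80% is retained and 79% is removed, with no floating-point edge.
Survival requires only that *some* nucleus matches; the recorded
nucleus-to-cell assignment is made one-to-one greedily by descending
fraction. At the protocol's 0.8 fraction this is automatically one-to-one
(fractions of one nucleus over disjoint cells sum to at most 1), and
keeping survival as the pure existence rule preserves a useful property:
lowering the fraction can only add survivors, never remove them.

**Perimeter and shape.** The shape score is the form factor
$4\pi A / P^2$. The perimeter convention matters: counting exposed pixel
edges (the crack boundary) overestimates a disc's perimeter by $4/\pi$,
giving digital discs a form factor near $\pi^2/16 \approx 0.62$ and making
"round" unreadable. We instead use the Benkrid weighted boundary-step
estimator — border pixels weighted 1 (straight), $\sqrt2$ (diagonal) or
$(1+\sqrt2)/2$ (corner) by their border-neighbour pattern — under which a
radius-20 digital disc scores ≈ 0.95. Perimeters are computed per object
on the object's own mask in isolation.

**Connectivity and ordering.** Foreground connectivity defaults to 8
(diagonal contact within one stained cell should not split it) with
4-connected background for hole filling, the standard dual pair. All label
maps are numbered 1..N by the raster order (row-major, top-left first) of
each object's first pixel, so outputs are deterministic and diffable.

## Protocol engine wiring

The engine executes a validated step graph (every referenced target
defined earlier, exactly one nuclear target). Three wiring choices go
beyond the printed step lists and are deliberate:

* **Class partition by construction.** The GFP-cells target is restricted
  to the final Cells mask, and the GFP-negative target is
  `maskSubtract(Cells, GFPcells)`. The two whole-cell pixel sets are then
  disjoint subsets of the Cells mask, which the engine asserts on every
  run together with the per-object nucleation rule.
* **Re-splitting after subtraction.** The original software derives the
  negative population by image-window subtraction before segmentation, so
  its per-cell splits survive implicitly. Explicit mask subtraction would
  merge touching negative cells again, so the engine re-applies
  nuclei-seeded clump breaking to the subtraction result before sieving.
* **Debris policy.** The protocol defines a debris target (small objects
  below 100 px²) but never states where it is consumed. It is computed
  and, by default, not consumed; `debrisPolicy = "exclude"` removes
  debris pixels from the cell targets after hole filling (excluding
  earlier would be undone when enclosed holes are refilled).

Unprinted values are exposed as arguments with documented defaults:
intensity ranges default to an automatic Otsu threshold on the integer
histogram (`autoIntensityRange`), the cell-target erosion kernel to a
width-3 disc, and the cell-scale sieves to less-than 15000 / greater-than
100 px², sized for cells at 20x magnification. All of this — including the
printed parameters — lives in the two shipped YAML presets.

## The synthetic field generator

`generateField` emulates the chip fields the protocols were designed for:
elliptical nuclei (radius 14–18 px, eccentricity ≤ 0.6, so areas sit
comfortably above the 600 px² minimum), cytoplasm at twice the nucleus
radius carrying the pan-cell stain (with a reduced residual level over the
nucleus, so the cell mask genuinely acquires nucleus holes that the
hole-filling step must close), GFP/RFP planes lighting the tagged subset's
whole cell, trapezoidal posts zeroed in all planes along both lateral
margins, and optical blur (Gaussian, σ = 2 px).

**Noise model.** Poisson shot noise on (background + signal) plus Gaussian
read noise. The single `snr` knob is defined as (peak nuclear amplitude) /
(background noise sd); the read-noise sd is chosen to hit that total
background sd given the Poisson contribution of the 500-count background
offset. Rendering amplitudes are fixed constants — nuclei and tags 5000
counts over background, cytoplasm 3000 — chosen as a well-exposed 16-bit
field (signal an order of magnitude over background), which also makes the
protocol's printed sensitivities meaningful on synthetic data.

**Placement.** Dart throwing with a minimum centre distance of 0.8× the
cytoplasm-radius sum; a `clumpProbability` fraction of cells is placed as
deliberate touching pairs at 0.9× the cytoplasm-radius sum. Pairs are
placed first, while the field is sparse, so the requested count is
reliably achievable; an infeasible request fails with an explicit error
after bounded retries. The pair distance is chosen so cytoplasm genuinely
overlaps (exercising clump breaking and the subtraction re-split) while
nuclei — the objects the counts hang on — remain separate; placing nuclei
so close that they merge would make any count-recovery statement about
the pipeline meaningless, since a merged nucleus pair is one seed for any
seed-based method.

**Class counts** are deterministic (`floor(n·f + 0.5)` cells tagged),
membership is random. Each field is generated under its own seeded RNG
stream and the global RNG state is restored afterwards.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: point-spread-function tails and channel
bleed-through, uneven illumination, autofluorescence gradients near the
gel interface, elongated sprouting morphology (cells are ellipses; a real
invading cell can be far from convex), focus drift, and density far above
the placement limit. Recovery results on synthetic fields bound what the
implementation can do under its own model, not instrument performance.

## Verification strategy and problem sizes

The test suite checks three layers:

* **Operator–oracle equivalence**: erosion, hole filling, sieve,
  connected components, clump breaking, subtraction and overlap linking
  are each compared, bit-exactly, against independent brute-force per-pixel
  implementations on 200 random instances up to 32×32.
* **Invariant properties**: anti-extensivity/extensivity/idempotence of
  the morphology, pixel conservation and the equal-distance property of
  clump breaking, monotonicity of intensity segmentation and of the
  linking fraction, offset invariance of object segmentation, partition
  and nucleation invariants on full protocol runs, and bit-identical
  reruns including CSVs.
* **Recovery on study fields**: 20 seeded 512×512 fields per protocol
  (30 cells, 40% GFP, snr 10, 20% clumped for the two-class protocol;
  10+10 GFP/RFP for the two-tag protocol), scored by one-to-one matching
  through nucleus centroids. Smaller 288×288 fields with proportionally
  smaller post geometry are used for the faster property tests, and a
  three-level noise sweep (snr 20/5/2, ten seeds each) checks that harder
  noise never improves mean F1.

`scripts/acceptance.R` re-runs the 2×20-field study from a command-line
seed and writes the pooled per-class F1, median absolute count errors and
summed counts as JSON.

## Known limitations

* The operator conventions above are declared reconstructions of an
  undocumented commercial toolbox, not reverse-engineered equivalents;
  parameter values transfer, exact masks will not.
* Physical-unit areas appear only when a pixel size is supplied; the
  20x pixel pitch of the original instrument is not assumed.
* Single 2D planes only: no z-stacks, no time-lapse linking, no
  illumination correction, no mosaic stitching (fields are summed).
* `breakClumps` computes one exact distance transform per nucleus; with
  thousands of nuclei per field a multi-source propagation would be the
  better implementation.
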