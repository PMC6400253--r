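---
title: "Automated micro-crystallography planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated micro-crystallography planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microzoo)
```

## What the package models

Fully automated data collection at a microfocus macromolecular
crystallography beamline proceeds, per sample, through a fixed sequence:
find the cryoloop in the on-axis microscope, center its tip on the beam,
find the *face angle* (the goniometer rotation at which the loop's largest
face is perpendicular to the X-rays), raster-scan a beam-sized grid over
the loop while counting diffraction spots per grid, segment the resulting
heat map into crystals, choose a collection scheme per crystal, and budget
the exposure so the absorbed dose stays below a user limit. `microzoo`
implements that entire decision core against a *virtual beamline*: every
measurement the planners consume is simulated from a ground-truth sample
description, so the full pipeline is testable on a desktop with no
hardware.

### Coordinate conventions

Sample-frame coordinates are (x, y, z) in micrometres. The goniometer
rotation axis is Z (horizontal; the loop tip points toward &minus;Z, the
left of the image), the beam travels along lab X, and lab Y is vertical.
Rotating the sample about Z by &omega; degrees maps sample to lab
coordinates; the beam passes through the lab origin. Heat maps and raster
areas live in the "planner frame": lab (y, z) at the angle the scan was
taken, with zero beam depth. `plane_to_sample()` (internal) converts
planner grids back to sample coordinates whenever a simulated measurement
is requested.

## The virtual beamline

A sample is a planar loop plus a list of crystals:

* **Loop.** A thin disk (ring plus liquid film &mdash; the microscope
  silhouette does not resolve the ring interior) whose plane contains the
  rotation axis, with a stem along +Z. The silhouette of the disk tilted
  by &gamma; from face-on projects with vertical semi-axis
  `max(R |cos g|, t/2)`: a thin plate whose edge-on width is floored at
  the effective material-plus-film thickness `t` (default 80 um, which
  also bounds how far crystal centers may sit off the loop plane). The
  floor matters: an
  additive `(t/2)|sin g|` term would have a cusp slope at the face angle
  and bias the silhouette maximum by `atan(t / 2R)` (~2&ndash;9 degrees),
  whereas the floored model keeps the extremum exactly at the face angle.
* **Crystals.** Axis-aligned boxes in the sample frame with a
  `diffraction_power`: the expected number of low-resolution spots when a
  raster grid fully illuminates the crystal. Because rotation is about Z,
  a box's shadow perpendicular to the beam is an exact rectangle, so the
  illuminated fraction of a top-hat beam footprint is a product of two
  one-dimensional overlaps &mdash; analytic, and cross-checked in the tests
  against an independent ray-march oracle.
* **Noise.** Raster spot counts are Poisson around the analytic
  expectation; images carry additive Gaussian noise. Both are pure
  functions of (sample, pose, seed).

The generator deliberately omits Bragg geometry, detector panels,
refraction and ice artifacts: the planners only consume silhouettes and
spot counts, and these are the quantities the synthetic model controls
exactly. Passing tests therefore demonstrate the *decision logic*, not
robustness to real-image texture.

## Loop centering

1. **Binarization.** The background image is subtracted, the difference
   Gaussian-blurred (sd 2 px) and thresholded; the default threshold is
   Otsu's method on the blurred difference, since the silhouette/background
   histogram is strongly bimodal and no fixed constant generalizes across
   cameras.
2. **Search.** Binarized views at &omega; = 0, 45, 90, 135 degrees are
   examined; if all are empty the sample is translated horizontally by 1.5
   image widths and the examination repeats, at most twice, after which
   the pin is reported empty (a normal outcome for unattended runs).
3. **Tip centering.** At 0, 45 and 90 degrees sequentially, the leftmost
   true pixel (ties: the row nearest the beam height) is driven to the
   beam column and the center of gravity of all true pixels to the beam
   row. Horizontal moves fix the Z coordinate; vertical moves at two
   angles 90 degrees apart fix the remaining two coordinates. The whole
   silhouette (not only the loop head) enters the center of gravity; on
   clean silhouettes the disk-plus-stem shape is vertically symmetric
   about the tip height, so the two definitions agree.
4. **Face angle.** True-pixel counts at 0/45/90/135 are fitted to
   `N = A + B cos(2(theta - phi))`; with four samples the least-squares
   solution is closed-form (`A` the mean, `B, phi` from the two
   differences). The face angle is 90 degrees past the fitted minimum,
   reported in [0, 180) with ties resolved toward the smaller angle. Equal
   counts (no modulation) are a flagged error.
5. **Raster area.** The bounding rectangle of true pixels at the face
   angle is divided by the beam sizes with ceiling division (grid step =
   beam size). A user "loop size" caps the horizontal span measured from
   the tip &mdash; under the cap, floor division is used so the scanned span
   never exceeds the cap &mdash; and the loop is then shifted left by half
   the cap so the scanned region straddles the beam.

## Spot finding and heat maps

The spot finder follows the peakfinder8 family: per-radial-bin (1 px wide)
background mean and sigma, refined over 3 iterations in which pixels more
than 2 sigma above their bin mean are excluded (the tighter clip is what
lets bright peaks stop inflating the background estimate); candidate
pixels above `mean + SNR x sigma` (SNR 6) and an ADC floor; 8-connected
agglomeration; footprint gating at 3&ndash;100 pixels;
background-subtracted intensity-weighted centroids. Resolution comes from
the radial position via `d = lambda / (2 sin(0.5 atan(r / D)))`.

A frame's score is the number of spots at `d >= 5` Angstrom. The 5 A
cutoff is the robust crystal-presence statistic because ice (~3.7 A) and
lipid (~4.5 A) powder rings fall below it. Scores assemble into a heat map
in raster or serpentine (boustrophedon) acquisition order and round-trip
losslessly through a plain TSV dialect (grid indices 1-based in the file,
coordinates at 0.1 um; origin/step/omega at full precision in header
comments). Grid selection applies the 15&ndash;100 score window (grids
above the window are treated as pathological and neglected) with greedy
minimum-distance thinning, ties broken by (row, column).

## Scheme planning

**Segmentation** repeatedly takes the best unassigned grid above the
threshold and flood-fills over 8-connected above-threshold neighbours
("surrounding" includes diagonals); the result equals connected-component
labeling, emitted by descending peak score.

**Categorization** (mixed scheme) applies, per crystal: no horizontal
overlap with any other crystal &rarr; *helical full rotation* candidate;
overlap but every vertical gap at least `3 x` the vertical collection beam
size (default 15 um) &rarr; *partial helical* candidate; otherwise
*clustered*. Size gates then move candidates shorter along the axis than
`min_helical` to *small wedge* and longer than `max_helical` to
*clustered*. The gates are applied to full-rotation candidates as well as
partial ones: an isolated 5 um crystal cannot support helical collection
either. Defaults `min_helical = 40`, `max_helical = 100` um: below ~4 grid
steps a measured length (quantized to the 10 um raster) is dominated by
grid alignment, and crystals beyond ~100 um at these beam sizes are better
treated as clusters. Vertical gaps are measured between grid-center
intervals; horizontal overlap uses intervals extended by half a grid step
(physical extents).

**Helical vectors.** Each crystal's leftmost/rightmost columns define its
edges. For a total oscillation `T` the start edge is scanned vertically at
`face - min(T/2, 90)` and the end edge at `face + min(T/2, 90)` (the
&plusmn;90 clamp corresponds to data sets beyond 180 degrees). The scan is
centered at the edge's predicted height at the scan angle under the
assumption that the crystal lies in the raster plane (true for crystals in
the loop film), and the best-scoring step (ties: lower index) provides the
second projection; the two linear projections are solved for the 3D edge
position. The edge height on the face-angle map uses the score-weighted
centroid of the edge column, so partially illuminated boundary grids pull
proportionally rather than voting fully. Depth recovery is well posed for
plate-like crystals whose beam-depth extent does not exceed the beam size;
thicker crystals carry a quasi-3D ambiguity of up to half the excess,
inherent to scanning a plateau-shaped response.

**Clustered splitting** collects small wedges on a stride-2 lattice of
member grids anchored at the best grid (grids separated by one grid in
both directions are assumed to be distinct crystals), guaranteeing no two
collection points are 8-adjacent.

**SS-ROX.** Serial rotation scans tile the loop: frames per line =
ceiling(horizontal extent / scan step), oscillation per line = frames x
rotation width per frame, lines tile the vertical extent at the line
spacing.

## Dose budgeting

The absorbed dose uses a transparent thin-crystal absorption model:

> dose = fluence x E_photon x (mu_en / rho)

with fluence = flux x transmission x time / footprint area. Defaults:
`mu_en_rho = 0.24` m^2/kg (water-like at 12.4 keV, a reasonable stand-in
for a typical protein crystal), density 1200 kg/m^3, photon energy 12.4
keV, and an unattenuated flux corresponding to a flux density of 1e10
photons/um^2/s over the footprint. Photoelectron escape and elemental
composition are deliberately not modelled; all coefficients are
configuration. `flux` is defined as the *unattenuated* beam (transmission
1) and is multiplied by the `transmission` field at dose time, so varying
transmission never double-counts attenuation.

Helical and SS-ROX illumination accumulate the per-frame stationary dose
over a uniformly translating top-hat footprint, sampled at 0.1 um; the
footprint is half-open so abutting frames tile without double counting.
The interior plateau equals the per-frame dose times the number of frame
centers within one beam width, and the peak is cross-checked in the tests
against an independent frame-by-frame accumulation oracle to &lt;1%.
Radiation-damage propagation is a declared stand-in: a Gaussian kernel of
configurable sigma convolves the profile on an extended support, which
conserves the integrated dose exactly by discrete kernel normalization.

Because every dose is linear in exposure time and transmission, inverting
a budget (default 10 MGy) is exact: the suggested plan re-estimates to the
budget to numerical precision, and a hardware floor on the frame time
turns an unreachable budget into an error naming the binding constraint.

## Orchestration

Plan rows (CSV with the documented header names, or JSON) carry per-sample
parameters; omitted fields fall back to typical multiple-small-wedge
conditions (5 degrees per wedge in 0.1 degree frames, 10 x 15 um beam,
10 MGy per wedge, 200 mm camera distance, 600 um loop size, 15&ndash;100
spot window, at most 100 collections per loop). The per-line goniometer
speed is grid step x frame rate (500 um/s at 10 um / 50 Hz) and the
2 ms trigger jitter is reported as a positional error bound of jitter x
speed (1 um under default conditions) &mdash; arithmetic only, no real-time
modelling. Runs enforce the spot window, the per-loop cap and the dose
budget; a missing loop yields a `no_loop` record and the run continues
(unattended operation); a crystal found on the map but lost by the
vertical scan is skipped with an `edge_not_found` status. The loop
position found on a pin seeds the search on the next pin of the same puck.
Collections against the virtual beamline record per-frame metadata only;
no synthetic detector frames are rendered inside runs, which keeps a full
multi-sample run to seconds.

## Validation sizes and limitations

The shipped tests validate: tip/face/helical-vector recovery on 50 random
noise-free samples (tip and vector endpoints within one 10 um grid step,
face angle within 3 degrees); segmentation against an independent
connected-component labeler on 200 random maps; the spot finder against a
brute-force per-pixel background oracle on 20 frames of 64 x 64 pixels;
helical peak dose against a 0.1 um accumulation oracle on 50 random
configurations; exact reproduction of the nine-crystal mixed-scheme
grouping; and dose round-trips at 8, 10 and 12 MGy budgets across all
schemes. These sizes keep the whole suite around a minute on one core
while leaving each claim with enough repetitions to be meaningful.

Known limitations: silhouette realism is intentionally minimal (no
texture, ice or refraction), crystals are axis-aligned boxes, the damage
propagation kernel is a stand-in for experimentally derived models, depth
recovery assumes plate-like crystals near the loop plane, and overlap
re-evaluation after removing clustered crystals is single-pass.
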