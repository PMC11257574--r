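---
title: "Screening predicted septin-exocyst interfaces and quantifying division-site fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening predicted septin-exocyst interfaces and quantifying division-site fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septexo)
```

## The problem

In fission yeast cytokinesis, the four vegetative septins (Spn1-Spn4)
form rings at the rim of the division plane, and the octameric exocyst
complex (Sec3, Sec5, Sec6, Sec8, Sec10, Sec15, Exo70, Exo84) must be
held at that rim to tether secretory vesicles where the septum meets
the plasma membrane. Asking whether these two machines touch leads to
two computational problems this package implements:

1. **An interface screen over predicted pairwise complexes.** Every
   septin-exocyst subunit pair can be modelled by a structure
   predictor; the screen extracts candidate binding residues from each
   model, discounts low-confidence regions, and demands that an
   interaction survive a prediction run in *both* sequence input
   orders before calling it.
2. **Quantitative fluorescence readouts.** Division-site intensities
   (paired-ROI background subtraction on sum projections), axial
   colocalization profiles, aligned cross-section line scans, a
   ring-vs-disk localization index, and FRAP recovery kinetics.

Because no model files or images are deposited alongside the study
this package re-implements, every stage is exercised against synthetic
inputs with planted ground truth, generated by the package itself.

## The interface screen

**Contacts.** An interface residue pair is any inter-chain residue
pair with a minimum non-hydrogen atom distance of at most
`cutoff_angstrom` (default 4.0 &#8491;, inclusive). Heavy-atom minimum
distance - rather than C&alpha;-C&alpha; or centroid distance - is the
standard convention at this length scale; hydrogens are excluded
because predicted models do not carry them. `extract_contacts()` is
required (and tested) to be bit-equivalent to a brute-force all-pairs
scan.

**Confidence filter.** Predictors write a per-residue pLDDT score
(0-100) into the B-factor field. Contacts are kept only when the
participating residues score at least `min_plddt` (default 50;
a residue at exactly 50 is retained, mirroring the convention of
excluding scores *below* 50). By default **both** partner residues
must pass: a contact whose one side is unreliable is unreliable. A
`scope = "either"` switch relaxes this for sensitivity analyses.

**Ranking and consensus.** Each prediction run returns several models
(five in the emulated design); they are ranked by model-mean pLDDT,
ties broken deterministically by model id, and the rank-1 model of
each input order defines that order's interface. A pair *shows an
interaction* when at least `min_contacts` filtered contacts survive in
each order. The source protocol gives no numeric criterion for
"showed interactions", so the default is the weakest defensible one
(`min_contacts = 1`), exposed as a parameter. Similarly, interfaces
are taken from the rank-1 model only (the protocol names the rank-1
model); pooling across ranks is deliberately not implemented. The
ranking score of a consensus pair is the *minimum* over the two orders
of the interface-mean pLDDT - a conservative choice that cannot be
inflated by one optimistic order.

## Steric feasibility on assembled complexes

Pairwise models ask whether two isolated subunits can touch; the
follow-up question is whether the predicted binding residues remain
available on the surface of the *assembled* septin or exocyst complex.
The original assessment was visual (surface colouring in a molecular
viewer); this package substitutes the only reproducible surrogate:

- `compute_sasa()` implements Shrake-Rupley numerical solvent-
  accessible surface area: each atom's expanded sphere (van der Waals
  radius + probe radius, default 1.4 &#8491;) is sampled with a
  deterministic golden-spiral lattice (`n_points = 960`); points
  inside any neighbour's expanded sphere are occluded. Boundary ties -
  a test point exactly on a neighbour's sphere, which arises for
  coincident atoms - are resolved in favour of the lower-numbered
  atom, so a fully overlapping pair contributes exactly one sphere's
  surface.
- Relative SASA divides by a per-residue-type theoretical maximum
  (Tien et al. 2013 table); the table used is recorded in every
  report. A residue is called accessible at relative SASA >=
  `rsa_threshold` (default 0.25, a common exposure threshold).
  The threshold is configurable, and reports always carry it, because
  this quantitative criterion is *our* surrogate for the original
  visual call - the headline percentages of the original study are not
  recomputable without its undeposited models.
- SASA is computed in **complex context**: an interface residue buried
  by the complex's own subunits counts as inaccessible, which is
  exactly the question asked of the assembled structure.
- Residue mapping between pairwise models and (possibly truncated)
  complex models is **explicit configuration** - per-subunit offsets
  and kept ranges - never sequence alignment. A residue-name mismatch
  is a hard error (the cheapest off-by-one guard); residues falling in
  trimmed ranges are reported as unmappable rather than dropped. The
  same code path runs on octamer and hexamer complexes; only the input
  file differs.

## Fluorescence quantification

Pixel coordinates are 0-based, origin top-left, half-open ROI bounds;
all positions are reported in micrometres via the pixel calibration.

- **ROI intensities** use a signal rectangle ROI1 inside a background
  rectangle ROI2 of roughly twice the area (the ratio is a
  configuration value, default 2.0, since only "approximately twice"
  is specified). The ROI2-minus-ROI1 annulus estimates per-pixel
  cytoplasmic background: `corrected = I1 - A1 (I2 - I1)/(A2 - A1)`.
  The protocol cites this correction without printing the formula;
  the formula above is the implemented convention and recovers a
  planted signal exactly on uniform background.
- **Line scans** average over a 3-pixel width; axis-aligned lines at
  integer coordinates reduce to exact pixel means, oblique lines are
  sampled by bilinear interpolation at unit-pixel steps.
- **Alignment** supports the four strategies used across the
  measurement designs: a reference channel's peak, each profile's own
  brightest position, the midpoint of two separated peaks, and an
  externally supplied centre. Peaks are found on a 3-point smoothed
  copy; the two-peak rule takes the two highest local maxima at least
  3 positions apart and fails loudly otherwise.
- **Rim-spread index** quantifies what was originally scored by eye
  (intact rim ring vs signal spread over the division plane): on a
  cross-section profile spanning the cell diameter, centre-third mean
  / (centre-third mean + rim-thirds mean). It is ~0 for a rim ring and
  large for centre-concentrated signal. This index is an invented,
  explicitly labelled surrogate - not a reimplementation of the
  original visual scoring.

## FRAP kinetics

The pipeline follows the acquisition designs of five pre-bleach frames
plus 150 post-bleach frames at 0.33 s (or 70 at 10 s):

1. **Correction**: background is subtracted and the acquisition-
   photobleaching decay measured on an unbleached reference cell is
   divided out, rescaled to the mean pre-bleach reference.
2. **Normalization**: affine map sending mean pre-bleach to 100% and
   the first post-bleach value to 0% (idempotent by construction).
3. **Smoothing**: centred rolling average (window 3) over post-bleach
   points only; edge windows shrink to the available points.
4. **Fit**: least squares for `y = m1 + m2 exp(-m3 x)` with x = 0 at
   the first post-bleach frame, `m3 > 0` bounded, deterministic
   initial values (plateau from the last 10% of points, rate from a
   log-linear regression); `t1/2 = ln 2 / m3` exactly.

One numerical subtlety is worth spelling out. A rolling average does
not commute with the exponential model: smoothing multiplies the
amplitude by `(e^{m3 dt} + 1 + e^{-m3 dt})/3` (about 8.5% at
`m3 = 0.05` /s and `dt = 10` s) and breaks exact exponentiality at the
shrunken edge windows. Fitting the raw model to smoothed data would
therefore bias `m2` and, through the edges, `m3`. Instead,
`fit_recovery()` applies the *same* smoothing operator to the model
curve before computing residuals, so the smoothed pipeline is exactly
invertible: a noiseless simulated trace returns the planted
parameters to numerical precision, while noisy traces still enjoy the
variance reduction smoothing was introduced for. A `smooth = FALSE`
switch fits the raw series, since the original protocol does not state
which series entered the fit.

## The synthetic generators

The generators define the study conditions under which everything is
tested; their defaults are fixed once and mirror the emulated designs.

- `make_pair_model()`: two poly-alanine-like chains (five heavy atoms
  per residue) on parallel scaffolds 25 &#8491; apart; planted contact
  pairs are relocated so the minimum heavy-atom distance equals a
  drawn value in (3.0, 3.9] &#8491; while every other inter-chain
  residue pair stays beyond a 6 &#8491; guard margin. Coordinates are
  rounded to the 3-decimal file precision, so written fixtures
  round-trip bit-identically.
- `make_screen_grid()`: the 4 x 8 subunit grid, both input orders,
  five models per order; six planted bidirectional interfaces (the
  scale of the emulated screen), four one-sided decoys and two
  low-confidence decoys whose contact residues sit below pLDDT 50.
- `make_complex_model()`: residues on a 14 &#8491;-spaced grid;
  buried residues are enclosed in an 80-atom cage (relative SASA <
  0.05 by construction-time check), exposed ones sit in open space
  (> 0.5).
- `make_division_stack()`: end-on division-plane geometry at 0.1
  um/pixel and 0.5 um z-steps: a rim annulus at the cell radius
  (1.8 um, thickness 0.3 um) or a centre disk of 0.6 x the cell
  radius - the disk is deliberately smaller than the cell so that
  "spread over the septum interior" and "confined to the rim" are
  geometrically distinct on a diameter profile. Gaussian PSF blur
  (sigma 0.15 um) and Poisson shot noise at a peak intensity of 200
  counts (peak SNR about 14) emulate confocal acquisition.
- `make_frap_trace()`: forward simulation of the bleach/reference/
  background ROI triplet with per-frame acquisition bleaching,
  constant background and optional Gaussian noise; with the default
  full-bleach shape (`m1 + m2 = 0`) the planted parameters are already
  on the normalized scale.

What these generators do **not** emulate: real protein folds and
packing (residues are geometric clusters), predictor-specific
confidence behaviour (pLDDT values are planted, not emergent), camera
physics beyond Poisson/Gaussian noise, cell-to-cell variability, and
chromatic or stage drift. Passing tests therefore demonstrate that the
*computations* are correct and invertible on controlled inputs - not
that the biological conclusions of any particular dataset would
reproduce.

## Problem sizes and tolerances

The test suite runs the contact oracle comparison on 1000 random
models (up to 60 residues per chain), the feasibility label-recovery
on 50 seeded complexes, the FRAP noise study on 200 seeded traces
(noise sd 2% of amplitude; median off-rate error required < 10%), and
the rim-index separation on 100 simulated cells, requiring zero
overlap between ring and disk classes. Isolated-sphere SASA must sit
within 2% of the closed form `4 pi (r + probe)^2` (the lattice makes
it exact for an isolated atom); noiseless FRAP recovery must be
within 1e-6 relative. The acceptance script
(`scripts/acceptance.R`) recomputes the same quantities at slightly
reduced replicate counts and writes them as JSON.

## Known limitations

- The feasibility threshold (relative SASA 0.25) is a surrogate for a
  visual criterion; percentages quoted for real complexes depend on it
  and on the max-ASA table, both of which are therefore recorded in
  every report.
- PAE matrices are parsed and attached but not used as a filter: the
  emulated screen filtered on pLDDT and input-order consensus only.
- The screen models 1:1 stoichiometry only, and no energetics, docking
  or clash scoring - absence of steric burial is necessary, not
  sufficient, for binding.
- Off-axis line scans interpolate bilinearly; sub-pixel alignment
  accuracy is limited to the sampling step.
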