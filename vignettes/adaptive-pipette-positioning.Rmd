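---
title: "Adaptive image-guided pipette positioning: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive image-guided pipette positioning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pipetteAim)
```

## The problem

Cell-type-targeted electrophysiology and single-cell electroporation in
mouse cortex require steering a glass micropipette onto one chosen,
fluorescently labeled soma under two-photon (2-P) volumetric imaging.
Two error sources dominate a straight advance along the pipette axis:
the pipette bends laterally as it penetrates the pia and tissue, and the
target cell is displaced by the advancing probe. Both are several
microns — comparable to a pyramidal soma radius (~5 µm) — so an
uncorrected approach typically ends about a cell diameter off axis.

The adaptive strategy implemented here re-images the scene part-way
through the approach, re-localizes the tip and the target in the fresh
substack, and corrects the remaining trajectory. This vignette documents
the models, every tunable parameter, the synthetic phantom used to
exercise the pipeline, and the design decisions taken where the
procedure itself leaves latitude.

## Coordinate conventions and separation geometry

All positions are microns in one right-handed stack frame: x anterior
(the horizontal component of pipette advance), y the remaining in-plane
axis, z increasing with depth. Voxel indices are 0-based; voxel centers
sit at `origin + index * voxelSize`. The reference acquisition is a
256 × 256 × 150 stack of (1.23, 1.23, 2) µm voxels.

The unit approach axis for approach angle θ (degrees below horizontal,
default 31) and azimuth φ is (cos θ cos φ, cos θ sin φ, sin θ), so its
vertical component is sin θ. `decomposeSeparation()` splits the
tip-to-target vector into a signed axial component along this axis and a
non-negative lateral component (the closest distance from the target to
the pipette axis line); the Pythagorean identity is enforced by the
`SeparationMetrics` validity method at 1e-9 relative tolerance. The
axial component is kept signed internally (positive = target ahead of
the tip); reporting layers take absolute values. Where the axial
reference point is ambiguous we use the perpendicular foot point of the
target on the axis line.

## Localization pipeline and its parameters

**Tip** (`locateTip()`, pipette-dye channel):

| parameter | default | meaning |
|---|---|---|
| `p` | 98 | upper percentile of the normalization range (lower anchor fixed at the 5th percentile) |
| `thresholdFraction` | 0.90 | segmentation threshold as a fraction of each projection's maximum |
| `minObjectPixels` | 10 | objects need strictly more pixels to qualify |
| `nTipPixels` | 10 | pixels fused into the tip estimate |

The substack is min-subtracted, rescaled so the 5th/p-th percentiles map
to 0/1 (clipped), smoothed with a 3 × 3 × 1 boxcar (in-plane only — the
z extent of the kernel is one voxel because axial sampling is already
coarse), and collapsed into three maximum-intensity projections. Each
projection is thresholded at 90 % of its maximum and the largest
8-connected object above the pixel floor kept. "At the tip" is not
otherwise defined, so we take the `nTipPixels` pixels of the object most
advanced along the in-plane projection of the approach axis, ties broken
by depth and then raster order for determinism. Fusion follows the
stated rules: x from the most anterior tip pixel of the x–z projection,
z from the deepest tip pixel, y from the mean over x–y tip pixels. The
x–y projection also yields a redundant x estimate; we report it, and its
disagreement with the primary estimate, in the `"quality"` attribute
rather than folding it into the fusion.

If the 5th and p-th percentiles coincide (a constant substack), the
normalization returns an all-zero image with a warning rather than an
error; downstream segmentation then reports a tip-not-found condition
identifying the failing projection.

**Target** (`locateTarget()`, cytosolic-label channel):

| parameter | default | meaning |
|---|---|---|
| `bandLow`, `bandHigh` | 2, 20 | characteristic sizes (pixels) of the difference-of-Gaussians bandpass |
| `thresholdFraction` | 0.90 | fraction of the *filtered* image maximum |
| `minObjectVoxels` | 10 | components smaller than this are eliminated (10-voxel objects survive) |

No σ convention is stated for the "characteristic sizes", so we use
σ = size/2 per lateral axis, with the z-σ divided by the voxel
anisotropy dz/dx so the filter is isotropic in microns; this puts the
response peak near 20-pixel blobs, i.e. somata of radius ~5 µm at
1.23 µm/pixel. The threshold is taken relative to the band-passed image
maximum (the plausible alternative — the raw maximum — is recorded as an
open choice; the filtered reference is logged in the output metadata).
Among surviving 26-connected components the one whose center of mass is
nearest the nominal position is returned; the center of mass is
intensity-weighted on the non-negative-clipped filtered image, which is
sub-voxel accurate, and exact ties resolve to the lower
(first-encountered, raster-order) component label.

Connectivity is 8-connected in the 2-D projections and 26-connected in
3-D — chosen for robustness with anisotropic voxels. All filters
replicate the nearest edge value at borders.

A practical limit worth knowing: at (1.23, 1.23, 2) µm voxels a soma of
radius 3 µm has only a handful of voxels above 90 % of the filter
maximum, fewer than the 10-voxel floor, so the defaults cannot detect
somata below roughly 4.5 µm radius. The threshold is user-adjustable
precisely for such cases; lowering it to ~0.6 recovers 3–4 µm somata
with sub-voxel accuracy, and the test suite demonstrates that regime
explicitly.

## Trajectory planning and adaptive correction

`planTrajectory()` plans: a retraction along the negative pipette axis
to a clearance above the pia (default 50 µm — only "up and away" is
prescribed, and retracting axially avoids dragging the tip sideways
through tissue before it leaves the brain), a horizontal translation
onto the approach line (the line through the target parallel to the
axis), and axial steps of at most `stepSize` (default 3 µm, working
range 2–4) ending at the buffer distance `R` (default 12 µm, working
range 10–12) from the target center. Discretization uses equal steps of
L/⌈L/step⌉, so the termination point is independent of the step size and
no step overshoots. Degenerate geometry (axis parallel to the pia) is an
error; a target shallower than R below the pia clamps the termination to
the entry point with a warning.

`computeCorrection()` takes the expected tip (the commanded waypoint at
pause time — always available, unlike an image-derived prior),
the measured tip and target, and returns the tip offset, its lateral
component, and the target displacement. `adaptTrajectory()` shifts the
remaining path by minus the lateral tip offset and translates it by the
full target displacement, then re-discretizes. Two deliberate
asymmetries: the axial tip offset is *not* compensated (only the lateral
deflection is corrected; the termination criterion remains
distance-R-from-target), and re-discretization after the shift keeps
every step within `stepSize` (whether the original procedure
re-discretizes or reuses its precomputed steps is not stated; we
re-discretize). The adaptive step runs once, by default at 50 % of the
intracortical depth ("an intermediate point"); the fraction is a
parameter.

`executePlan()` writes one absolute move per waypoint to a command sink
and logs commanded vs acknowledged positions. The sink contract (a
function from a micron triple to an acknowledged triple, `NULL` for
rejection) is all a hardware adapter needs; only a simulated manipulator
ships here.

## The phantom: what it emulates, and what it does not

`phantomSpec()`/`renderStack()` produce two-channel stacks with ground
truth. The pipette channel renders a solid dye-filled cone: apparent tip
radius 2.5 µm (a 2–3 µm tip outer diameter plus the point-spread skirt
that becomes visible at the very low saturation level of percentile
normalization), taper half-angle 3°, edge width set by `psfBlur`
(default 1 µm, a typical in vivo 2-P lateral resolution). The cell
channel renders Gaussian-edged spheres (default radius 5 µm, peak 150
counts over a 25-count background) with a slight center brightening so
the intensity maximum is unambiguous. The dense-labeling mode adds
randomly placed distractor somata (drawn dimmer than the target, as an
operator picks a clearly labeled cell) and a smooth neurite-like
texture. Noise is applied last under a stated seed: Poisson on photon
counts plus Gaussian read noise (σ = 2 counts). SNR is defined as peak
signal above background divided by the background standard deviation.

One generator property matters for "noise-free" experiments: percentile
normalization degenerates on an exactly constant background (5th and
98th percentiles coincide) whenever the pipette occupies less than 2 %
of the substack — which a thin cone always does. Real pipette channels
always carry a detector noise floor, so clean-phantom configurations
retain the seeded Gaussian floor while rendering the signal noise-free;
localization accuracy is insensitive to the floor (it sits far below the
90 % threshold after smoothing).

The deflection model is entry-dominated: the lateral tip deflection
ramps linearly with insertion depth and saturates at `saturationDepth`
(default 50 µm) below the pia, and the target displacement is applied as
a step at tissue entry. The reasoning: bending and tissue push occur
while penetrating the stiff pia and superficial tissue, after which the
pipette tracks its commanded path; this is also the only simple profile
under which a correction based on exact mid-course measurements cancels
the deflection completely, which the simulation verifies (final lateral
error < 1e-6 µm with ground-truth localization). How deflection really
correlates with depth is not characterized; the profile is a
configuration choice, not a claim. Batch simulations draw per-approach
deflections and target displacements as independent Gaussian components
in the plane perpendicular to the axis (σ = 5 µm and 4 µm respectively),
magnitudes in the range reported for uncorrected in vivo approaches.

What the phantom does *not* model: optical point-spread anisotropy
beyond a single blur scale, depth-dependent attenuation and scattering,
brain pulsation, neurite-level structure in the pipette channel, and
true beam mechanics of the pipette (deflection is a rigid lateral
offset). Passing tests on phantoms therefore demonstrate the internal
consistency of the pipeline — localization recovers rendered truth,
corrections cancel modeled offsets — not performance on real tissue,
where SNR, motion and tissue mechanics dominate.

## Numerical choices

- Percentiles use linear interpolation between order statistics
  (`quantile` type 7); the test suite cross-checks against an
  independent sort-based computation.
- Gaussian kernels are truncated at 3σ (minimum radius one voxel) and
  renormalized; borders replicate edges for both boxcar and Gaussian
  filters.
- Unit-axis checks tolerate 1e-6 relative deviation; lateral-offset
  orthogonality is enforced to 1e-9 (a second projection pass removes
  accumulated round-off).
- Component labels are assigned in raster-scan discovery order, making
  every tie-break deterministic; identical inputs give bit-identical
  outputs throughout (no hidden randomness).
- Degenerate inputs are conditions, not crashes: constant stacks warn
  and return zeros; an empty segmentation raises a classed
  tip/target-not-found error naming the failing projection; a corrected
  termination above the pia refuses to adapt.

## Problem sizes used by the test suite

Unit tests run on small synthetic arrays (8 × 8 × 4 for the filter
micro-oracles) and rendered regions of interest of roughly
40 × 40 × 20 voxels. The end-to-end suites use 75 tip placements
(25 positions × 3 approach angles), 25 soma placements, 100 seeded
approaches per strategy for the naive/adaptive comparison, 50 trials at
SNR 5, and 100 dense-labeling trials — sizes at which the full suite
completes in a few minutes on one CPU while keeping the Monte-Carlo
estimates stable.

## Known limitations

- The tip estimate inherits a ~1-voxel bias from threshold erosion of
  the smoothed projections; it is below one voxel per axis under the
  reference optics but grows if the apparent tip is much thinner than
  two voxels.
- Somata below ~4.5 µm radius require a lowered segmentation threshold
  (see above).
- The adaptive correction assumes the deflection present at the pause
  persists unchanged to termination; deflection that keeps growing after
  the adaptive step leaves a proportional residual, as it would in the
  real procedure with a single correction.
- Stage/objective registration between microscope and manipulator frames
  is out of scope: all coordinates live in one stack frame.
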