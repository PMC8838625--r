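---
title: "Quantifying void morphology in crystallized lipids: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying void morphology in crystallized lipids: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voidnet)
```

## The problem

Crystallized fats such as cocoa butter and trilaurin contain a gas-filled
void phase whose amount and topology control moisture migration, texture
and stability. Micro-CT resolves this phase non-destructively: at typical
scan resolutions of 15–18 µm/voxel, voids appear as low-attenuation
(dark) regions inside the solid/liquid lipid matrix. voidnet turns such
grayscale volumes into quantitative morphology descriptors:

* **void fraction** `v` — void voxels over total voxels;
* **connectivity** `z` — the mean pore coordination number (throats per
  pore), equal to `2T/P` by the degree identity;
* **volume-weighted mean radii** `R43` for pores and throats — each
  feature weighted by the volume it occupies, the De Brouckère-type
  D[4,3] mean (`Σr⁴/Σr³` for spheres), because large features dominate
  transport;
* binned coordination and radius **distributions** and the **micropore
  fraction** (radius ≥ 10 µm — note this lipid-literature convention is
  inverted relative to IUPAC usage).

## Segmentation

The void/solid threshold is the minimum of the intensity histogram
between the two phase modes. The histogram uses 1-intensity-unit bins for
integer volumes (256 equal bins otherwise), is smoothed with a symmetric
triangular kernel (default half-width 5 bins), and the two
highest-prominence local maxima — histogram ends included — are taken as
the phase modes, with a prominence floor of 0.1 % of the voxel count to
ignore noise spikes. The threshold is the argmin strictly between the
modes; a tied minimal plateau resolves to its midpoint, so a cleanly
separated two-spike histogram thresholds halfway between the spikes. Air
attenuates less than lipid, so `void_is = "dark"` is the default.

For low-contrast volumes whose valley is shallow or absent,
`consensus_threshold()` averages the valley estimate with the
between-class-variance (Otsu) threshold, falling back to whichever
exists; the `method` field flags consensus output. Two caveats the
phantom experiments make explicit: (i) when the noise standard deviation
approaches a quarter of the mode gap, the histogram becomes genuinely
unimodal and *no* threshold recovers the truth well — with modes 40
intensity units apart and noise sd 15, even the best threshold over a
full sweep misclassifies ≈ 7 % of voxels; (ii) Otsu's criterion is biased
toward splitting the dominant mode when the void phase is a small
minority, so the consensus is only as good as the shallower valley
allows.

## Maximal-ball network extraction

The void is discretized into pores (spheres) and throats (cylinders):

1. **Distance map.** An exact Euclidean distance transform gives, for
   every void voxel, the centre-to-centre distance to the nearest solid
   voxel — the maximal inscribed sphere radius at that voxel. The volume
   border counts as solid (a virtual shell), so no ball escapes the field
   of view. No −0.5 surface correction is applied; the constant offset
   cancels in comparisons and the convention is recorded in
   `extraction_params`.
2. **Maximal balls.** Every void voxel proposes a ball of radius `d(x)`;
   a ball contained in another (`|c₁−c₂| + r₂ ≤ r₁ + 1e-9` voxels) is
   redundant and removed. The retained set traces the medial axis.
3. **Pores.** Pore seeds are the plateau-collapsed local maxima of `d`
   over the 26-neighbourhood (one seed per connected equal-`d` plateau —
   digitized spheres otherwise over-seed — at its lexicographically
   smallest voxel). Every void voxel is then assigned to exactly one pore
   by priority flooding from the seeds, i.e. a watershed of `−d`: the
   highest-`d` frontier voxel joins the region of its highest-`d`
   already-assigned neighbour, ties toward the lower region id. Flooding
   (rather than a single globally ordered sweep) guarantees each voxel
   has an assigned neighbour when its turn comes, including members of
   non-maximum plateaus; assignment is a partition, so pore voxel counts
   sum exactly to the void voxel count.
4. **Throats.** Each 26-adjacent region pair defines one throat. Its
   radius is the saddle height of the interface: the maximum over
   spanning voxel pairs of `min(d_i, d_j)` — the widest inscribed ball a
   path from one pore to the other must squeeze through. Defined this
   way the saddle can never exceed either peak, so throat radius ≤ both
   pore radii holds structurally. Dead-end interfaces (single region
   against the border) are not throats; isolated pores count
   coordination 0.
5. **Merging.** A "throat" nearly as wide as the pore it feeds is not a
   constriction but an artefact of over-segmentation; pore pairs with
   throat radius > `merge_ratio` (default 0.7) times the smaller pore
   radius are merged, iterated to a fixed point, and throats recomputed
   between the merged super-regions. One throat is recorded per adjacent
   pore pair after merging.
6. **Geometry.** Pore radius is the seed ball radius; pore volume is the
   assigned-voxel volume; throat length is the centre-to-centre distance
   minus both pore radii, clamped to ≥ 1 voxel; throat volume uses the
   cylinder model `πr²L`. Physical coordinates place voxel `(z, y, x)`
   (0-based) at `(index + 0.5) × voxel_size_um`; voxels are assumed
   isotropic because scans report a single µm/pixel.

All tie-breaks are lexicographic on `(z, y, x)` and the containment
tolerance is `1e-9` voxels, making extraction bit-deterministic; the
suite cross-checks the compiled watershed against an independent plain-R
implementation and the distance map against exhaustive search.

## Synthetic phantoms: what they emulate and what they do not

Because raw CT scans of crystallized lipids are not generally available,
every stage is validated on seeded phantoms reproducing the three void
morphologies such materials show:

* **bubbles** — dilute, disconnected voxelized spheres (air incorporated
  during shearing; `z ≈ 0`, radii lognormal around 50 µm by default).
  The default overlap policy is *forbidden* with a 2-voxel solid
  clearance, chosen so that digitized bubbles are never 26-adjacent and
  the ground-truth pore count is exactly the bubble count. A voxel is
  void iff its centre lies inside the continuous sphere, which gives an
  exact brute-force oracle.
* **cracks** — unions of planar slabs with random orientation (brittle
  post-process fracture). Uniform-aperture slabs are a degenerate input
  for any maximal-ball extractor: the saddle equals the peak everywhere,
  so the merge pass correctly collapses each sheet to a single pore.
  Physical cracks pinch and bulge, so the default aperture is modulated
  sinusoidally in-plane (`aperture = thickness·(1 + 0.6·cos u·cos v)`,
  wavelength 18 voxels), giving each sheet pore bodies connected through
  constrictions. Defaults (3 full-extent planes, mean thickness 2.2
  voxels at 120³) were chosen once to land in the qualitative
  crack-network regime (`v ≈ 0.05`, `z` of order 2) and are not tuned
  further.
* **sintered** — quantile-thresholded smoothed random fields (voids from
  oil displacement during crystal bridging). A single Gaussian excursion
  field does not percolate at `v = 0.12` (its threshold for spanning is
  near 16 %), whereas the sintered voids of high-melting fats form long
  continuous channels. The default `"channel"` field is therefore the
  pointwise maximum of the normalised absolute values of two independent
  smoothed fields: its low values trace the intersection of the two
  nodal surfaces — a volume-spanning network of irregular tubes that
  bulge and pinch. Satellite components (≈ 1–2 % of the void volume) are
  dropped by default so the phantom is genuinely percolating; quantile
  thresholding hits the target fraction up to ties. The `"excursion"`
  field remains available for blob-like voids.

`render_grayscale()` turns a truth mask into a CT-like volume: one mode
intensity per phase, isotropic Gaussian blur (partial-volume mixing),
additive Gaussian noise, clipped 8-bit output. What the phantoms do *not*
emulate: beam hardening, ring artefacts, anisotropic voxels,
sub-resolution porosity, or intensity gradients across the field of
view. Passing tests on phantoms therefore demonstrate the correctness of
the chain on ideal two-phase data, not robustness to scanner artefacts.

A practical resolution note: at 16 µm/voxel a 50 µm pore spans ~3
voxels. Rendering such barely-resolved features with a 1-voxel blur
erases the void intensity mode entirely — which is faithful to how hard
the real segmentation problem is at these scan resolutions. The
segmentation validation therefore uses phantoms whose pores (10 voxels)
are resolved well above the blur scale; extraction itself is validated
separately on unrendered masks at the study resolution.

## Group statistics

`compare_groups()` reproduces the reporting convention of
crystallized-lipid studies: replicate-level scalars per treatment cell
(base fat × emulsifier × shear type), a homoscedasticity gate, then
either ordinary two-way ANOVA (factor p-values) with Tukey HSD across
the four cells, or Welch ANOVA with Dunnett T3 (pairwise Welch t
statistics against Šidák-style studentized-maximum-modulus tails with
Welch–Satterthwaite degrees of freedom). Letters come from the standard
insert-and-absorb compact-letter algorithm and are assigned within one
base fat only; sharing a letter is exactly equivalent to pairwise
`p > α`.

The gate is the Brown–Forsythe statistic (ANOVA on absolute deviations
from group medians). With the three-replicate groups typical of these
experiments, the textbook F reference is severely conservative — the
group median zeroes one deviation per group, and the measured type-I
error at n = 5, four groups, is 0.002 instead of 0.05 — so the default
gate calibrates the same statistic against a 199-label-permutation null
(medians recomputed per permutation), which holds the nominal level at
any group size and is deterministic via a fixed internal RNG substream.
`calibration = "parametric"` restores the textbook p-value.

Two deliberate edge-case behaviours: all-constant groups short-circuit
to a "no difference detectable" flag rather than dividing by zero, and
designs unbalanced beyond one missing replicate force the Welch branch
with a warning. The stage-5 analysis script also illustrates an honest
limitation of the prescribed workflow: with n = 3 and zero-variance
cells (e.g. connectivity exactly 0 in all bubble cells), the gate
detects heteroscedasticity and Dunnett T3 — with its Welch degrees of
freedom of 2 and six-fold multiplicity correction — cannot resolve even
a large shift. The letters faithfully report that inability; they do not
overrule it.

## Numerical choices and problem sizes

* Histogram smoothing bandwidth 5 bins; mode prominence floor 0.1 % of
  voxels; all user-overridable.
* Containment ε `1e-9` voxels; merge ratio 0.7; 26-connectivity for
  maxima, growth, interfaces and component labelling — all echoed into
  `extraction_params` and the network table headers.
* Binary masks serialise as 0/255 8-bit; network tables round-trip at
  full double precision (17 significant digits).
* The test suite and the analysis scripts run phantoms at 12³–200³; the
  replicated study set uses 96³ volumes and the regime checks 120³,
  sizes at which the complete chain (generation, extraction, metrics)
  takes a few seconds per replicate on one CPU and which are large
  enough for ≥ 25 pores per crack/channel replicate.
* Statistical calibration uses 1000-repeat null simulations at n = 5 per
  group.

## Known limitations

* Throat radii are saddle heights of the inscribed-ball field, not
  cylinder fits; absolute throat radii carry the voxel discretization
  error of the distance map (up to ~1 voxel on narrow necks).
* `R43` for throats weights by the model cylinder volume; a different
  throat-volume convention would shift throat radius distributions.
* The merge ratio is a genuine free parameter of all maximal-ball
  extractors; results at ratios near 1 collapse connected structures,
  near 0 they over-segment. 0.7 is the package default and every output
  records it.
* Segmentation assumes a global threshold; spatially varying
  illumination or beam hardening would need local methods that are out
  of scope here.
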