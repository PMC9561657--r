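---
title: "Intrasarcomere morphometry: models, parameters, and validation phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intrasarcomere morphometry: models, parameters, and validation phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcomorph)
```

## Scope and conventions

`sarcomorph` quantifies intrasarcomere structure in isotropic 3D voxel
volumes of striated muscle, of the kind produced by FIB-SEM after binning to
isotropic voxels. Every array uses the same convention: **axis 1 is the
longitudinal (contractile) axis**, axes 2–3 span the muscle cross-section,
voxel centers sit at `(index - 1) * voxel_nm`, and all lengths are in nm.
Anisotropic volumes are rejected rather than resampled, and axis order is
never auto-detected — a `transpose` argument reorders axes explicitly at
load. Distances are voxel-center to voxel-center throughout; surface-to-
surface distances are deliberately not used, because all inputs are masks
and a consistent center convention keeps the distance-transform, proximity
and lattice modules exactly comparable.

The package consumes label masks (Z-disk, A-band, mitochondria, SR/T, lipid,
cell) and grayscale volumes; it does not perform semantic segmentation.
Instance segmentation of mitochondria is likewise out of scope: the
partition and local-thickness analyses operate on the binary network mask.

## The measurements

### Half-sheet CSA heterogeneity

Sarcomere cross-sectional area (CSA) is compared between the Z-disk and the
A-band *per half sarcomere sheet*: the volume is grouped into
sarcomere-length slabs aligned so that each contains exactly one Z-disk
sheet (slab boundaries at M-lines), the Z-disk mask is maximum-projected
per slab and its foreground area counted, and each Z-disk area is duplicated
to serve its two flanking half sarcomeres. A-band areas come from
half-sarcomere-length average projections passed through local-contrast
normalization (window radius P/4, clipped at ±10 SD, stretched to 8-bit),
masked by the slab's maximum projection, and thresholded with the IsoData
intermeans rule. The headline per-sheet statistic is

$$\text{percent difference} = 100\,(A - Z)/A,$$

so 40% means the Z-disk CSA is 40% below the A-band CSA. The raw ratio
\(Z/A\) is emitted alongside, because the alternative convention
\(A/Z - 1\) is also in circulation; inverted sheets (Z > A) are legal and
flagged. The sarcomere period is estimated from the autocorrelation of the
per-slice Z-disk count profile (parabolic sub-voxel refinement, at least
three Z-disks required) with a manual override for short stacks.

### Z-adjacent mitochondria and local thickness

Mitochondrial voxels within \(W_I + 200\) nm of the nearest Z-disk voxel
(exact Euclidean distance transform, threshold inclusive) are classed
Z-adjacent; the fraction of mitochondrial voxels in that compartment
separates perpendicular/grid network configurations from longitudinal ones.
\(W_I\), the I-band width, is an explicit input measured on the raw data —
the package never auto-estimates it, and one scalar is used per volume.
Mitochondrial content is mitochondrial voxels over cell-mask voxels.
Mitochondrial diameters use the local-thickness definition (diameter of the
largest inscribed sphere containing each voxel), computed from the exact
EDT by painting spheres in decreasing radius order.

### Filament tracing

Myosin filaments are segmented by normalized cross-correlation against a
(hollow) cylindrical template — length 100 nm, outer radius 19 nm, inner
radius 0, correlation mask radius 20 nm — over a quasi-uniform Fibonacci
sample of orientations, keeping the per-voxel maximum correlation (mapped
to 0–255) and argmax orientation. "Angular sampling of 5" is interpreted as
approximately 5° spacing between sampled orientations; a `max_tilt_deg` cap
restricts the sample when the fiber axis is known. Correlation is computed
by FFT with replicate padding, and windows whose local SD falls below 2% of
the volume's dynamic range are zeroed: NCC is scale-invariant, so
near-constant windows would otherwise respond to arbitrarily faint
structure.

Centerlines are traced greedily from 26-neighborhood local maxima at or
above the seed threshold (115 by default, range 105–125; ties broken by
voxel index for determinism), stepping bidirectionally inside a search cone
(length 100 nm, half-angle 30°) around a direction that blends the previous
step with the local orientation (direction coefficient 0.3; orientations
are axial, the sign is aligned with travel). The base step is 10% of the
cone length, doubling while correlation stays at seed level. The doubling
cap is exposed as `max_step_nm` because in a dense ~45 nm lattice a 100 nm
step inside a 30° cone can reach a neighboring filament; capping the step
below half the lattice constant removes such hops, and the phantom suite
runs with a 20 nm cap. Traces stop below the continuation threshold (80),
are suppressed within the minimum distance (20, interpreted in nm — 20
voxels at 5 nm would suppress genuine 45-nm neighbors) of accepted traces,
and are discarded under the 500 nm minimum length.

### Deviation from linearity

Per filament, the inertia tensor of its unit-mass voxels is diagonalized
and the moment about the **longest principal axis** is divided by the voxel
count. For an elongated body that moment is the *smallest* eigenvalue, and
the quotient is the mean squared perpendicular distance of filament mass
from its best-fit line (nm²): a straight solid rod of radius r gives the
cross-section floor \(r^2/2\); a thin parabolic arc of chord L and sagitta
s adds \((4/45)s^2\) independent of L. Because naming conventions for
inertia eigenvalues differ between tools (some label the largest "I3" while
describing the moment along the long axis), the largest-eigenvalue variant
is computed alongside and the choice is a switch; the longest-axis
convention is the default because only it is minimal for straight filaments
and reproduces the closed forms above. Proximity statistics use only
filaments longer than 1 µm with zero organelle-overlap voxels, and
proximity bins are half-open, (0, 100], (100, 200], … nm, excluding exact
overlap.

### Lattice spacing

Filament voxels are windowed into 50-nm slabs of distance-from-Z-disk
(half-open intervals tiled from the Z-disk outward, so "filament centers"
is the farthest populated slab), maximum-projected along the longitudinal
axis, and Fourier-transformed (no window function, zero-padding to the next
power of two; the padded size N is recorded for the frequency→distance map
\(d = N\,\mathrm{px}/r\)). Spectral intensity is averaged in integer radial
bins and the peak within the closed 30–60 nm band is the spacing estimate.
For an ideal hexagonal lattice of constant a this operational peak is the
d₁₀ row spacing \(a\sqrt{3}/2\); both the raw peak (the headline, matching
the operational definition) and the \(2/\sqrt{3}\)-converted center-to-center
value are reported, since X-ray diffraction work quotes either convention.
Confidence is the peak-to-median ratio in the band; below 1.5 the slab is
flagged. Magnitude (not power) spectra are the default; both are available.

### The geometric force model

Two scenarios for isometric force under CSA reduction \(f\):

* **Uniform**: the whole cross-section shrinks, filament number falls
  proportionally, per-filament force is unchanged — relative force is
  exactly \(1 - f\).
* **Heterogeneous (Z-disk only)**: a circular bundle keeps its filament
  count, but each filament is displaced inward at the Z-disk by
  \(\Delta(x) = x(1-\sqrt{1-f})R\) (x = normalized radius) along a
  circular-arc centerline tangent to the longitudinal axis at the A-band
  edge. The chord-tangent geometry gives an insertion tilt
  \(\theta = 2\arctan(\Delta/h)\), the axial force scales as
  \(\cos\theta\), and with uniform filament density the relative force is
  \(\int_0^1 2x\cos\theta(x)\,dx\) (composite Simpson, ≥10³ samples). For
  the circular arc this has the closed form
  \(F = (2/q^2)\ln(1+q^2) - 1\), \(q = \rho_g(1-\sqrt{1-f})\), which the
  tests verify by quadrature.

The bundle aspect ratio \(\rho_g = R/h\) is the single free parameter. It
defaults to 0.6, the value at which *one shared geometry* yields a 1.8%
force loss at f = 0.40 and 10.3% at f = 0.80 — a joint constraint, not two
fits — and small-f losses grow as \((\rho_g(1-\sqrt{1-f}))^2\). The model
deliberately excludes cross-bridge kinetics, length dependence and any
change in per-filament tension.

## The synthetic phantoms

Because real FIB-SEM muscle volumes run to 10⁸–10¹¹ voxels, validation runs
on constructive phantoms (`build_phantom()`) whose ground truth is known
exactly and recomputed by counting, not echoed from the parameters. A
phantom is a cylindrical myofibril of hexagonally packed filaments
(lattice constant 45 nm, filament radius 10 nm) with transverse Z-disks at
the sarcomere period (default 2.1 µm, a physiological resting length;
I-band 200 nm, Z-disk 100 nm), built periodic in complete sarcomeres so no
edge half-sheets arise. Filaments run Z-face to Z-face — the
fibrillar-muscle geometry, where thick filaments span nearly the whole
sarcomere — and near each Z-disk every filament is displaced toward the
axis in proportion to its radial position (outermost shell moves most, the
core stays straight), along the same circular-arc taper the force model
uses, over a taper length defaulting to \(W_I\) + Z-disk thickness. The
envelope CSA at the Z-disk is then \((1-\delta)\) times the A-band CSA;
negative \(\delta\) builds expanded-end sarcomeres for the
tubular-muscle-like ordering tests. Mitochondria are either Z-disk-wrapping
transverse rings ("grid") or longitudinal tubes ("parallel") whose radius
is chosen so both configurations carry the same mitochondrial volume; thin
SR/T tubes and spherical lipid droplets populate the organelle shell, and
all organelle labels are mutually disjoint by construction (priority
painting: Z-disk, filaments, mitochondria, SR/T, lipid).

The `phantom_preset()` pair couples the grid configuration with strong CSA
heterogeneity (δ = 0.35) and the parallel configuration with weak
heterogeneity (δ = 0.05), in the ranges measured for oxidative and
flight-type muscle respectively; the end-to-end sign test checks that the
pipeline recovers this constructed covariation, not that it discovers
biology.

Rendering (`render_grayscale()`) paints filaments as bright soft-edged
cylinders and organelles at distinct intensity bands with additive Gaussian
noise at a stated SNR (contrast / noise SD), deterministically per seed.
The phantoms emulate geometry only: no cristae, membrane contrast, EM
texture, milling artifacts or deformation. Passing tests therefore
demonstrate algorithmic correctness and parameter recovery on clean
geometry, and noise robustness only at the stated SNR levels — not
performance on real EM contrast.

## Numerical choices and degenerate inputs

* Exact squared EDT by the separable lower-envelope algorithm (in C++);
  distances are exact to double precision, and tests compare against an
  explicit brute-force minimum.
* Local thickness paints spheres largest-first, so the first writer at a
  voxel is the maximal sphere; complexity is acceptable for network masks
  at phantom scale.
* IsoData thresholding iterates intermeans to ±0.5 gray level;
  single-valued images are an error, empty slabs are an error.
* The period estimator refuses flat profiles and fewer than three Z-disks;
  the autocorrelation peak is searched beyond the first zero crossing.
* NCC of a constant volume is undefined: the field is returned all-zero
  with a `degenerate` flag, and tracing it yields an empty set.
* Single-voxel filaments have all-zero inertia eigenvalues and are flagged,
  not dropped.
* An empty mitochondrial mask leaves the Z-adjacent fraction `NA` with an
  `undefined` flag (content is 0); an empty Z-disk mask is an error.
* Seed ordering, tie-breaks, and orientation sampling are deterministic;
  the only RNG in the package is the rendering noise, seeded explicitly.

## Problem sizes used in the test suite

The suite validates on deliberately small instances: 64³ oracle volumes,
single-period bundles of 7–73 filaments at 5–10 nm voxels, and
three-sarcomere CSA phantoms of ~8M voxels, chosen so the full suite
exercises every stage end to end in minutes on one CPU. The tracing
benchmark (73 filaments, noiseless, δ = 0.2) uses an orientation sample
capped at 25° tilt and 12° spacing — appropriate when the fiber axis is
known, as it is for aligned muscle stacks — and a template whose outer
radius matches the rendered filament radius; the full-hemisphere 5° default
remains for data of unknown orientation.

## Known limitations

* TIFF stacks (plus JSON sidecar) are the on-disk format; derived distance
  fields are in-memory objects.
* The tracer follows the documented behavior of correlation-line tracing,
  not any particular proprietary implementation; on real, noisy EM at the
  sarcomere periphery its error characteristics will differ from the clean
  phantom benchmark.
* Whether the FFT lattice peak should be read as d₁₀ or center-to-center
  spacing is data-dependent; both are reported and the band-peak raw value
  is the headline.
* The force model's aspect ratio is a geometric idealization; reported
  losses are specific to the circular-arc taper family.
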