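# sarcomorph

Intrasarcomere morphometry for volume electron microscopy of striated
muscle.

Muscle cells pack contractile sarcomeres against mitochondria, sarcoplasmic
reticulum and lipid droplets, and the accommodation is geometric: sarcomere
cross-sectional area (CSA) can shrink at the Z-disks relative to the A-band,
myosin filaments near the periphery curve around adjacent organelles, and
the hexagonal myofilament lattice compresses or expands along the sarcomere.
`sarcomorph` implements the measurements needed to quantify this from
isotropic 3D voxel volumes (FIB-SEM scale data, consumed as label masks and
grayscale stacks), plus a geometric model of what Z-disk CSA reduction costs
in isometric force. It is aimed at microscopists and muscle physiologists
with segmented volume-EM data.

## What it computes

| Analysis | Functions |
| --- | --- |
| CSA heterogeneity per half sarcomere sheet, 100·(A−Z)/A | `sheet_csa()`, `estimate_period()`, `zdisk_sheet_areas()`, `aband_sheet_areas()` |
| Z-disk-adjacent mitochondrial fraction (threshold W_I + 200 nm) and content | `partition_mitochondria()`, `distance_field()` |
| Myosin filament tracing by hollow-cylinder correlation | `cylinder_correlation()`, `trace_lines()`, `rasterize_filaments()` |
| Deviation from linearity, I_long/V (nm²) | `filament_morphometry()`, `filament_inertia()`, `filter_filaments()` |
| Filament–organelle minimum distances | `min_distance_per_filament()`, `proximity_bin()` |
| Mitochondrial diameter (local thickness) | `local_thickness()` |
| Lattice spacing per 50-nm slab, 2D-FFT radial peak in 30–60 nm | `lattice_by_slab()`, `radial_fft_profile()`, `lattice_peak()` |
| Isometric force vs CSA reduction, two scenarios | `uniform_force()`, `heterogeneous_force()`, `force_curve()` |
| Synthetic validation phantoms with constructive ground truth | `phantom_spec()`, `build_phantom()`, `render_grayscale()`, `ground_truth()` |

The force model's heterogeneous scenario tapers a circular filament bundle
along a circular arc tangent at the A-band; a filament at normalized radius
x inserts at the Z-disk with tilt θ(x) = 2·atan(x·(1−√(1−f))·ρ_g) and the
relative force is ∫₀¹ 2x·cos θ(x) dx, with closed form
(2/q²)·ln(1+q²) − 1, q = ρ_g(1−√(1−f)). One aspect ratio ρ_g = 0.6 yields a
1.8% loss at 40% Z-disk CSA reduction and 10.3% at 80%.

## Worked example

Build a barrel-shaped phantom (Z-disk CSA reduced 40% below the A-band,
grid-configured mitochondria), then recover the construction end to end:

```r
library(sarcomorph)

spec <- phantom_spec(zdisk_csa_reduction = 0.4, mito_config = "grid")
ph   <- build_phantom(spec)

res <- sheet_csa(ph$labels$zdisk, ph$labels$aband)
res
#> <half_sheet_csa> 6 half sheets: 40.1 +/- 0.0 % CSA difference

part <- partition_mitochondria(ph$labels$mito, ph$labels$zdisk,
                               iband_width_nm = spec$iband_width_nm,
                               cell = ph$labels$cell)
part
#> <mito_partition> threshold 400 nm: 265016 / 265016 voxels Z-adjacent (fraction 1.000)
#>   mitochondrial content: 0.025 of cell volume

head(lattice_by_slab(ph$labels$filaments, zdisk = ph$labels$zdisk), 3)
#>   slab_center_nm spacing_nm spacing_c2c_nm confidence confident bin_width_nm n_voxels
#> 1             25   31.21951       36.04919   3.698230      TRUE    0.3807258    25368
#> 2             75   33.24675       38.39004   3.639986      TRUE    0.4317760    32214
#> 3            125   36.05634       41.63427   4.297920      TRUE    0.5078357    31062
```

The measured 40.1% heterogeneity matches the constructed 40%; every
mitochondrial voxel of the grid configuration lies within the W_I + 200 nm
Z-adjacency threshold; and the lattice spacing (d₁₀ row-spacing peak of the
slab-wise FFT; nominal a·√3/2 ≈ 39 nm here) compresses toward the Z-disk,
as built. The force model then prices that 40% reduction:

```r
100 * (1 - heterogeneous_force(0.40))   # Z-disk-only reduction
#> [1] 1.807039
100 * (1 - uniform_force(0.40))         # whole-sarcomere reduction
#> [1] 40
```

A thin CLI over the same functions lives at `inst/cli/sarcomorph.R`
(subcommands `phantom`, `force`, `csa`, `mito`, `lattice`, `trace`).

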