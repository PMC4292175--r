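---
title: "Detecting hexagonal close packing of RuBisCO in tomographic volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting hexagonal close packing of RuBisCO in tomographic volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomopack)
```

## The problem

The pyrenoid of *Chlamydomonas reinhardtii* concentrates most of the
cell's RuBisCO into a dense matrix. Whether the ~13 nm holoenzymes in
that matrix are disordered or crystalline is a quantitative question
about particle positions in a 3D density volume. `tomopack` implements
the full computational chain that answers it on cryo-electron
tomograms:

1. **Localization** (`match_template`, `extract_peaks`): rotation-free
   template matching with a 13.68 nm soft sphere, after low-pass
   filtering chosen by the Crowther criterion, followed by exhaustive
   greedy peak extraction under a hard-sphere exclusion radius.
2. **Subtomogram averaging** (`extract_subvolumes`,
   `iterative_average`): 45.6 nm boxes around each particle,
   iteratively aligned to a common reference and averaged without
   imposing symmetry.
3. **Neighborhood analysis** (`range_query`, `pooled_cloud`,
   `cluster_centers`): a 22.8 nm range query around each particle,
   neighbor offsets rotated by each particle's alignment rotation and
   pooled into one point cloud, then k-means with k = 13 to find the
   reference particle and its 12 nearest-neighbor positions.
4. **Lattice model fitting** (`registered_rmsd`, `scan_diameter`,
   `select_model`): hard-sphere HCP, CCP and BCC point sets simulated
   over a range of sphere diameters and compared to the cluster
   centers by rotationally registered nearest-correspondence RMSD.

A second, independent set of tools covers membrane morphometrics:
averaged line-scan densitometry of thylakoid stacks with
autocorrelation-based layer measurement (`average_line_profile`,
`measure_layers`), envelope-invagination counting statistics
(`invagination_stats`), and the center-spacing gap arithmetic
(`surface_gap`).

Everything is exercisable on synthetic data from the `latticegen`
functions (`generate_lattice_points`, `render_scene`,
`generate_membrane_stack`, `generate_invagination_fixture`), which
carry their ground truth with them.

## The lattice models

All three periodic models are built from touching hard spheres, so the
nearest-neighbor center distance equals the sphere diameter $d$:

* **HCP** — triangular layers stacked A-B-A with the ideal axial ratio
  $c/a = \sqrt{8/3}$; coordination number 12; the two out-of-plane
  neighbor triangles are eclipsed.
* **CCP (FCC)** — A-B-C stacking; coordination 12; the out-of-plane
  triangles are staggered by 60°. HCP and CCP share every first-shell
  distance, so telling them apart is purely a question of the
  *angular* arrangement, which is why the fit registers rotation
  before scoring.
* **BCC** — coordination 8 at $d$, with the conventional cell scaled
  so the body diagonal neighbors touch.

The second HCP/CCP shell sits at $\sqrt{2}\,d$; at $d \approx 15$ nm a
22.8 nm query therefore admits 6 second-shell points alongside the 12
first-shell ones. `nearest_k_filter` optionally trims each
neighborhood to its 12 nearest offsets for clean recovery tests, while
the default analysis keeps the full query.

`registered_rmsd` searches a 15° Euler grid, then refines by iterated
closest-correspondence assignment with an SVD (Kabsch) rotation solve
about the origin. Correspondences run from each data center to its
nearest model point, and model points may be reused; the mirrored
model point set is also scored and the better enantiomorph kept. The
diameter scan runs 10–20 nm at 0.05 nm with a 0.01 nm refinement pass
around the coarse minimum.

## Why pooling needs the alignment rotations

The two sublattices of HCP (A-layer and B-layer sites) see their
out-of-plane neighbor triangles in opposite orientations, related by a
60° turn about the stacking axis. Pooling raw neighborhood offsets
therefore smears the 6 out-of-plane clusters into 12 half-weight
spots even for a perfect single crystal. The per-particle rotations
recovered by subtomogram alignment map both sublattices into the
average's common frame and collapse those split clusters — this, not
noise suppression, is what makes the pooled cloud sharp, and it is the
property the package's polycrystal pooling test asserts.

## Synthetic data: what it emulates, what it does not

`render_scene` draws each particle as a soft-edged sphere
(cosine taper one voxel wide) and adds i.i.d. Gaussian noise. Two
edge conventions coexist deliberately: a *rendered* hard sphere of
diameter $d$ has its density supported strictly inside $d$, so that
jitter-free lattice scenes touch at exactly the stated spacing without
overlapping density, whereas the *matching template*'s nominal
diameter marks its half-maximum surface, which makes the template's
integral agree with the analytic sphere volume.
`tilt_geometry` optionally applies a ±60° binary missing-wedge mask
(2° increments by default) before the noise. Positional disorder is
isotropic Gaussian jitter, independent per particle — the minimal,
parameter-recoverable choice. The phantoms deliberately omit CTF,
dose-dependent damage, lamella geometry and realistic macromolecular
density: the localization target in the real analysis was itself a
featureless sphere, so soft spheres are the right level of detail for
validating the chain, but passing tests on them says nothing about,
e.g., CTF-induced localization bias in real data.

No noise or jitter statistics for the pyrenoid matrix are available,
so the generator defaults are field-plausible conventions rather than
calibrated values: jitter of 5 % of the lattice spacing, amplitude 1
spheres, and SNR 1 (noise SD equal to the sphere amplitude) for the
stress tests.

## Numerical choices

* **Coordinates**: right-handed, nm units, origin at the corner of the
  first voxel; voxel centers at $(i - \tfrac12)\,\mathrm{voxel}$ for
  1-based index $i$. Volumes are stored as plain arrays with an
  isotropic voxel size; MRC mode-2 I/O records the voxel size in the
  header cell fields.
* **Crowther cutoff**: $d_{res} = \pi D / N$ with $N = 180^\circ /
  \text{increment}$. At $D = 12$ nm and 2° increments this yields
  0.419 nm — finer than Nyquist at every voxel size used here — so the
  applied cutoff clamps to twice the voxel size and the
  canonical-parameter filter is in practice a pass-through. Synthetic white noise punishes
  this: the robustness tests instead band-limit at roughly a third of
  the lattice spacing, which is where a sphere-against-sphere matched
  filter keeps its contrast.
* **Local normalization**: the correlation map is normalized by the
  patch mean and SD under the template's spherical support mask, so
  scores are comparable across an uneven background; positions whose
  mask overlaps the volume boundary are set to −1 rather than padded.
* **Peak extraction**: greedy, with the exclusion radius defaulting to
  the template radius (6.84 nm) — hard spheres cannot overlap closer —
  and separable parabolic subvoxel refinement of each peak.
* **Alignment**: exhaustive ZYZ grids, coarse-to-fine (30°, 30°, 15°,
  7.5° by default); rotations are scored in batch by masked zero-shift
  correlation against rotated references (template matching has
  already centered the boxes to a voxel), then the integer-voxel
  translation is refined by FFT cross-correlation at the best
  rotation, bounded by `max_shift`. Ties resolve to the first grid
  point in lexicographic (z1, y, z2) order. Trilinear interpolation
  throughout; rotations about the box center. On strongly symmetric
  scenes the unaligned mean is a degenerate starting reference, so
  `initial_reference = "box"` seeds iteration 0 from a single member
  box instead. An optional `align_lowpass` band-limits the scoring
  (never the averages, which always come from the unfiltered boxes).
* **k-means**: Lloyd iterations on squared Euclidean distance with
  greedy D²-weighted (k-means++) seeding from a fixed RNG, 10
  restarts, centers reported sorted by distance from the origin.
* **Layer measurement**: the lateral repeat is the first
  autocorrelation peak beyond the main lobe (global maximum after the
  autocorrelation first turns negative), parabolically refined; layer
  widths come from half-maximum crossings between each membrane
  trough and its adjacent plateaus, so one repeat's widths sum to the
  repeat by construction. Intervals touching the profile ends are
  excluded, and intervals between membranes are classed lumen/gap by
  relative brightness.

## Problem sizes and the pipeline recipe

The package's end-to-end validation renders jittered HCP scenes of
roughly 450–700 particles in a 120 × 120 × 80 nm box at a 1.9 nm voxel
size (45.6 nm boxes are then 24 voxels), with SNR 1 noise and jitter
of 5 % of the spacing. These sizes keep a full match → average →
cloud → fit round trip at a few minutes on one CPU while leaving
~100 usable interior references, enough for cluster-center standard
errors well below the 0.05 nm scan step.

The matching stage of that validation uses a template whose nominal
(half-maximum) diameter equals the rendered particles' half-maximum
diameter — the matched-filter condition under the two edge
conventions above — and scales its band-limit ($0.35\,d$) and
exclusion radius ($0.475\,d$) with the lattice spacing $d$ of the
scene under test, at a fixed score threshold of 0.22. The scalings
matter most at $d = 13$ nm, where the rendered spheres touch and
inter-particle contrast is weakest; the matched template holds
detection precision and recall above 0.95 even there. Recovered
diameters sit within two coarse scan steps of the generating values
across 13–17 nm under these conditions.

## Known limitations

* Alignment scoring ignores the missing wedge (no wedge-masked
  constrained correlation); acceptable for spherical particles and a
  spherical template, where wedge bias is second order.
* No gold-standard FSC (half-sets are split by index parity only, no
  masking or phase randomization), no classification into multiple
  averages, and no fitting of defective or partial lattices.
* Translation search is integer-voxel; subvoxel positions enter only
  through template-matching peak refinement.
* The invagination module consumes annotated records (size,
  envelope width, tip distance); membrane segmentation itself is out
  of scope.
* The `RANDOM` scene generator is a sequential hard-sphere packing,
  adequate as a disordered control but not a statistically uniform
  dense packing.
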