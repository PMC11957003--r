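---
title: "Generating voxel-wise training labels from cryo-EM map/model pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating voxel-wise training labels from cryo-EM map/model pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryolabel)
```

## The problem

Experimental cryo-EM density maps carry noise from the ice matrix, from the
quantum statistics of electron detection, and from the recording chain.
Supervised models that denoise or enhance such maps need, for each
experimental volume, a clean voxel-aligned target. `cryolabel` builds those
targets from the deposited atomic model: an idealized density simulated from
the coordinates, cropped to the structure's neighbourhood, plus two
categorical views of the same geometry. The package also quantifies how much
cleaner the targets are than the maps they accompany, using unmasked Fourier
Shell Correlation (FSC).

## The grid model

Everything operates on a `voxel_grid`: a 3-D array indexed `(i, j, k) ≡
(z, y, x)` with a per-axis voxel size and a physical origin in Å. The center
of voxel `(i, j, k)` (0-based) sits at `origin + (i·vz, j·vy, k·vx)`, and
all distance computations in the package refer to voxel **centers**. MRC
files whose headers permute the storage axes are canonicalized on read; the
origin is taken from the header's `ORIGIN` record when any component is
nonzero and otherwise from the `N*START` offsets times the voxel size,
which is the dominant convention among EMDB depositions. Only orthogonal
cells are supported — single-particle maps satisfy this.

Continuous coordinates map to indices by the floor convention

```
i = floor((z − oz)/vz),  j = floor((y − oy)/vy),  k = floor((x − ox)/vx)
```

so an atom at `x = 10.4` on a unit grid with zero origin lands in `k = 10`.
A nearest-integer alternative is available (`coord_to_voxel(...,
rounding = "nearest")`) but floor is the default cell-index convention
throughout.

## Standardization

Deposited maps vary in voxel size (roughly 0.7–1.6 Å), so every map is
resampled to a 1 Å isotropic grid before label generation. `resample()` uses
trilinear interpolation at the output voxel centers, preserves the physical
origin (so map/model alignment is untouched), sizes the output as
`floor(extent/target) + 1` samples per axis with `extent = (n−1)·voxel`, and
treats points outside the input support as 0 (solvent background). Trilinear
interpolation was chosen over Fourier-space resizing because it is local,
deterministic, bounded by the input's value range, and exact on affine
fields — all properties the test suite exploits directly. No density-value
normalization or sharpening is applied: value-range heterogeneity between
depositions is left to downstream consumers.

## Simulated density

`simulate_density()` implements real-space Gaussian convolution: each atom
contributes `a · G_σ(‖r − r_atom‖)` with `G_σ` a unit-integral isotropic
Gaussian evaluated at voxel centers and truncated at `cutoff_sigmas · σ`
(default 4σ; contributions are stamped per atom inside the cutoff sphere,
so no FFT is needed at typical map sizes). Parameters:

* `resolution` (Å) — the nominal resolution; in a full pipeline this is the
  map's reported resolution from the manifest, so simulation parameters
  match their experimental counterparts.
* `kernel_sigma_factor` — defaults to `1/(2√(2 ln 2)) ≈ 0.4247`, i.e. the
  kernel FWHM equals the nominal resolution. Real-space convolution tools
  differ in this constant; it is exposed precisely because no single value
  is canonical.
* `amplitude_mode` — `"unit"` by default (labels are consumed after per-map
  normalization by learners, so per-element weighting adds little);
  `"mass"` weights atoms by atomic mass for closer fidelity to
  mass-weighted convolution tools.
* `cutoff_sigmas` — 4 by default; the spherical truncation loses ~1e-3 of
  the kernel mass at 4σ and ~1e-4 at 5σ.

A warning is raised when σ falls below half the voxel size (aliasing) and
when no atom lands inside the target box.

## The three label volumes

`generate_labels()` simulates density on the experimental map's exact grid
and derives three aligned volumes. The labels are a function of the map's
*geometry* only — its density values are never read — which the tests check
by regenerating labels under different noise seeds.

1. **Regression** — the simulated density wherever the voxel center lies
   within 6 Å (inclusive, Euclidean, center-to-coordinate) of any atom;
   exactly 0 elsewhere. The 6 Å neighbourhood reflects the spatial extent
   of density around an atom in high-resolution maps and softens the
   precision loss of snapping continuous coordinates onto the grid.
2. **Classification** — `{0, 1, 2}`: atom voxels (via the floor
   conversion) are 1, the remaining neighbourhood is 2, background is 0;
   1 beats 2 regardless of atom order.
3. **Atom type** — `{0..5}`: only the voxel holding each atom is labelled,
   because the chemical identity of surrounding voxels is ambiguous.
   Classes: Cα (1), Cβ (2), carbonyl carbon (3), oxygen (4), nitrogen (5).
   The carbon classes additionally require the element to be carbon and the
   residue to be a standard amino acid — a calcium ion named "CA" is class
   0 — while classes 4 and 5 apply to every O/N atom, backbone or side
   chain, in any residue (restricting them would silently drop side-chain
   labels). When two atoms land in one voxel the later atom in file order
   wins; collisions are reported. Atoms whose indices fall outside the grid
   are skipped.

All heavy atoms of all chains participate in the regression and
classification masks, including ligands and nucleic acids; waters are
excluded, hydrogens are dropped at parse time, and only the first altloc
conformer is kept. Biological-assembly expansion is not performed — supply
the assembly file directly so the model fully occupies the map.

`extract_subcubes()` tiles any volume into 64³ patches (edge and stride
configurable, zero-padded at the boundary, offsets recorded) for
memory-efficient patch training, and `split_by_resolution()` stratifies a
manifest into train/validation/test within resolution bins using a seeded
shuffle with largest-remainder apportionment.

## FSC validation

`fsc_curve()` computes unmasked FSC between two volumes of identical
geometry: Fourier voxels are binned into spherical shells one
reciprocal-grid step wide (`1/(N·voxel)` on a cubic grid; on anisotropic
boxes shells are defined on the physical frequency magnitude with the
finest reciprocal step across axes), the DC term is excluded, and shells
run up to Nyquist (`1/(2·max voxel)`). `resolution_at_threshold()` finds
the first crossing by linear interpolation between adjacent shells; if the
first shell is already below threshold the first shell's frequency is used,
and if the curve never crosses, the estimate is the Nyquist resolution with
`crossed = FALSE`. No masking is applied anywhere.

`map_model_fsc()` simulates the model map with this package's Gaussian
kernel rather than electron scattering factors, so agreement with
scattering-factor implementations is approximate (about ±0.3 Å on
map-model resolutions in our experience); the thresholds 0.143 and 0.5 are
the field's standard map-resolution and high-confidence criteria.

## The synthetic fixture generator

`make_fixture_bundle()` produces a fully deterministic end-to-end input: an
idealized poly-alanine α-helix (rise 1.5 Å, twist 100°, CA radius 2.3 Å;
N, C, O, CB at fixed offsets in the local helical frame — testability, not
chemical realism, is the goal), a clean simulated map on a bounding box
padded by `box_pad`, and a noisy variant with seeded additive Gaussian
white noise. Defaults were chosen once to describe a mid-resolution
single-particle scenario: resolution 3.0 Å (the midpoint of the 1–4 Å
high-resolution regime), 1.0 Å voxels, 8 Å padding, ten residues, and
`noise_sigma = 0.02` density units — a moderate signal-to-noise ratio
against the ~0.03 peak a single atom produces at 3 Å.

What the fixtures do *not* emulate matters for interpreting green tests:
real maps carry structured noise (ice, carbon film, conformational
variability), B-factor variation, CTF effects and solvent flattening, none
of which white Gaussian noise reproduces. Passing fixture tests therefore
demonstrates the correctness and determinism of the label-generation
machinery and the qualitative noise-response of the FSC estimator, not
performance on experimental depositions.

```{r example}
bundle <- make_fixture_bundle(fixture_spec(n_residues = 10, seed = 1))
bundle$labels
curve <- fsc_curve(bundle$standardized, bundle$labels$simulated)
resolution_at_threshold(curve, 0.5)
```

## Numerical choices and degenerate inputs

* Boundary semantics: the 6 Å radius is inclusive (`≤`), with a 1e-9
  slack so exact integer distances on unit grids are classified stably.
* Geometry comparisons use a 1e-4 Å tolerance, generous enough for
  float32 MRC metadata round trips.
* MRC files are written mode 2 (float32); round trips are exact up to
  float32 rounding of the density values. Integer label maps are stored as
  mode 2 with integral values.
* Degenerate inputs error early and by name: axes of length 1 cannot be
  resampled, all-zero volumes have undefined FSC, empty structures cannot
  be simulated, duplicate manifest `map_id`s are rejected.
* Curation keeps, among maps sharing a model, the one with the best
  (smallest) reported resolution, ties broken lexicographically by map id;
  resolution bounds are inclusive at both ends.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic
fixtures: helices of 2–20 residues on grids up to ~70³ voxels, oracle
cross-checks on 16³ (FSC, direct dense DFT) and ≤32³ (dilation,
brute-force distance enumeration) grids, and a 20-fixture randomized
invariant sweep. These sizes were chosen so the whole battery completes in
well under a minute while still exercising every code path at
non-trivial scale; the machinery itself is size-agnostic and handles
deposited maps of several hundred voxels per edge.

## Known limitations

* The Gaussian kernel ignores electron scattering form factors, per-atom
  B-factors and solvent contributions; map-model resolutions are therefore
  comparable between maps processed identically, but not numerically
  interchangeable with scattering-factor tools.
* No half-map FSC, noise-substitution correction, masked FSC or
  local-resolution estimation.
* No symmetry expansion; the user supplies biological assemblies.
* Non-orthogonal (crystallographic) cells are rejected.
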