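---
title: "Determining the architecture of bacterial microtubules by simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Determining the architecture of bacterial microtubules by simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmtsim)
```

## The problem

BtubA/B heterodimers polymerize into thin tubes inside *Prosthecobacter*
cells. Cryo-electron tomography can show these tubes in situ, but at
tomographic resolution a 7–8 nm tube is a pair of blurry arcs: the
protofilament number, lattice type and helical start cannot be read off
directly. The argument for a five-protofilament, one-start helical
architecture therefore rests on model-based reasoning — build candidate
lattices, simulate how each would look under the microscope's known
distortions, and ask which candidate reproduces the measurements. This
package implements each link of that argument as testable code.

## Lattice model and its assumptions

A tube lattice is parameterized by the protofilament count $N$, the
lateral spacing $s$ between adjacent protofilament axes, the axial stagger
$a$ between neighbours, the monomer rise $m$ (half the 8.8 nm heterodimer
repeat), the protofilament thickness, and the lateral packing rule (A- or
B-lattice). Protofilament axes are placed on the circle whose chord
between neighbours is exactly $s$, giving circumradius
$r = s / (2\sin(\pi/N))$. Tube diameter in this package always means
$2r$ — twice the circumradius of the protofilament *axes* — because that
convention reproduces the 7.8 and 9.2 nm five- and six-protofilament
model diameters; the outer envelope ($2r$ + one protofilament thickness)
is reported separately. Two conventions the source arithmetic leaves open
are settled here and documented rather than guessed silently:

- `lateral_spacing_nm` is the in-plane chord. The 3-D center distance
  between laterally adjacent subunits is then
  $\sqrt{s^2 + a^2} \approx 4.68$ nm at the defaults.
- For four protofilaments the chord formula gives 6.5 nm, 0.2 nm below
  the 6.7 nm sometimes quoted; how that model was measured is unstated,
  so this package reports the formula value and flags the discrepancy.

Protofilaments are straight and parallel to the tube axis; the
`twist_deg_per_nm` argument of `build_tube()` adds an artificial
supertwist used only as a negative control for the straightness analysis.

Subunit identities alternate A, B along each protofilament. In a
B-lattice, lateral neighbours at matching axial levels share an identity,
so the alternation phase is common to all protofilaments; in an A-lattice
the phase flips between neighbours. Seams are not asserted from theory:
`assign_subunit_types()` enumerates every lateral contact by brute force
(nearest axial partner in the adjacent protofilament) and records the
contacts that violate the lattice rule. For the one-start five-pf tube
this enumeration yields exactly one seam in the B-lattice and none in the
A-lattice, matching the classical "B-lattice with seam / A-lattice
without seam" dichotomy; the same enumeration is the oracle for the test
suite's N = 3..8 property.

```{r lattice}
spec <- tube_lattice_spec()
derive_lattice_report(spec)
```

## What the synthetic-data generator emulates

`rasterize()` turns a model into a density map with one kernel per
monomer. Two kernels are available:

- `"gaussian"` (default): an isotropic Gaussian, $\sigma$ = 1.2 nm,
  truncated at $3\sigma$ and normalized to unit mass on the grid. It is
  the cheap, smooth stand-in used for diffraction and classification
  work, where the positions of subunits matter more than the wall
  profile.
- `"sphere"`: a solid ball of the protofilament radius (2.0 nm, from the
  4 nm protofilament thickness) with a half-voxel soft edge. At 4.6 nm
  spacing the balls overlap, so the tube wall becomes a continuous shell,
  as it is in an atomic-density model. This representation is used for
  the missing-wedge morphology experiment, because how strongly the tube
  tops and bottoms fade depends on wall continuity: isolated isotropic
  blobs lose amplitude almost independently of where they sit, whereas a
  continuous wall loses its radial structure anisotropically.

An atomic mode (`write_model_pdb(..., template = )`) can replicate a
user-supplied heterodimer coordinate file instead, aligning its principal
axis to the tube axis before replication; the package builds and tests
fully without any such file.

The imaging chain follows the published simulation protocol: project the
map over −60..+60° in 1° increments about the tilt axis, multiply each
image in reciprocal space by a 10 µm underfocus CTF, optionally resample
to coarser pixels by Fourier cropping, and reconstruct by ramp-filtered
weighted backprojection. Working voxel sizes are package choices made for
desk-scale runtime: 0.3–0.5 nm for classification and diffraction, and
for the wedge-morphology preset a 0.24 nm map resampled by a factor of 4
to the 0.96 nm display pixel (a scaled stand-in for the published
0.096 → 0.96 nm protocol, preserving its band limit). CTF constants not
stated anywhere — spherical aberration 2.0 mm, amplitude contrast 0.07,
no envelope — are explicit, configurable guesses. Noise, when requested,
is additive white Gaussian per image at a stated variance SNR; it is the
only stochastic component, controlled by a single seed.

What the generator does **not** emulate: multislice scattering, detector
MTF, dose weighting, fiducial alignment errors, cytoplasmic crowding, or
membrane context. Passing tests therefore show that the *geometric and
Fourier-optical* logic of the argument is sound, not that the classifier
would work on arbitrarily poor experimental data.

## Reconstruction and the wedge oracle

`weighted_backprojection()` ramp-filters along the tilt-perpendicular
axis on a 2× zero-padded grid (avoiding circular wrap) with a Hann
rolloff ending at 0.9 Nyquist to suppress ringing; reconstruction
thickness defaults to the image width. Because reconstruction parameters
of the original workflow are not printed anywhere, these are package
decisions. A fast oracle, `apply_missing_wedge()`, zeroes the Fourier
coefficients a ±60° tilt series never samples (directions within 30° of
the beam axis, in the plane perpendicular to the tilt axis); the test
suite requires wedge-masked volumes and actual backprojections of the
same phantom to correlate above 0.9, which ties the shortcut to the full
path. Morphometry unit tests ride the fast path; acceptance-level
classification uses full projection + backprojection.

## Diffraction analysis

Power spectra are computed on mean-subtracted, 4× zero-padded images so
that sub-pixel peak interpolation near the meridian is stable (the J1
first maximum of a 5.9 nm outer-radius tube sits at only 0.05 nm⁻¹).
Layer-line power is summed off-meridian (excluding ±2 pixels) per axial
frequency; `estimate_repeat()` takes the strongest row in the 0.1–0.33
nm⁻¹ band, requires it to exceed 3× the median band power, and refines it
parabolically, reporting a half-frequency-pixel uncertainty. The helical
selection rule `allowed_bessel_orders()` is the exact congruence
$n \equiv q s \pmod N$; spot positions are predicted at the first Bessel
maxima over the **outer** radius (ring radius + half a protofilament
thickness), the convention used for annotating measured transforms, which
marks the meridian-ward border of each spot — measured maxima are
expected at or slightly inside the predicted positions, and the test
suite asserts the bracketing rather than exact coincidence. Spot
intensities are out of scope; only positions and the left/right power
asymmetry of each layer line are reported.

## The asymmetry statistic

No formal definition of "left-right asymmetry" survives in the source
material, so this package defines one and motivates it. A cross-section
perpendicular to the tube axis is extracted by trilinear interpolation
and averaged over a slab; intensities are clamped at zero (reconstruction
ringing would otherwise leak sign changes into a ratio statistic); a wall
annulus of radii 0.5–1.5× the expected ring radius selects the tube wall.
The score is the mirror-difference ratio of the *beam-integrated* wall
profile $W(l) = \sum_b I(l, b)$:

$$A = \frac{\sum_l |W(l) - W(-l)|}{\sum_l (W(l) + W(-l))} \in [0, 1].$$

Beam integration is what makes the statistic discriminate protofilament
parity: an even-$N$ tube is centro-symmetric, so its wedge-distorted
section obeys $I(-l, b) = I(l, -b)$ and $W$ is exactly mirror-symmetric
at every rotation about the tube axis, while an odd-$N$ tube (a single
wall protofilament facing a two-protofilament wall) is not. The naive
pointwise mirror difference $\sum |I(l,b) - I(-l,b)| / \sum (I + I)$
does *not* discriminate — the two side arcs of an even tube sit at
opposite beam offsets, so its pointwise residual is large (~0.37 in the
default simulations) for every candidate. It remains available as
`metric = "pointwise"` for comparison. A signed variant (left minus
right integrated wall density) supports the straightness profile.

The classification threshold is calibrated, not fixed: candidates are
flagged asymmetric when their maximum score over the rotation sweep
exceeds 3× the largest even-count score (0.05 as a fallback when no even
candidate is present). The calibration is deterministic because the
simulations are noise-free. At the defaults the even-count maxima are
≈ 0.02 and the five-protofilament maximum ≈ 0.31.

`measure_diameter()` reads the distance between the two outer wall peaks
of the lateral profile through the section center. Note a geometric
caveat the tests encode explicitly: for odd $N$ no rotation places
protofilaments at both $+r$ and $-r$, so the wall-peak separation is
bounded by $(1 + \cos(\pi/5))\,r \approx 1.81 r \approx 7.1$ nm for the
five-protofilament tube — systematically below the 7.8 nm ring diameter,
the same direction of bias as the ~7.6 nm measured on real tomograms.
The unit tests therefore check the measurement against a one-dimensional
Gaussian-mixture oracle computed directly from the ring geometry, and
against a continuous annulus phantom where the peak separation does equal
the true diameter.

## Subtomogram averaging

Subvolumes are extracted at uniform arc-length positions along a modelled
axis (4.5/9 nm presets for overlapping boxes, 21/42 nm for unique ones)
and aligned to an iteratively updated reference. The rotational search is
restricted to the axis-rotation degree of freedom within ±15° — the same
constraint that makes the straightness argument work: were the
protofilaments supertwisted, a ±15° search could not keep the wall
asymmetry in register along the tube, and averaging would wash it out.
Correlations are computed under a soft spherical mask (0.45× box) and
only over wedge-sampled Fourier coefficients, so the missing wedge cannot
dominate the alignment. Translations are integer-voxel, found on the
masked correlation map within a stated limit. Degenerate settings
(rotation limit 0, translation limit 0) reduce the procedure to plain
averaging, which the noise-reduction test ($\sqrt{n}$ background
suppression at $n = 25$) uses directly.

## Numerical choices and degenerate inputs

- Rotations and projections use bilinear interpolation; mass is conserved
  through rasterize → project to better than 1%.
- Fourier cropping keeps an odd, DC-centered frequency block, dropping
  the unpaired Nyquist row, so crop→pad is exactly idempotent on
  band-limited input and the output stays real.
- Start numbers round half away from zero; an exactly half-integer
  closure climb warns.
- `n_pf = 1` is a legal degenerate lattice: ring radius 0, no lateral
  contacts, no seams; `ring_radius()` itself refuses `n_pf < 2`.
- Blank or single-peak sections return `"unresolved"` from
  `measure_diameter()` instead of a number; spectra without a
  supra-threshold layer line return `"no layer line"`.
- Problem sizes in tests and presets (tube lengths 17.6–70.4 nm, voxels
  0.24–0.8 nm, 25–50 subvolumes) are the package's desk-scale choices;
  all physical parameters retain their published values.

## Known limitations

- The A/B-lattice question is not addressable from spectra here (and was
  not resolved in the source work); lattice type only affects seam
  bookkeeping and PDB B-factors.
- Relative spot intensities (e.g. why J4/J6 pairs are weak) are not
  modelled; only positions.
- The classifier's observed-section mode matches on two summary features
  (asymmetry, diameter); it is a demonstration, not a calibrated
  estimator for experimental tomograms.
- Tube detection/segmentation in crowded cellular volumes is out of
  scope; axes are supplied as models.
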