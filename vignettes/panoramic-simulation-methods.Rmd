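---
title: "Simulating spectral panoramic dental radiographs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating spectral panoramic dental radiographs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panospec)
```

## The problem

Panoramic dental radiography sweeps a narrow X-ray beam around the dental
arch to produce a single curved-layer projection of the jaws. Photon counting
detectors would let such a system separate the beam into energy bins and
compute *material-decomposed* and *virtual monoenergetic* images, but no
commercial panoramic system does this yet. `panospec` simulates what such a
system would produce, starting from an ordinary (non-spectral) head CT volume
or from a synthetic labeled head phantom:

* **PETI** — panoramic equivalent thickness images: for each detector pixel,
  the projected thickness in mm of one basis material (bone or soft tissue)
  along its ray;
* **PAN** — a synthetic conventional polychromatic panoramic radiograph;
* **PVMI** — panoramic virtual monoenergetic images at arbitrary energies.

The pipeline is: segment the volume into air / soft tissue / bone, fit the
dental arch and build the panoramic source–detector sweep, forward project
each material to its PETI, and synthesize the spectral images from the two
PETIs. A reader-study module aggregates ordinal image-quality scores and
compares each modality against the conventional PAN baseline with the
Wilcoxon signed-rank test.

## Coordinates and data model

One fixed convention is shared by all modules: right-handed patient-like
axes with x = left–right, y = posterior–anterior, z = inferior–superior;
world coordinates in mm at voxel centers; three integer labels
(`air = 0`, `soft = 1`, `bone = 2`). Teeth are labeled *bone*: the forward
model has exactly two attenuating basis materials, and enamel/dentin are
treated as part of the bone compartment.

## The synthetic head phantom

Real head CT data cannot be redistributed, so the package ships a parametric
phantom (`phantom_params()`, `generate_head_phantom()`) that emulates the
structure classes the pipeline needs, not the anatomy of any population:

* an ellipsoidal soft-tissue head (default semi-axes 70 × 80 × 55 mm in a
  160 × 160 × 120 grid at 1 mm isotropic — desk-scale runtime was the
  criterion for the grid);
* a U-shaped dental arch: a symmetric quartic `y(x) = a0 + a2 x² + a4 x⁴`
  (defaults `a0 = 40` mm, `a2 = -0.020` mm⁻¹, `a4 = -1e-6` mm⁻³ over
  |x| ≤ 42 mm), swept vertically as mandibular and maxillary bone walls
  of half-width 4 mm;
* 14 teeth placed at equal arc-length intervals along the arch (cylinders,
  radius 3 mm, height 12 mm, HU 1800) each with a soft-tissue root canal
  (radius 0.8 mm);
* a retro-arch air slab (6 mm thick, 10 mm behind the arch midline)
  mimicking the pharynx / tongue–palate air gap that causes the classic
  dark-shadow positioning artefact.

Default HU values are air −1000, soft 40, bone 1200, tooth 1800 — widely
separated so that threshold segmentation is *exact* on noise-free phantoms,
which turns the generator into a ground-truth oracle for the segmentation
and projection tests. Optional Gaussian HU jitter (seeded) makes the volumes
less idealized when wanted; the default is 0.

What the phantom deliberately does **not** emulate: realistic anatomy
(sinuses, vertebrae, skull base), CT reconstruction artifacts, partial
volume effects, metal restorations. Tests passing on the phantom therefore
demonstrate the correctness of the *geometry, projection and spectral
arithmetic*, not robustness to clinical image imperfections.

The construction is solid-by-solid (ellipsoid, dilated curve, cylinders,
curve-following slab), so the expected voxel count of every label has a
closed form (`phantom_analytic_volumes()`); the voxelization is verified
against it to within 3 % in the tests.

## Segmentation

`segment_volume()` applies a plain HU threshold for air (default −400 HU)
and classifies the remaining voxels by a blended score
`(1 − w)·HU + w·gain·S`, where `S` is a multi-scale Hessian sheetness
response and `w` the blend weight. With `w = 0` (the default) this is pure
HU thresholding (bone at ≥ 300).

The bone-enhancement filter (`bone_enhancement_filter()`) is the standard
sheetness measure for bright plate-like structures: at each scale σ the
volume is convolved with Gaussian-derivative kernels, the scale-normalized
Hessian (γ = 2) is assembled, eigenvalues are sorted by magnitude
|λ1| ≤ |λ2| ≤ |λ3|, and the response combines a sheet ratio |λ2|/|λ3|,
a blob ratio |2|λ3| − |λ2| − |λ1||/|λ3| and the Frobenius norm as a
structure-strength cutoff, for λ3 < 0 only. The strength cutoff is
data-driven (a fraction of the volume's maximum Hessian norm), so a
constant volume yields an identically zero response. The design keeps the
filter behind a switch because pure thresholding is exact on the phantom;
the filter is there for real CT data, where cortical plates are thin and
noisy.

## Dental arch and panoramic geometry

`fit_dental_arch()` detects the occlusal plane as the z slab with maximum
bone cross-section (optionally windowed or fixed), collapses the slab's
bone occupancy along z, and estimates the arch midline per x column as the
midpoint of the bone extent in y before least-squares fitting the symmetric
quartic. Fitting the *midline* rather than the anterior-most bone edge
removes the half-wall-thickness bias an edge fit would inherit; on the
default phantom the fit lands within ~0.6 mm RMS of the generating curve
(the tests require ≤ 2 mm over the tooth-bearing span). The fitted curve is
resampled to equal arc length with outward (anterior-pointing) unit
normals.

`build_trajectory()` places, at each of C equally spaced arc-length
stations, the source `source_to_arch` mm behind the arch point along the
inward normal and the detector column base `arch_to_detector` mm in front;
rows form a vertical fan from the source through R detector pixels centered
on the occlusal plane (defaults C = 700, R = 500, 400 mm / 100 mm,
vertical field 100 mm). The central ray of every column is thus normal to
the arch — the focal layer is exactly the arch curve. A real
orthopantomograph moves its rotation center along a guide path during the
sweep; that vendor kinematics is intentionally not modeled. The normal-ray
sweep produces the same projected-thickness semantics and keeps every
geometric property analytically checkable (circular arches yield rays
through the center; vertical magnification follows similar triangles).

## Forward projection

`project_all_materials()` computes exact line integrals of the label
indicator functions by Siddon-style voxel-boundary traversal (Rcpp). For
piecewise-constant labels this is *exact*, so the tests can assert chord
lengths to 10⁻⁶ mm and path-length conservation
(t_air + t_soft + t_bone = bounding-box chord) to solver precision; an
interpolating sampler would make all of these approximate. Rays that miss
the grid contribute 0 mm (not missing values), matching the projected-
thickness semantics. Rays are independent; results do not depend on
evaluation order.

## Spectral model

* **Attenuation tables.** Embedded ICRU-44-style mass-attenuation values at
  the standard 20–150 keV node energies for soft tissue (ρ = 1.06 g/cm³)
  and cortical bone (ρ = 1.92 g/cm³), plus elemental aluminium for
  filtration, interpolated log–log between nodes (`attenuation_mu()`,
  exact at nodes).
* **Tube spectrum.** `tungsten_spectrum()` uses the Kramers bremsstrahlung
  shape ∝ (kVp − E)/E filtered by a configurable aluminium thickness
  (default 120 kVp, 2.5 mm Al, 64 bins from 20 keV). Characteristic
  tungsten lines and measured spectra are not modeled, but
  `read_spectrum_csv()` / `xray_spectrum()` accept any tabulated spectrum.
* **PAN.** `synthesize_pan()` evaluates the polychromatic Beer–Lambert sum
  `N = N0 Σ w_j exp(−μ_b(E_j) t_b − μ_s(E_j) t_s)` per pixel. N0 defaults
  to 10⁵ expected counts; **no Poisson noise, scatter or detector response
  is simulated** — the model is an ideal detector, and counts are
  expectations. The default display is the attenuation view −ln(N/N0)
  (dense structures bright); raw counts are always retained.
* **PVMI.** `synthesize_pvmi()` computes `μ_b(E0) t_b + μ_s(E0) t_s`; 40
  and 60 keV are the conventional evaluation energies.
* **Decomposition.** `recover_thickness()` solves the per-pixel 2 × 2
  system exactly, and round-trips the forward model to ~10⁻¹⁴ mm; it
  errors on equal energies rather than returning amplified noise.

Beam hardening appears with the right sign automatically: the effective
attenuation per mm of a polychromatic beam decreases with depth, and is
constant for a single-bin spectrum (a property test).

## Reader-study statistics

Scores are long-format records (reader, case, modality, criterion, score
1–5) over five modalities (PAN, PVMI40, PVMI60, PETI_BONE, PETI_COMBO) and
five criteria. `aggregate_scores()` reports per-reader means ± SD, the
across-reader average (unweighted mean of reader means — all readers rate
the same cases), and per-modality total points (sum of the per-reader means
over criteria; 75 maximum for 3 readers × 5 criteria).

`wilcoxon_signed_rank()` follows the classical zero-discard convention
(also the default of the major commercial statistics packages): zeros
dropped, mid-ranks for tied |d|, W = min(W⁺, W⁻). The two-sided p-value is
computed by *exact enumeration* of all 2ⁿ sign assignments of the observed
rank vector for n ≤ 15 (valid with mid-ranked ties), and otherwise by the
normal approximation with tie correction and continuity correction. All
differences zero is an explicit error ("no nonzero pairs"), never a silent
p = 1; `compare_modalities()` converts that error into an `untestable`
status per comparison. Two-sided testing at α = 0.05 throughout; no
multiplicity correction by default (a `p_adjust` switch exposes
Holm/Bonferroni), mirroring how such reader studies are conventionally
reported.

The bundled `reader_study_summary()` contains the per-reader means and SDs
of the original three-reader, 17-case evaluation. The raw per-case score
sheets were never published, so only the aggregation arithmetic — not the
signed-rank p-values — can be recomputed from it. For end-to-end testing of
the inference path, `simulate_score_table()` draws seeded baseline scores
and derives each modality by a clipped ordinal shift from the *same* draw,
preserving the paired design.

## Numerical choices and degenerate inputs

* Ray entry points are nudged by 10⁻⁹ of the clipped parameter range so
  rays starting exactly on voxel boundaries traverse deterministically.
* Arch-curve tangents use central differences with second-order one-sided
  stencils at the ends (first-order stencils visibly bias the end normals).
* A constant image in auto-windowing maps to mid-gray (window widened to 1).
* Degenerate single-bin spectra are legal and reduce the PAN to the
  monoenergetic model exactly.
* Float TIFF output is stored normalized with the scale factor in a JSON
  sidecar (32-bit TIFF payloads are defined on [0, 1]); round trip is good
  to ~10⁻⁷ relative.
* NIfTI stores spacing as 32-bit float (`pixdim`), so spacings like
  0.67 mm round-trip only to float precision.

## Problem sizes

The test suite runs the full pipeline on a 100 × 100 × 80 phantom with
reduced detector grids, and once on the default 160 × 160 × 120 phantom
with the full 700 × 500 sweep — a few seconds on one CPU. These sizes were
chosen as the smallest grids on which every structure class (arch walls,
teeth, canals, air gap) is still resolved by at least several voxels.

## Known limitations

* No noise, scatter, detector blur, focal-spot penumbra or energy-bin
  response — by design, the simulation isolates the geometry and spectral
  arithmetic.
* The panoramic trajectory is an idealized normal-ray sweep, not a vendor
  kinematic model; focal-trough depth blur is absent.
* The DICOM reader supports uncompressed little-endian single-frame CT
  series only, and the embedded attenuation nodes span 20–150 keV.
* The phantom is a structural stand-in; conclusions about clinical image
  quality require real CT inputs.
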