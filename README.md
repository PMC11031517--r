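# panospec

Simulation of spectral panoramic dental radiographs from head CT volumes.

Photon counting detectors can sort X-ray photons into energy bins, enabling
material-decomposed and virtual monoenergetic images — but panoramic dental
systems do not use them yet. `panospec` simulates, from an ordinary
(non-spectral) head CT volume or a built-in synthetic head phantom, the
image types such a system would produce:

* **PETI** — *panoramic equivalent thickness images*: per detector pixel,
  the projected thickness `t_m(x)` in mm of one basis material
  (m ∈ {bone, soft tissue}) along its ray;
* **PAN** — a synthetic conventional panoramic radiograph via the
  polychromatic Beer–Lambert law,
  `N(x) = N₀ Σ_j w_j exp(−μ_b(E_j) t_b(x) − μ_s(E_j) t_s(x))`,
  with a filtered tungsten (Kramers) tube spectrum `{E_j, w_j}`;
* **PVMI** — *panoramic virtual monoenergetic images* at any energy E₀,
  `A(x) = μ_b(E₀) t_b(x) + μ_s(E₀) t_s(x)`, plus the exact two-energy
  inverse recovering `(t_b, t_s)` from two PVMIs.

The pipeline: threshold segmentation of the HU volume into air / soft /
bone (with an optional multi-scale Hessian sheetness bone-enhancement
filter), a quartic dental-arch fit, a panoramic source/detector sweep whose
central rays are normal to the arch, exact Siddon forward projection of
each material, and spectral synthesis. A reader-study module aggregates
ordinal 1–5 image-quality scores and compares each modality against the
conventional PAN baseline with a Wilcoxon signed-rank test (exact sign
enumeration for n ≤ 15, tie/continuity-corrected normal approximation
otherwise).

It is aimed at medical-physics and dental-imaging researchers who want a
reproducible, fully synthetic testbed for spectral panoramic imaging
methods — no patient data required.

## Worked example

```r
library(panospec)

# synthetic labeled head phantom: ellipsoidal head, quartic dental arch,
# 14 teeth with root canals, retro-arch air gap
ph <- generate_head_phantom(phantom_params())

# segment -> fit arch -> build sweep -> project -> synthesize
sim <- simulate_panoramic(ph$hu)

sim$arch
#> arch curve: 200 points, arc length 126.8 mm, z = -15.5 mm
sim$geometry
#> panoramic geometry: 700 cols x 500 rows, source-arch 400 mm, arch-detector 100 mm, pitch 0.2 mm
sim$peti$bone
#> PETI [bone]: 500 x 700 px, thickness 0.00-9.22 mm
sim$pan
#> PAN: 500 x 700 px, counts 1.52e+03-5.47e+04 (N0 = 100000)
sim$pvmi$pvmi_40
#> PVMI @ 40 keV: 500 x 700 px, A in [0.605, 5.35]

write_simulation(sim, "out/", png = TRUE)  # pan, pvmi_40, pvmi_60, peti_bone, peti_soft
```

The arch fit recovered the occlusal plane at z = −15.5 mm (inside the
phantom's mandible) and a 126.8 mm arch; the bone PETI peaks at 9.2 mm of
bone along rays crossing both jaw walls, and the PAN's minimum of ~1.5 %
transmitted counts occurs where rays traverse the full head plus both
walls. Windowed 8-bit previews land next to the float TIFFs.

Reader-study statistics:

```r
res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 2, 3, 4, 5))
res
#> Wilcoxon signed-rank: W = 0, n = 5, p = 0.0625 (exact enumeration), median diff > 0

summ <- reader_study_summary()   # bundled per-reader means/SDs of the original study
across_reader_average(summ$mean[summ$modality == "PETI_BONE" &
                                summ$criterion == "bone_quality"])
#> [1] 4.86
```

A command-line front end for the same pipeline lives at
`system.file("cli", "panospec.R", package = "panospec")` with subcommands
`phantom`, `segment`, `simulate` and `readerstats`.

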