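# saxsgpa — Guinier peak analysis for SAXS quality control

Small-angle X-ray scattering (SAXS) characterizes biological
macromolecules in solution through two headline parameters: the radius of
gyration *R*g and the forward scattering *I*(0), both usually obtained
from the Guinier approximation *I*(*q*) ≈ *I*(0) exp(−*q*²*R*g²/3) at
*qR*g ≲ 1.3.  Whether the data actually *contain* a Guinier region — and
whether deposited (*R*g, *I*(0)) values are consistent with the measured
curve — is a recurring QC problem for beamline pipelines and scattering
databases.

`saxsgpa` implements Guinier **peak** analysis: multiplying the Guinier
approximation by *q* turns the monotone low-q region into a peak in the
*qI*(*q*) vs *q*² plot, with theoretical maximum at *q*²max = 1.5/*R*g²
(*q*max·*R*g ≃ 1.22).  In dimensionless form — *qR*g·*I*(*q*)/*I*(0) vs
(*qR*g)² — every ideal scatterer peaks at

> (1.5, √1.5 · e^(−1/2)) = **(1.5, 0.7428)**,

so a displaced peak flags annotation errors, elongated scatterers, or
genuinely problematic low-q intensities.  The package provides:

* **saxs_io** — tolerant 2/3-column ASCII readers/writers for curves and
  *P*(*r*) files, JSON/CSV screening reports;
* **transforms** — windowed Guinier fitting, the GPA transform family,
  dimensionless GPA/Kratky plots, peak↔parameter algebra, sliding-window
  local-*R*g diagnostics;
* **peakfind** — model-free scale-space peak localization with a
  rank-product heuristic and polynomial/shape-aware smoothing;
* **pr_metrics** — real-space *R*g/*I*(0) moments, the elongation ratio
  (ER = area after the *P*(*r*) maximum / area before it), and
  *R*g-normalized unit-sum *P*′(*r*′) functions;
* **shape_cluster** — composite-angle distances between *P*′(*r*′)
  functions and hierarchical shape clustering;
* **qc_screen** — end-to-end screening with Hampel (3-MAD) outlier
  flagging against the theoretical peak and a four-way triage of flagged
  curves;
* **synth** — exact form-factor intensities for spheres, ellipsoids,
  cylinders and prisms, polydisperse populations, mixtures, a repulsion
  emulator, Monte Carlo / analytic *P*(*r*), and seeded noise — so the
  whole pipeline is testable without any external data.

## Worked example

Simulate a noisy solid sphere (radius 38.73 Å, so true *R*g = 30 Å),
fit it, locate its Guinier peak and validate the fit:

```r
library(saxsgpa)
spec <- shape_spec("sphere", radius = 38.73, i0 = 120)
q    <- seq(0.003, 0.08, length.out = 400)
crv  <- add_noise(synth_intensity(spec, q), 0.01, seed = 4)

(gf <- guinier_fit(crv))
#> <guinier_fit> Rg = 30.66 A, I(0) = 120.449, qRg in [0.092, 1.3], 205 pts, R2 = 0.995839

pk <- find_guinier_peak(gpa_transform(crv))
pk
#> <peak_result> index 185, x = 0.00148293, y_raw = 2.98679, y_smooth = 2.92462 (crit 7, rank prod 6.0)

peak_to_dimensionless(pk$x_refined, pk$y_refined,
                      annotation(gf$rg, gf$i0, "guinier"))
#> <dimensionless_peak> (x', y') = (1.4600, 0.7413); d = (-0.0400, -0.0015) from (1.5, 0.7428)

estimate_from_peak(pk$x_refined, pk$y_refined)
#> <annotation> Rg = 31.07 A, I(0) = 121.8 (guinier)

elongation_ratio(synth_pair_distribution(spec))
#> <er_result> ER = 0.9388 (r_largest = 40.67 A)

guinier_validity_limit(spec)
#> [1] 1.54
```

Reading the output: the fit recovers *R*g within ~2% (the 1.3-window cap
carries a small known bias on exact spheres); the located peak maps to
(1.460, 0.7413), close to the theoretical (1.5, 0.7428) — a solid sphere
genuinely peaks slightly below 1.5 — so the annotation is consistent;
ER ≈ 0.94 says "compact, symmetric body"; and the Guinier approximation
holds to *qR*g ≈ 1.54 at 5% tolerance, comfortably past the 1.3
guideline for globular scatterers.  Collections of curves go through
`screen_collection()`, which adds 3-MAD outlier flags and class hints
(`ok` / `elongated` / `annotation_suspect` / `problematic_guinier` /
`no_guinier_region`) and writes JSON or CSV via `write_report()`.

A command-line interface mirrors the main operations:

```sh
exec/saxsgpa simulate --kind sphere --radius 38.73 --qmax 0.12 \
    --npts 300 -o sphere.dat --pr sphere_pr.dat
exec/saxsgpa guinier sphere.dat --qrg-max 1.3
exec/saxsgpa gpa sphere.dat --find-peak --rg 30 --i0 1
exec/saxsgpa er sphere_pr.dat
```

## Vignette

`vignettes/guinier-peak-analysis.Rmd` documents the model, the scale-space
peak criterion, the refinement used for parameter estimation, the
synthetic world's deliberate non-idealities (polydispersity, repulsion
emulation, mixtures) and the numerical edge cases.
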