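---
title: "Guinier peak analysis: model, methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guinier peak analysis: model, methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsgpa)
```

## The model

Small-angle X-ray scattering of a dilute monodisperse solution follows, at
low resolution, the Guinier approximation

$$I(q) \approx I(0)\,\exp(-q^2 R_g^2/3), \qquad q R_g \lesssim 1.1\text{--}1.3,$$

where $q$ is the scattering-vector magnitude (Å⁻¹), $R_g$ the radius of
gyration and $I(0)$ the forward scattering.  Multiplying both sides by $q$
turns the monotone Guinier region into a *peak*: $qI(q)$ versus $q^2$ rises
from the origin to a maximum at $q^2_{\max} = 1.5/R_g^2$, equivalently
$q_{\max} R_g = \sqrt{1.5} \simeq 1.22$.  Two facts make this transform a
useful quality-control device:

1. **The rise is parameter-free evidence.**  If the data reach down into
   the Guinier region, the transformed curve rises before it falls.  No fit
   is needed, so the check works even when only a handful of Guinier-region
   points were measured.
2. **The dimensionless peak is universal.**  Scaling to
   $qR_g\,I(q)/I(0)$ versus $(qR_g)^2$ with the *annotated* $(R_g, I(0))$
   puts the ideal peak at $\bigl(1.5,\ \sqrt{1.5}\,e^{-1/2}\bigr)
   = (1.5,\ 0.7428)$ for every size and intensity scale.  A displaced peak
   means the data near the peak disagree with the annotation — because the
   annotation is wrong, because the scatterer is elongated, or because the
   low-q intensities are themselves distorted (polydispersity,
   interparticle interference, aggregation).

The algebra also runs backwards: a located peak $(x, y)$ on the $qI(q)$ vs
$q^2$ plot yields $R_g = \sqrt{1.5/x}$ and $I(0) = y\,e^{1/2}/\sqrt{x}$
(`estimate_from_peak()`).  The estimate uses only data near
$(qR_g)^2 = 1.5$ and is biased for elongated bodies, for which the Guinier
approximation fails before the peak; a windowed Guinier fit
(`guinier_fit()`) is preferred when the region is well measured.

## Automated peak localization

Validation must find the peak *without* assuming the Guinier model.
`scale_space_criterion()` scores every point of the transformed curve by
its persistence under smoothing: the signal is convolved with Gaussian
kernels of standard deviation 1, 2, 4, … bins (up to a quarter of the
signal length, reflected boundaries), and a point earns one unit of score
per scale at which it lies within a drift radius (2 bins per octave) of a
local maximum of the smoothed signal.  Broad features survive the whole
ladder; one-bin noise spikes die at the first scale.

`find_guinier_peak()` then ranks each point twice — `r_c` by criterion
score and `r_qI` by raw height, rank 1 highest, average ranks on ties —
and takes the point minimizing `r_c * r_qI`, breaking rank-product ties
toward lower q (the Guinier peak is the lowest-q major feature).  A winner
in the first or last two grid points is reported as a flagged failure
("no interior peak") rather than a guess: either the Guinier region was
not measured or the heuristic was defeated, and both deserve eyes.  A
`trim` argument reproduces the practice of re-running after cutting noisy
extremes.

Because a single point's intensity is noisy, the reported peak *height*
comes from a least-squares polynomial (degree 2 over ±5 points by
default) evaluated at the winner.  For quantitative parameter
*estimation* a second refinement is applied: over ±50 points around the
winner we regress $\ln y - \tfrac12\ln x$ on $x$, which fits the exact
transformed Guinier form $y = a\sqrt{x}\,e^{-bx}$ and therefore has no
window-width bias on ideal curves (a quadratic vertex, by contrast,
carries an $O(h^2)$ bias of −0.6% to −2.4% in $R_g$ that we measured
before discarding it).  The refined coordinates cut the peak-position
scatter at 2% noise from ~0.1 to ~0.02 in $(qR_g)^2$; screening and
estimation use them, while the raw winner and polynomial height remain
available as the strictly model-free coordinates.

## Real-space statistics

From a pair-distribution function $P(r)$ (read from a 2-column file or
generated synthetically — this package never inverts experimental $I(q)$):

* `pr_moments()`: $R_g^2 = \int r^2 P\,dr \,/\, 2\!\int\! P\,dr$ and
  $I(0) = 4\pi\!\int\! P\,dr$, trapezoidal on the native grid.  The $4\pi$
  convention matches common indirect-transform output; any fixed constant
  cancels in dimensionless coordinates.
* `elongation_ratio()`: area under $P(r)$ after its maximum divided by the
  area before it.  Symmetric bodies give ER ≈ 1 (the solid sphere is at
  0.94); elongated bodies push the maximum to small $r$ and ER grows
  quickly — ER > 5 marks scatterers elongated enough that their
  dimensionless peak legitimately misses (1.5, 0.7428).  Ties at the
  maximum resolve to the smallest $r$.  Note ER is *not* stationary at the
  split point, so its discretization error is first-order in the grid
  step; we quote ±0.005 at ~800 bins.
* `normalize_pr()`: resamples $P$ on $r' = r/R_g$ in steps of 1/4 (linear
  interpolation, zero beyond $D_{\max}$) and rescales to unit sum, making
  curves comparable purely by shape.

Shape comparison uses the composite-angle distance
(`composite_angle_distance()`): per-bin shared mass $\min(a_i, b_i)$ and
unique mass $\max - \min$ are summed into a 2-vector whose angle to the
shared axis, scaled to [0, 1], is the distance (0 identical, 1 disjoint
support; unequal grids are zero-padded so differing $D_{\max}/R_g$ is
penalized).  `cluster_shapes()` feeds the matrix to complete-linkage
agglomerative clustering (`hclust`; average linkage optional) with a flat
cut at user-chosen `k` — how many shape groups a survey contains is a
judgment call, so no default `k` is dictated beyond the CLI demo's 3.

## Screening a collection

`screen_collection()` runs the pipeline per curve, then applies the
Hampel identifier with $k = 3$: spread is the unscaled median absolute
deviation of the collection's peak coordinates, and a record is an
outlier when its deviation **from the theoretical point** reaches
$3\,\mathrm{MAD}$ in either axis.  Medians/MADs rather than means/SDs keep
the outliers being hunted from inflating the yardstick.  Synthetic
collections can have essentially zero spread, so the MAD is floored at 1%
of the theoretical coordinate.

Flagged records are triaged by `classify()`:

* `no_guinier_region` — no interior peak found;
* `elongated` — outlier with ER above the cutoff (default 5);
* `annotation_suspect` — outlier whose curve is internally consistent: a
  fresh Guinier fit of the curve itself moves the peak back inside the
  Hampel limits, so the supplied annotation is the odd one out;
* `problematic_guinier` — even the curve's own fit cannot reconcile the
  peak: the low-q intensities disagree with the peak region.

The annotation-vs-intensity discriminator is this package's design (the
four classes come with no operational rule).  A tempting alternative —
substituting the peak-based re-estimate itself — is algebraically
degenerate: mapping a peak through parameters derived from that same peak
lands on (1.5, 0.7428) identically, reconciling everything.  Substituting
an *independent* fit of the same curve is the weakest non-trivial test and
is what we implement.

## The synthetic world

`shape_spec()` + `synth_intensity()` generate orientation-averaged
form-factor intensities, normalized to $I(0)$ exactly: the closed-form
sphere; ellipsoids of revolution $(a, a, va)$; triaxial ellipsoids;
cylinders (radius $r$, length $2vr$); rectangular prisms — anisotropic
bodies via 128-point Gauss–Legendre quadrature per angular axis, chosen so
the $v = 1$ ellipsoid matches the sphere to 10⁻⁶.  Analytic radii of
gyration (e.g. $\sqrt{3/5}\,R$ for the sphere, $\sqrt{r^2/2 + L^2/12}$
for the cylinder) serve as ground truth.  `synth_pair_distribution()`
histograms distances between independent uniform point pairs inside the
solid (2×10⁵ pairs by default; the sphere also has its exact
$p(r) \propto r^2(1 - 1.5u + 0.5u^3)$, $u = r/2R$).  `add_noise()`
perturbs intensities with $\sigma(q) = \epsilon\sqrt{I(q)\,I(0)}$ —
relative error growing as intensity falls, the usual counting-statistics
shape — deterministically per seed.

Three deliberately non-ideal generators emulate the problem cases:

* **Polydisperse spheres**: volume²-weighted truncated-Gaussian radius
  law (41 points, ±4σ).  A caution from building this fixture: at
  moderate width (σ/μ = 0.3) the sphere form factor's own concavity in
  $\ln I$ vs $q^2$ *outweighs* the polydispersity convexity inside
  $qR_g \le 1.3$, and local $R_g$ rises with $q$.  The textbook
  polydispersity signature — concave-up Guinier plot, local $R_g$
  falling with $q$ — emerges only for broad populations; the package's
  strongly-polydisperse fixture uses σ/μ = 1.0.  A second caution: a
  smooth polydisperse curve annotated from *its own* Guinier fit is
  nearly self-consistent (the GPA peak at $q_{\max}R_g = 1.22$ sits
  inside the fit window), deviating by at most ~0.03 in $(qR_g)^2$.
  The screening fixture therefore annotates the population with its
  *nominal* monodisperse species — the particle the experimenter
  believes is in the tube — which is the scenario in which
  polydispersity is actually caught.
* **Repulsion emulator**: $I(q)\,[1 - A e^{-q^2\xi^2}]$, explicitly
  non-physical, reproducing the concave-down Guinier plot and rising
  local-$R_g$ track of electrostatic repulsion.  Defaults $A = 0.3$,
  $\xi = 20$ Å on an $R_g = 30$ Å base keep the apparent low-q $R_g^2$
  positive while displacing the self-annotated peak to $x' \approx 1.28$.
* **Mixtures**: weighted sums of component intensities.  The observed
  low-q $R_g^2$ is the intensity-weighted z-average, which is exactly why
  heterogeneous assemblies annotated with z-average values are a *blind
  spot*: monomer/dimer analogues and a 0.27%-aggregate "pre-column"
  curve (calibrated to a 9% $R_g$ increase) pass the screen.  On
  synthetic collections, whose MADs are several-fold tighter than real
  survey spreads, the 9% aggregation case sits almost exactly at the
  3-MAD boundary — the blind spot is partly a property of the
  real-data threshold scale.

`guinier_validity_limit()` scans $I(q)$ against the ideal Guinier decay
(true parameters) and reports the largest $qR_g$ reached before the
relative deviation first exceeds a tolerance (default 5%): the ideal
scatterer holds to the end of the scan, the sphere to $qR_g \approx 1.54$
(comfortably past the 1.3 guideline), a 16:1 cylinder only to
$\approx 1.17$ (near the 1.1 guideline for extended samples).

## Numerical choices and degenerate inputs

* Guinier fit window: iterative — seed fit on the lowest 20% of points,
  then refit on $q R_g \in [q R_{g,\min}, 1.3]$ until the point set is
  stable (≤ 10 iterations; non-convergence is flagged, not hidden).
  Unweighted by default; `weighted = TRUE` uses $1/\sigma^2$ on
  $\ln I$.  On the exact sphere the 1.3 cap carries a known +1.8%
  $R_g$ bias from form-factor curvature (+0.8% at 0.9); callers wanting
  tighter agreement with real-space $R_g$ should lower `qrg_max`.
* Non-positive intensities abort the fit; rising low-q intensity gives
  the explicit error "Rg undefined" rather than a complex $R_g$.
* $D_{\max}$ from files: the grid point just past the last value above
  $10^{-6}\max(P)$, so a triangle ending in an exact zero keeps its full
  base while trailing noise rows do not extend the support.
* Small negative $P(r)$ (truncation artifacts) are clipped when the
  negative mass is < 1% of the positive mass, else the input is rejected.
* All Monte Carlo and noise generators take explicit seeds and restore
  the caller's RNG state.

## What a green test establishes — and what it does not

The synthetic world contains ideal scatterers, mathematically exact
solids, stationary Gaussian noise and clean two-component mixtures.  It
does not contain instrument smearing, buffer-subtraction artifacts,
inter-particle structure factors beyond the phenomenological suppression
term, concentration series, or the conformational heterogeneity of real
macromolecules.  Green tests therefore establish the *mechanics* —
transforms, peak finding, statistics, flag logic — and the physics of
regular solids, not performance on any particular beamline's output.
Thresholds tuned here (the MAD floor above all) matter only for clean
synthetic collections; real surveys have MADs an order of magnitude
larger and the floor never binds.
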