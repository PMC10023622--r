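---
title: "trimorph: models, phantoms, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{trimorph: models, phantoms, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trimorph)
```

# Scope

`trimorph` re-implements, as reusable tested code, the quantitative analysis
chain of an ex vivo beating-heart model of functional tricuspid
regurgitation: tricuspid annulus morphometry from sparse rotational
annotations, semi-automatic right-ventricle volumetry, pulsatile and steady
hemodynamic indexes, and the paired fresh-vs-defrosted cohort statistics.
The physical bench (pump, impedance simulator, probes) and the tissue
protocol are out of scope; what the package owns is everything downstream of
the recorded volumes, annotations and signals — plus synthetic generators
that stand in for those recordings with known ground truth.

# The morphometric model

## Annulus representation and fitting

The annular curve is represented per Cartesian coordinate as a truncated
Fourier series in a sweep angle, order 4 by default. Landmarks arrive on 18
half-planes rotated 20 degrees apart around the valve long axis, so the fit
is a per-coordinate linear least squares of 18 points on the 9-function
harmonic basis (overdetermined by a factor 2). Two consequences worth
knowing:

* any curve whose harmonic content in the station angle is at most the fit
  order is reproduced to machine precision — the suite asserts this;
* the fitted series is parameterized by *plane azimuth*, not by the
  phantom's own construction parameter. For non-circular annuli these
  parameterizations differ; all derived quantities are therefore defined so
  they do not depend on parameterization (see the plane paragraph below).

Whether the original analysis fit Cartesian coordinates or cylindrical ones
is not derivable from the source; Cartesian per-coordinate fitting was
chosen as the simpler linear problem, and the point is moot for curves the
fit reproduces exactly.

## The annular reference plane

L2D, A2D, Dmax/Dmin and the tenting volume all depend on "the" annulus
plane. We define it as the total-least-squares plane of the fitted curve
*resampled uniformly by arc length* (720 points). Arc-length weighting makes
the plane a geometric functional of the curve rather than of its
parameterization — fitting the same saddle annulus parameterized two ways
gives the same plane. The quadrature oracle uses the identical definition
(curve-speed-weighted covariance), which is what makes a 2 % oracle-vs-
pipeline comparison meaningful for saddle shapes; with naive uniform
weighting the two planes differ enough to move the clipped tenting integral
by several percent. The plane normal is oriented atrially (against the
long axis, which points ventricularly, toward the mean free-margin offset).

## Perimeters, areas, diameters

* `L3D` — arc length of the 360-point fitted polyline; `L2D` — arc length of
  its orthogonal projection on the plane.
* `A2D` — shoelace area of the projected polygon. `A3D` — the centroid-fan
  triangle area over the 3D curve. The source names but never defines the
  "area enclosed by" a non-planar curve; the fan is the minimal standard
  choice and reduces to the planar area for planar curves (asserted to
  1e-6 relative).
* `Dmax`/`Dmin` — the annulus is expressed in polar form about the projected
  centroid; the chord at direction φ is `r(φ) + r(φ + π)`, scanned on a
  0.05-degree grid (finer than a 1-degree scan with 0.1-degree refinement,
  and branchless). A curve that is not star-shaped about its centroid raises
  a `trimorph_non_star_shaped` error rather than returning a meaningless
  chord; the same check guards `A2D` against self-intersecting projections.

## Leaflet surface and tenting volume

The leaflet surface is reconstructed by 2D Delaunay triangulation of all
available surface points (annulus polyline, free-margin points, per-plane
leaflet traces, coaptation apex) projected on the annular plane, lifted back
to 3D; triangles outside the projected annulus polygon are discarded. The
projection step encodes the closed-valve assumption that the surface is
single-valued over the annular plane.

Two numerical choices matter:

* **Azimuthal ring refinement.** Interior points exist only on the 18
  annotation planes. Triangulating them raw leaves 20-degree azimuthal gaps
  whose linear interpolation biases the tenting volume by several percent on
  saddle-shaped annuli. Each ring of homologous trace points (and the
  free-margin ring) is therefore azimuthally interpolated with an order-8
  harmonic fit — exact for every supported phantom shape, and a smoothing
  interpolant for real annotations — before triangulation
  (`reconstruct_leaflet_surface(refine = 72)`; `refine = 0` restores raw
  behavior, under which every input point is a mesh vertex).
* **One-sided prisms.** `Tvol` sums, per triangle, the projected area times
  the mean of the vertex distances below the plane clipped at zero.
  Clipping makes atrial prolapse unable to cancel ventricular tenting.

The Delaunay triangulation itself is an in-package Bowyer–Watson
implementation (no R package in the deployment environment provides one):
O(n²) vectorized insertion, strict in-circle test with a relative tolerance
and a containment fallback for the cocircular configurations that
structured rings produce. It is validated against the defining
empty-circumcircle property by brute force, not against another library.

# The phantoms (the stated world)

The synthetic generator exists to give every operation a testable ground
truth; its defaults are the study's stated operating point wherever one is
stated, and fixed plausible values elsewhere:

* **Annulus**: circle, ellipse, or ellipse plus a `cos 2θ` out-of-plane
  saddle (the classic bimodal atrioventricular saddle; the source gives no
  quantitative porcine annulus shape). Calibration sizes default to the
  fresh-cohort diameters (a = 25.1, b = 21.55 mm). The replica's default
  saddle height of 3.6 mm was chosen once so the fresh-calibration
  phantom's `L3D/L2D` ratio matches the reported fresh ratio
  (152.8/149.2 ≈ 1.024; for an ellipse of mean radius r the excess is
  ≈ (s/r)²), and is not revisited.
* **Leaflets**: a single-valued tent `S(f, θ) = c + f (Q(θ) − c) +
  [f d(θ) + h g(f)] n` with profile g ∈ {paraboloid 1−f², cone 1−f, flat 0}
  and depth h. For a planar circular annulus the tenting volume has closed
  forms (`h π r² / 2` paraboloid, `h π r² / 3` cone) used as oracle anchors;
  for general shapes the oracle integrates the clipped depth by dense 2D
  quadrature using the analytic surface tangents.
* **Voxelization**: tissue 200, background 30, optional additive Gaussian
  noise, clipped to [0, 255]; 0.5 mm isotropic default spacing (finer than
  echo, keeping phantom error below metric tolerances). The ground-truth
  annotation is emitted at voxelization time with every landmark snapped to
  a voxel center — an idealized manual annotator; automatic landmark
  *detection* from intensities is deliberately out of scope because the
  source's landmarks are manual.
* **RV**: an ellipsoidal cavity (dark cavity in bright wall, matching echo
  blood-pool contrast) with truth `(4/3) π a b c`; default shape ratio
  50:40:22.2 scaled to the target volume.
* **Cohort**: per metric, (fresh, defrosted) truths are bivariate normal
  with the reported marginal means/SDs; the within-pair correlation is not
  reported and defaults to 0.8 (strongly paired hearts). The sampler is
  mean-unbiased and unclamped; the replica driver clamps physically
  impossible draws (negative backflow, TRF ≥ 100 %) when building phantoms
  and records the clamped value as that sample's truth.

What a green test does **not** establish: fidelity to real porcine anatomy
(no chordae, no leaflet thickness, no speckle physics, single-frame only),
operator variability beyond isotropic landmark jitter, or the pressure
dependence of real regurgitant orifices (see limitations).

# Hemodynamics

## Waveform generator

Half-sinusoid ejection over a 0.35 systolic fraction (the source shows but
does not parameterize its waveforms; any smooth shape meeting the volume
contracts would do). Per cycle, with stroke volume SV, TRF target τ and PRV
target ρ: the tricuspid flow carries a systolic backflow lobe of volume
`τ·SV/100` and a diastolic filling lobe of `SV − ρ`; the pulmonary flow the
complementary forward volume and an early-diastolic lobe of `ρ`. The
balance "forward TV − TV backflow = forward pulmonary − PRV" then holds by
construction (the ventricle is a pass-through at cycle scale).

## Index estimators

Cycles are segmented at the nominal fixed period (the rig is paced; no peak
detection) and ensemble-averaged pointwise. Per-cycle integrals use the
periodic trapezoidal rule (`sum · dt`), which is the trapezoid with
wrap-around closure and exact for band-limited periodic signals.

`compute_prv` deserves a note: the literal estimator `∫ max(−q, 0) dt`
rectifies noise over the long zero-flow part of the cycle and acquires a
positive bias `E[max(0, N)] ≈ σ_avg/√(2π)` per unit time — roughly 3–5 % of
an 8 mL PRV at 20 dB SNR even after 10-cycle averaging, which breaks the
package's own 2 % round-trip contract. The default estimator therefore
integrates the *contiguous retrograde lobe* containing the flow minimum:
identical on clean signals, unbiased under zero-mean noise. The rectified
form remains available (`method = "rectified"`). TRF keeps the rectified
definition: its backflow volume is large enough that the same bias is far
inside tolerance.

## Windkessel

`C dPc/dt = q − Pc/Rp`, `PAP = Rc q + Pc`, fixed-step RK4 at the sampling
interval with linear flow interpolation at half-steps (`substeps` subdivides
for convergence studies; no adaptive stepping is needed at these time
constants). Because `τ = Rp C ≈ 16.5 s` dwarfs the heart period, a cold
start would drift for minutes; by default the compliance state starts on the
periodic orbit, computed in closed form from one cycle of flow,
`Pc(0) = ∫ e^{−(T−s)/τ} q(s)/C ds / (1 − e^{−T/τ})`, so cycle means are
stationary from the first beat. For constant inflow this reduces to
`q · Rp` and the simulated PAP equals `q (Rc + Rp)` immediately.

## Steady backflow

The orifice model is plain Bernoulli flow `Q = cd · EROA · √(2 ΔP/ρ)` with
cd = 0.7 and saline density; it exists to generate calibratable synthetic
data, not to model valve mechanics. Notably the reported backflow ratios
BF(30)/BF(15) ≈ 2.1–2.5 exceed the orifice-law √2, implying pressure-
dependent orifice area in real (especially defrosted) valves; the package
keeps a constant EROA calibrated per pressure point and leaves `eroa(ΔP)`
modeling open. `measure_steady_backflow` averages the trailing half of the
record and flags readings whose trailing-half trend exceeds 1 %/s of the
mean as unsettled.

# RV segmentation

The interactive active-contour workflow is reduced to a deterministic core:
intensities inside a user window map to speed +1, intensities more than
`ramp_width` outside to −1, with a linear ramp just outside each edge
(`ramp_width = 0` gives the hard map used for phantoms, window = cavity
intensity ± 3σ); a 6-connected breadth-first front grows from the seeds
through positive speed (compiled, `max_iter` caps the front radius and
flags truncation); scripted sphere/box add/remove edits replace interactive
clean-up (reproducibility over interactivity); volume is
`voxels × spacing³`. On binary speed images this equals thresholded
connected-component labeling — asserted against a brute-force oracle — and
the curvature-regularized evolution of the original software is a
documented divergence that cannot matter for high-contrast cavities.

# Cohort statistics

Shapiro–Wilk (3 ≤ n ≤ 50, non-constant input enforced), two-sided paired
t-test `t = mean(d)/(sd(d)/√n)`, df = n − 1, no multiple-testing correction
(none was used in the source). "Mean variation" is the mean of per-sample
percent changes, not the percent change of the means: the reported
BF-15 mmHg row (0.4 → 1.7 L/min printed as 551 %) is inconsistent with the
change-of-means reading (325 %), so per-sample averaging over heterogeneous
samples is the only definition consistent with the printed numbers. The
per-sample data behind that column are unavailable, so this reading is
reproduced qualitatively, not verified against raw data.

# The replica driver

`run_replica` draws a paired cohort calibrated to the reference table,
builds per sample a saddle-ellipse valve phantom (ellipse axes from
Dmax/Dmin, paraboloid depth root-found so the quadrature tenting volume
equals the sampled target), an RV ellipsoid scaled to the sampled volume
(0.7 mm spacing — twenty segmentations stay inside a minute-scale budget at
~0.1–0.3 % discretization error), waveform records (stroke volume solved as
`SV = (CO·T/0.06 + PRV)/(1 − TRF/100)` so the three sampled hemodynamic
targets are jointly attainable — the reported index means are not mutually
consistent with a pass-through ventricle at SV = 70 mL), and steady records
from per-pressure calibrated orifices. It then runs the full measurement
pipelines and reports a summary table plus recovery diagnostics. L2D, L3D,
A2D and A3D are geometrically determined once Dmax/Dmin/Tvol are set, so
their per-sample targets are the phantom's quadrature truths rather than
the table means. With n = 10 the *cohort means themselves* scatter around
the configured targets by far more than a few percent (e.g. SE ≈ 24 % for
BF-15), so recovery is judged measured-vs-truth per drawn sample, never
measured-vs-population-mean. Every output embeds an MD5 config hash and the
whole bundle is byte-reproducible under a fixed seed.

# Degenerate inputs and error taxonomy

All contract violations raise classed conditions (`trimorph_*`):
`invalid_parameter`, `degenerate_geometry` (collinear points),
`non_star_shaped`, `underdetermined` (too few stations for the Fourier
order), `incomplete_annotation` (lists the missing plane angles),
`bounds_error`, `bad_seed` (names the offending seed),
`insufficient_cycles` (reports the available count), `degenerate_data`
(zero-variance statistics), `inconsistent_spec` (flat profile with positive
depth), `stage_failure` (replica, names sample and stage).

# Known limitations

* Single-frame geometry only; end-systole frame selection from 4D data is
  the annotator's job.
* The saddle phantom family cannot represent every porcine annulus; phantom
  defaults are chosen for testability, not anatomical fidelity.
* The tenting-volume definition depends on the annular plane convention;
  other tools that weight the plane fit differently will disagree by
  O(plane offset × annulus area) on strongly saddled annuli.
* Constant-EROA steady backflow under-predicts the measured
  pressure-dependence of real regurgitant orifices.
* The CLI's NIfTI support covers the single-frame, diagonal-sform,
  little-endian subset this package writes.
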