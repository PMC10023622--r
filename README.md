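# trimorph

Quantitative machinery for an **ex vivo beating-heart model of functional
tricuspid regurgitation** (FTR): 3D-echocardiography-style tricuspid valve
morphometry, semi-automatic right-ventricle (RV) volumetry, pulsatile and
steady hemodynamic indexes, and the paired fresh-versus-defrosted cohort
comparison — all exercisable on synthetic phantoms with closed-form ground
truth, so every stage of the measurement chain is testable without access to
porcine hearts or an echo machine.

## Who this is for

Cardiovascular-engineering groups running mock circulatory loops and
benchtop valve models, and anyone re-implementing annulus morphometry from
sparse rotational annotations. The package separates the *measurement
pipeline* (what you would run on real annotated echo volumes) from the
*phantom generator and quadrature oracle* (what you use to validate it).

## The quantities

**Morphometry** — from two annular points manually identified on each of 18
half-planes rotated 20° apart around the valve long axis:

- the annular curve is fit per coordinate with a 4th-order Fourier series
  in the plane azimuth φ:
  `P_c(φ) = a_c0 + Σ_{k=1..4} a_ck cos kφ + b_ck sin kφ`;
- **L3D / L2D** (mm): arc length of the 3D annulus and of its orthogonal
  projection on the least-squares annular plane;
- **A3D / A2D** (mm²): centroid-fan area of the 3D curve and shoelace area
  of its projection;
- **D_max / D_min** (mm): extremal chords through the centroid of the
  projected annulus;
- **T_vol** (mL): tenting volume, the space between the annular plane and
  the Delaunay-reconstructed leaflet surface, counting the ventricular side
  only.

**Hemodynamics** — from 200 Hz flow/pressure records averaged over 10 paced
cycles (60 bpm, stroke volume SV = 70 mL):

- **TRF** (%) `= 100 · ∫ max(−q_tv, 0) dt / SV` — tricuspid regurgitant
  fraction;
- **CO** (L/min) `= 0.06 · mean(q_pulm)` — cardiac output;
- **PRV** (mL) — per-cycle volume of the retrograde pulmonary lobe;
- **BF** (L/min) — steady backflow through the closed valve at 15 / 30 mmHg;
- pulmonary pressure from a three-element Windkessel
  (`Rc = 0.029 mmHg·s/mL`, `C = 16.5 mL/mmHg`, `Rp` adjustable
  0.22–1.18 mmHg·s/mL): `C dPc/dt = q − Pc/Rp`, `PAP = Rc q + Pc`.

**RV volumetry** — ITK-SNAP-style four steps, fully scripted: ROI crop →
threshold speed image in [−1, 1] → seeded 6-connected region growing →
scripted refinement edits → `voxels × spacing³`.

**Cohort statistics** — Shapiro–Wilk screen, two-sided paired t-test, and
the mean per-sample percent variation
`mean_i 100 (defrosted_i − fresh_i)/fresh_i`.

## Worked example

```r
library(trimorph)

## a fresh-calibrated phantom: ellipse annulus Dmax/Dmin = 50.2/43.1 mm,
## 3.6 mm saddle, paraboloid tenting
ann   <- build_annulus("saddle", a_mm = 25.1, b_mm = 21.55, saddle_height = 3.6)
valve <- leaflet_spec(ann, "paraboloid", tenting_depth = 7.06)
run_morphometry(valve)
#> <morpho_result>
#>   L2D 146.76 mm   L3D 150.17 mm
#>   A2D 1699.2 mm^2  A3D 1749.1 mm^2
#>   Dmax 50.09 mm  Dmin 43.01 mm
#>   Tvol 6.505 mL

## pulsatile record with prescribed regurgitation, then index recovery
st <- pump_settings()                       # 60 bpm, 70 mL, 200 Hz
wf <- split_flows(st, trf_target = 67.1, prv_target = 7.9, n_cycles = 10)
wf$pap <- simulate_windkessel(windkessel_params(Rp = 1.0), wf$q_pulm,
                              dt = 1 / st$fs, cycle_samples = 200)
idx <- compute_hemo_indexes(wf, stroke_volume = 70)
sprintf("TRF %.1f %%  CO %.2f L/min  PRV %.1f mL", idx$TRF, idx$CO, idx$PRV)
#> "TRF 67.1 %  CO 0.91 L/min  PRV 7.9 mL"
```

The recovered TRF/PRV equal the prescribed targets (the measurement chain
inverts the generator); CO is whatever mass conservation implies for this
SV/TRF/PRV combination. The `Dmax`/`Tvol` values sit within a fraction of a
percent of the phantom's quadrature ground truth (`analytic_truth(ann,
valve)`).

End-to-end cohort replica (generate paired cohorts → phantoms → full
measurement → Table-style summary):

```r
rep <- run_replica(replica_config(n_samples = 10, seed = 42), outdir = "out")
rep
#> <replica_report> 10 paired samples, seed 42, config 1cae2216
#>   worst cohort-mean recovery error: 0.71% (RVvol, fresh)
```

`out/summary.md` holds the fresh/defrosted table (mean ± SD, mean
variation, paired-t p), `out/measurements.csv` the per-sample truth and
measured values.

## Command line

```sh
trimorph synth flow --trf 67.1 --prv 7.9 --rp 1.0 --cycles 10 --out wf.csv
trimorph hemo  --waveforms wf.csv --hr 60 --sv 70 --cycles 10
trimorph synth valve --out valve && trimorph morph --annotation valve.json --out m.json
trimorph synth rv --volume-ml 185.8 --out rv.nii.gz
trimorph rvseg --volume rv.nii.gz --seeds "0,0,0" --thresholds 15,45
trimorph replica --n 10 --seed 42 --out replica_out
```

(The launcher installs under `exec/trimorph` in the package library; or call
`trimorph_cli(c("synth", "flow", ...))` from R.)

## Further reading

`vignettes/methods.Rmd` documents the model assumptions, the phantom
generator's stated world, numerical choices and known limitations.
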