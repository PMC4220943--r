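# fourpoint

Error analysis of four-point plane orientation for 3D cephalometric
landmarks.

## The problem

Orthodontic and craniofacial analysis of CBCT volumes starts by digitizing
named skull landmarks (nasion, sella, menton, ...) and expressing them in a
standardized anatomical coordinate system so that repeated scans or
digitizations can be superimposed. A simple and clinically practical way to
build that system uses four cranial-base points:

- the **y (anteroposterior) axis** is parallel to the sella–nasion line
  (positive toward nasion),
- the **z (vertical) axis** is parallel to the perpendicular dropped from
  basion onto that line (positive superior),
- the **x (transverse) axis** completes the right-handed triad, x = y × z,
- **MLWS** (midpoint between the posterior points of the bilateral lesser
  wings of the sphenoid) becomes the origin.

Every landmark, including the four reference points, moves a little each
time it is digitized, so the frame itself shifts between sessions and the
superimposition inherits that error. `fourpoint` quantifies the propagation:
for two digitization trials of the same image it computes, per landmark,

- **Db** — locating error: the 3D distance between the two placements
  (plus per-axis absolute differences),
- **Y** — reorientation error: the distance between the two positions after
  each trial is reoriented by its *own* frame,
- **DX** — the perpendicular distance of the (pair-averaged) landmark from
  the reoriented transverse axis,
- **A3r** — the sum of the three angles (in degrees) that the two placements
  of each reference point Na, S, Ba subtend at the averaged landmark,

together with ICC(3,1) reliability per coordinate, per-landmark summary
tables, and a stepwise multiple-regression error model

    Y = b0 + B_Db · Db + B_DX · DX + B_A3r · A3r + ε

fitted per trial-pair scope (T1–T2, T1–T3, T2–T3) and pooled, with 3-SD
response-outlier screening and VIF collinearity diagnostics. Marginal
effects of the fitted model translate directly into clinical statements
("1 mm of locating error adds ≈ 0.76 mm of reorientation error").

Because real digitizations require a radiologist and an imaging workstation,
the package ships a seeded synthetic-cohort generator: an anatomically
plausible 19-landmark skull template whose distances from the transverse
axis match published per-landmark means, between-patient size/shape/pose
variation, and per-landmark anisotropic Gaussian placement noise calibrated
(via the half-normal identity σ = m·√π/2) to published per-axis mean
absolute locating errors. Every pipeline stage is exercised end to end on
that generator.

## Worked example

The numbered drivers under `analysis/` run the full study pipeline and
write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R --seed 20   # cohort.csv
Rscript analysis/02_reorient.R             # reoriented.csv
Rscript analysis/03_metrics.R              # error records, summaries, ICC
Rscript analysis/04_regression.R           # regression_report.json
```

which prints (seed 20):

```
simulated 20 patients x 3 trials x 19 landmarks -> 1140 rows
reoriented 60 trials; max |MLWS coordinate| = 0 mm (exact origin)
1140 error records; minimum ICC 0.9967
mean Y exceeds mean Db for 18/18 non-origin landmarks
T1-T2: predictors {DY, Db, A3r, DZ}, adj R^2 0.271, n 294 (6 excluded)
T1-T3: predictors {DY, Db}, adj R^2 0.295, n 296 (4 excluded)
T2-T3: predictors {D0, Db, A3r}, adj R^2 0.324, n 293 (7 excluded)
Total: predictors {Db, A3r, D0}, adj R^2 0.280, n 882 (18 excluded)
```

Reading the output: MLWS is each trial's own origin, so its reorientation
error is exactly zero; every other landmark ends up with *more* error after
reorientation than its own locating error, because the frame jitters too;
coordinate reliability stays above 0.99 because anatomy varies far more
between patients than placements do within one; and the stepwise model
explains roughly a quarter to a third of the reorientation-error variance
from simple geometric factors. (On synthetic cohorts the position-size
candidates DX, DY, DZ, D0 are nearly interchangeable, so scopes may pick
different members of that family; locating error Db is selected in every
scope.)

The same machinery is available interactively:

```r
library(fourpoint)
co  <- generate_cohort(cohort_config(), seed = 20)
rec <- error_records(co)
summarize_records(rec)[, c("landmark", "Y_mean", "Db_mean", "DX_mean")]
fit <- fit_all_scopes(assemble_rows(rec))$Total
predict_marginal(fit, "Db", 1)   # mm of Y per mm of locating error
```

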