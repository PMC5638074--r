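# htrcine

Retrospectively gated high-temporal-resolution (HTR) CINE MRI of the mouse
heart, as a fully simulatable, testable pipeline in R.

## The problem

Diastolic dysfunction — impaired ventricular relaxation and filling — is an
early marker of heart failure, conventionally read from the ratio of the
early (E) to atrial (A) filling peaks. In mice the cardiac cycle lasts only
~100 ms, so resolving two distinct filling peaks needs ~90 frames per cycle
(≈1 ms temporal resolution), far beyond prospectively triggered CINE
imaging. The retrospective alternative: run an ungated FLASH sequence
continuously (TR = 3.15 ms, one phase-encode line per TR, the full 128-line
k-space swept NR = 1400 times ≈ 9.4 min) while logging every R-wave,
respiration window and RF excitation, then sort the recorded k-lines into
cardiac frames afterwards.

Each line acquired at time *t* inside the R-R interval [*R_i*, *R_{i+1}*)
goes to frame

&nbsp;&nbsp;&nbsp;&nbsp;*f* = ⌊ NF · (t − R_i) / (R_{i+1} − R_i) ⌋,&nbsp; NF = 90,

after discarding lines inside respiration windows and lines from cycles
whose R-R deviates more than 20% from the median (presumed gating errors).
Surviving lines are averaged per (frame, phase-encode) cell, residual gaps
borrow the nearest frame's line, and an inverse 2-D DFT per frame yields the
CINE. With the protocol above, ≥ 99% of the 90 × 128 cell grid ends up with
at least three averages.

Downstream, the left-ventricular blood pool is segmented in every frame,
volume = pixel count × in-plane voxel area × slice thickness, the
time–volume curve V(t) is differentiated to the filling-rate curve dV/dt,
and its two diastolic maxima give E, A and E/A (EDV, ESV, SV = EDV − ESV and
EF = 100·SV/EDV come from the curve's extrema). Test–retest precision is
quantified by the coefficient of variation CV = 100·σ/μ, the Bland–Altman
repeatability coefficient RC = 1.96·√(ΣΔF²/(n−1))/F̄ × 100% and Spearman's
ρ.

Because no public dataset accompanies the method, the package includes a
digital beating-heart phantom whose filling waves are raised-cosine steps,
giving a *closed-form* E/A ratio — an exact oracle for validating the whole
acquisition → reconstruction → analysis chain. It is aimed at preclinical
MR physicists and cardiac-imaging methodologists who want to stress-test
retrospective gating choices (NR, NF, rejection rules, gap handling) before
scanning animals.

## Worked example

```r
library(htrcine)

p <- phantom_params()        # mouse LV slice: EDV 36 uL, ESV 9 uL
p
#> LV phantom: EDV 36 uL, ESV 9 uL (EF 75.0%), analytic E/A 1.500
#>   matrix 128, FOV 25.6 mm, slice 1 mm, epicardial radius 5 mm

st <- run_phantom_study(phantom = p, seed = 7)   # full 9.4-min scan, ~30 s CPU
st$coverage
#> coverage: >=1: 100.00%, >=3: 99.92% (mean 12.6 averages)
st$diastolic
#> diastolic_metrics: E 2.334, A 1.558 uL/ms -> E/A 1.498
st$systolic
#> EDV 37.0 uL, ESV 9.6 uL, SV 27.4 uL, EF 74.1%
```

The reconstructed 90-frame CINE recovers the phantom's analytic E/A of 1.50
as 1.498 and its true EF of 75% as 74.1%; 99.9% of k-space cells hold at
least three averages, matching the protocol's design point.

Repeatability statistics work on plain per-subject trial vectors or CSV
tables ([read_trial_table()]):

```r
t1 <- c(1.43, 1.52, 1.38, 1.49, 1.40, 1.36, 1.51, 1.45)  # E/A, trial 1
t2 <- c(1.35, 1.48, 1.42, 1.38, 1.33, 1.41, 1.46, 1.39)  # E/A, trial 2
repeatability_result(t1, t2)
#> repeatability (n=8): CV 3.1 +/- 0.4%, RC 9.8%, bias -2.79%, LoA [-10.68, 5.09]%
```

So for this cohort a between-scan change in E/A smaller than 9.8% is not
distinguishable from test–retest variation.

A thin CLI (`inst/scripts/htrcine`) exposes the same pipeline as
`simulate`, `reconstruct`, `analyze`, `coverage-sweep` and `stats`
subcommands operating on RDS/CSV files.

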