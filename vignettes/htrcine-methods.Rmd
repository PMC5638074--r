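---
title: "Retrospective HTR-CINE reconstruction and diastolic analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retrospective HTR-CINE reconstruction and diastolic analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htrcine)
```

This vignette is the package's own account of the science it implements:
the acquisition and reconstruction model, the phantom that serves as ground
truth, the analysis chain from images to E/A, the repeatability statistics,
and the numerical and design choices behind each.

## 1. The acquisition model

An ungated FLASH sequence acquires one phase-encode line per repetition
time. Line *k* of repetition *r* is acquired at time $(r M + k)\,\mathrm{TR}$
with $M$ the matrix size, sweeping k-space linearly within each repetition.
Defaults follow the high-temporal-resolution mouse protocol:
$\mathrm{TR} = 3.15$ ms, $M = 128$, FOV 25.6 mm, 1 mm slice,
$\mathrm{NR} = 1400$ repetitions (564.5 s of continuous data), later sorted
into $\mathrm{NF} = 90$ cardiac frames.

The simulator computes each line's instantaneous cardiac phase from the
R-wave train, looks the image up in a dictionary of $4\,\mathrm{NF}$
precomputed phases (quantisation error $\le 1/(8\,\mathrm{NF})$ of a cycle,
i.e. an eighth of a reconstruction bin), extracts the corresponding row of
the image's 2-D DFT, and adds i.i.d. complex Gaussian noise per sample.
K-space is stored FFT-shifted: phase-encode row 0 is the most negative
$k_y$, DC at row $M/2$ (zero-based). This convention is fixed so archived
line streams are bit-interpretable.

Two corruption mechanisms make gating matter:

* **Respiration.** While a respiration window is open, the object is
  bulk-shifted along the readout axis by `resp_shift_px` pixels (default 2),
  implemented exactly as the equivalent k-space phase ramp.
* **Heart-rate variability.** Each R-R interval is $60000/h$ ms with
  $h \sim \mathcal{N}(\mu_{HR}, \sigma_{HR})$ truncated at $\pm 3\sigma$,
  i.i.d. per beat. Defaults $588 \pm 38$ bpm. Only cohort-level mean and SD
  are physiologically documented for anaesthetised mice; an i.i.d. per-beat
  model is the simplest generator consistent with them, and it deliberately
  contains no slow drift or respiratory sinus arrhythmia.

Respiration defaults are 55 breaths/min with a 200 ms window: reported
anaesthetised-mouse rates span roughly 49–58 breaths/min, and 200 ms is a
typical inspiration-gate length; together they reject about 18% of lines,
which the coverage margin at NR = 1400 absorbs easily. The default noise
level, `noise_sd = M · blood_intensity / 20`, sets the blood-pool SNR of a
single-average reconstruction to ≈ 20.

One open point in the protocol description is whether the scanner looped
full k-space per repetition or repeated each line NR times; the total line
count is identical either way, and this package fixes
full-k-space-per-repetition with linear ordering (a centric extension point
exists in the code but is not a supported option).

## 2. The beating-heart phantom

The phantom is a concentric-disc short-axis LV slice: blood pool of radius
$r(\varphi) = \sqrt{V(\varphi)/(\pi\,d)}$ ($d$ = slice thickness), a
myocardial annulus to `outer_radius` (5 mm), dark background; bright-blood
FLASH contrast is a fixed intensity triple (1.0 / 0.35 / 0.02), not a
Bloch simulation. The volume model over cardiac phase
$\varphi \in [0, 1)$ is

$$V(\varphi) = \mathrm{ESV} + (\mathrm{EDV} - \mathrm{ESV})
  \left[ E_j(\varphi) + a_E S(\varphi; c_E, w_E)
       + (1 - a_E) S(\varphi; c_A, w_A) \right]$$

with $E_j$ a raised-cosine fall from 1 to 0 over systole $[0, \varphi_{es}]$
and $S$ a raised-cosine step of center $c$ and width $w$. The step's peak
filling rate is $a (\mathrm{EDV}-\mathrm{ESV})\,\pi/(2w)$, so

$$E/A = \frac{a_E / w_E}{(1 - a_E)/w_A}$$

in closed form — the reason raised-cosine steps were chosen over, say,
Gaussian bumps: the pipeline's E/A estimate can be judged against an exact
oracle rather than a numerical one. `phantom_for_ea()` holds
$w_E = w_A = 0.10$ and solves $a_E = EA/(1+EA)$.

Defaults put EDV at 36 µL and ESV at 9 µL (EF 75%), consistent in magnitude
with reported mouse values, with end systole at $\varphi_{es} = 0.35$, the
E wave at $c_E = 0.52$ and the A wave at $c_A = 0.80$. The constructor
enforces disjoint ejection/E/A intervals; genuinely merged E and A waves
(the high-heart-rate failure mode) are exercised in tests by building the
overlapping volume model directly.

Rendering uses 4× supersampling per pixel axis (16 subsamples), giving
area-weighted boundary intensities. This keeps the pixel-counted volume
curve smooth without analytic edge integrals; the residual volume
quantisation is well under the one-boundary-ring bound asserted in tests.

**What the phantom does *not* emulate:** myocardial texture, through-plane
motion, multi-chamber anatomy, coil profiles, flow and off-resonance
artifacts, and any real segmentation ambiguity. Passing the recovery tests
therefore demonstrates that the *reconstruction and analysis chain* is
unbiased under the stated physiology and noise — not that segmentation of
real myocardium is solved.

## 3. Retrospective binning and reconstruction

`bin_kspace()` classifies every line, in precedence order: respiration
(inside a logged window ± `resp_margin`), unassignable (before the first or
after the last R-wave, or overrunning the absolute-mode grid), arrhythmia
(enclosing cycle's R-R deviating more than `rr_reject_frac` from the
median). Survivors are summed into the $\mathrm{NF} \times M$ accumulator;
assigned + rejected always equals total.

Decisions taken where the protocol is silent:

* **Phase mode.** Relative binning (fraction of the enclosing R-R) is the
  default because a 9.4-min ungated scan inevitably spans heart-rate
  drift; absolute binning (fixed bins of median R-R / NF) is retained for
  comparison.
* **Arrhythmia guard.** `rr_reject_frac = 0.2`: cycles deviating > 20%
  from the median R-R are treated as mistimed/missed triggers. At
  $\sigma_{HR}/\mu_{HR} \approx 6.5\%$ this rejects only far-tail beats.
* **Gap handling.** The < 1% of cells left empty borrow the averaged line
  of the nearest frame (circular frame distance, ties to the preceding
  frame) with the same phase encode — preserving spatial-frequency content
  where zero-filling would null it. `zero_fill` remains available.
* **Coverage accounting.** The ≥ 99% / ≥ 3-averages figure is counted per
  (frame, phase-encode) cell, unweighted by k-space region.
* **Frame timing.** Frame 0 starts at the R-wave; frame timestamps are bin
  centers; frame duration is median R-R / NF.

Reconstruction divides each cell by its count and takes the magnitude of
the inverse 2-D DFT. A noiseless, motion-free, fully sampled acquisition
round-trips to the rendered phantom at machine precision (asserted at
$10^{-6}$ relative).

`nr_coverage_sweep()` reruns only the timing/counting part of this pipeline
(no image synthesis), which is how the NR = 1400 design point is verified:
ten replicates at the default physiology put the fill fraction at ≥ 3
averages near 99.9% with sub-0.5% spread.

## 4. From images to function

Manual segmentation and manual peak reading are replaced by deterministic,
parameterised stand-ins (the protocol names no algorithm, so all three
knobs are surfaced):

* `threshold_frac = 0.5`: threshold at half the blood-pool reference
  intensity (max over a 3-pixel disc around the seed, default the image
  center), keep the 4-connected component containing the seed
  (EBImage's flood fill). Halfway between blood and myocardium, the 50%
  contour lands mid-way through partial-volume boundary pixels, making the
  pixel count approximately area-unbiased.
* Volume = count × (FOV/M)² × slice thickness (mm³ = µL);
  `filling_rate()` smooths circularly (moving average, default window 3
  frames, odd) and differentiates by circular central differences — the
  cycle is periodic, so rates integrate to ~0 by construction.
* `detect_ea()` restricts the search to diastole (volume minimum to cycle
  end — the protocol never defines this window; anchoring at the volume
  minimum is the natural automated choice), finds local maxima with
  prominence ≥ `prominence_frac = 0.1` of the maximum rate, and takes the
  earliest as E and the latest as A. One surviving peak sets
  `merged_flag` and leaves the ratio undefined rather than fabricating it.

With 90 frames per cycle a 0.10-wide filling wave spans ~9 frames; the
3-frame smoothing plus central differences attenuates both peaks by the
same factor (equal widths), so the *ratio* is nearly unbiased — the
end-to-end recovery error for E/A ∈ {0.8, 1.0, 1.4, 1.8} stays within
±10% (typically ±5%) under full protocol conditions, and EF within ~1
point of the true 75%.

`combine_slices()` averages aligned per-slice volume curves frame-wise
into the whole-volume curve; `systolic_metrics()` on a list of slices sums
them instead (volumes add, means don't).

## 5. Repeatability statistics

The printed formulas are implemented literally and cross-checked in tests
against brute-force recomputation on a thousand random tables:

* $CV = 100\,\sigma/\mu$, per subject over trials, summarised as cohort
  mean ± SEM. The sample ($n-1$) SD is the default; for two-trial designs
  the $n$ vs $n-1$ choice changes CV by $\sqrt 2$, so it is an explicit
  option rather than a silent convention. Note the two-trial sample SD is
  biased low by $c_4(2) = \sqrt{2/\pi}$; the synthetic-cohort test
  recovers exactly $100\,\sigma_w c_4/\mu$.
* $RC = 1.96\sqrt{\sum \Delta F^2/(n-1)}\,/\,\bar F \times 100\%$ with
  $\bar F$ the grand mean over all $2n$ estimates (the defining text says
  only "mean estimate between trials"; the grand mean is the symmetric
  reading).
* Bland–Altman differences are percent of the pair mean, matching how
  such repeatability plots are reported; limits are bias ± 1.96 SD.
* Spearman's $\rho$ is the Pearson correlation of average ranks; its
  two-sided p-value uses the exact permutation null up to $n = 9$
  (all $n!$ pairings) and the $t$ approximation beyond. Mann–Whitney and
  Wilcoxon signed-rank comparisons are pass-throughs to
  `stats::wilcox.test`.
* `percent_change()` returns $100(\text{ref}-\text{comp})/\text{ref}$ at
  full precision; the integer percentages quoted in cohort summaries are
  display rounding.
* `cohort_filter()` implements the mild-impairment exclusion with strict
  inequalities (EF > 50% *and* LGE/LV < 10%), so boundary subjects stay in.

## 6. Problem sizes, tolerances, degenerate inputs

The test suite runs the full protocol (NR = 1400, 179,200 lines) for the
four E/A-recovery phantoms and the ten coverage replicates, and scales
everything else down (32–64 matrix, few repetitions) — small enough that
the whole suite completes in a few minutes on one CPU while the headline
checks still run at study scale. Event-log timestamps are written with six
decimals (ms), so round trips are exact to ≪ 1 µs. Bit-reproducibility is
guaranteed per seed; all simulators restore the caller's RNG state.

Degenerate inputs fail loudly by design: empty segmentations, zero-mean
CVs, zero-reference percent changes, constant correlation inputs, a
phase-encode row empty at every frame, mismatched stream/log pairs and
malformed CSVs all raise classed errors (`htrcine_*` conditions) rather
than returning repaired values.

## 7. Known limitations

* Single 2-D slice; no multi-slice interleaving or 3-D coverage. The
  slice-combination and slice-summing utilities operate on curves, not on
  interleaved acquisitions.
* ECG events are taken as given; there is no self-gating from k-space DC,
  and no simulation of trigger-detection noise beyond whole-cycle
  rejection.
* No iterative or compressed-sensing reconstruction; gap handling is
  nearest-frame copying, which slightly smooths fast motion at
  sparsely-covered frames.
* The phantom's analytic E/A oracle presumes non-overlapping filling
  waves; genuinely merged physiology can only be *flagged*, not ratioed,
  which mirrors how such cycles are treated in practice.
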