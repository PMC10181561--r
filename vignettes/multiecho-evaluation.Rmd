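---
title: "Evaluating multi-echo EPI for resting-state fMRI: models, phantom design and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-echo EPI for resting-state fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

A three-echo EPI protocol (TE 11.9/29.8/47.8 ms) costs repetition time:
TR grows from 700 ms (single echo at TE 30 ms) to 940 ms, so for a fixed
scan duration the single-echo arm collects about 34 % more frames.
T2\*-weighted echo combination repays that cost by averaging down thermal
noise while preserving BOLD contrast. `meepi` implements both arms of this
trade as a fully synthetic, ground-truth-known experiment so that every
downstream claim — TSNR gain, explained variance, coverage recovery,
connectivity detection versus scan length — can be measured rather than
argued.

## Signal model

Every voxel inside the head follows mono-exponential transverse decay,

$$S(v, e, t) = S_0(v)\, e^{-TE_e / T_2^*(v,t)} + n_\text{struct}(v,t) + n_\text{therm}(v,e,t).$$

BOLD enters **multiplicatively through T2\***: the planted network time
courses modulate $T_2^*(v,t)$ about its baseline, so the fractional BOLD
amplitude grows with TE while additive noise does not. This is the
mechanism that makes the combination worthwhile: with matched-filter
weights $w_e \propto TE_e e^{-TE_e/T_2^*}$ (normalised to sum 1, computed
once from temporal means and held fixed so the combination stays linear),
thermal variance shrinks by $\sum_e w_e^2$ while the BOLD amplitude is
essentially preserved.

Structured noise is shared across echoes (the physiology, motion and
drift that corrupt one echo corrupt all three), so echo combination
neither removes nor amplifies it; that is the regression's job. Thermal
noise is drawn independently per echo, voxel and frame with equal SD per
echo at each voxel.

## Phantom design

`generate_phantom()` builds concentric compartments inside an ellipsoidal
head: a grey-matter shell, white-matter interior and a small ventricle-like
CSF core. Baseline T2\* is 66 ms in GM — the typical cortical value at
3 T — with 53 ms (WM) and 100 ms (CSF) as literature-typical stand-ins,
plus 2 ms Gaussian spatial jitter. S0 is 1000/950/1200 (arbitrary units)
with 1 % jitter.

**Dropout region.** An inferior GM ball (~3 % of GM) receives a short
T2\* of 10 ms to emulate susceptibility-induced signal loss. The value is
deliberately severe: at the middle echo a 10 ms voxel retains only ~5 % of
its equilibrium signal and falls below the 0.1-of-median intensity clip
used for EPI coverage masks, while the combined image (first-echo
dominated there) retains ~21 % and stays inside the mask. A milder 25 ms
region would never leave the mask, and the coverage-recovery property the
combination is known for would be unobservable in the phantom. The same
region lifts the GM-mean TSNR gain of combination: at T2\* = 66 ms the
matched-filter ceiling for these echo times is only ≈ 1.57, whereas short-
T2\* voxels gain far more; with a ~3 % dropout share the default phantom
lands its GM gain at ≈ 1.7, inside the 1.6–2.2 band that three-echo
studies report against single-echo references. This calibration is part
of the phantom's definition and is not adjusted per experiment.

**Noise calibration.** Each component's amplitude is set per voxel so that
it contributes a configured fraction of the total temporal variance at the
middle echo; the default fractions are

| tissue | bold | physio | motion | drift | thermal |
|--------|------|--------|--------|-------|---------|
| GM     | 0.03 | 0.10   | 0.04   | 0.08  | 0.75    |
| WM     | 0.00 | 0.04   | 0.04   | 0.08  | 0.84    |
| CSF    | 0.00 | 0.25   | 0.05   | 0.10  | 0.60    |

with a total temporal coefficient of variation of 2 % — the regime of a
modern 3 T acquisition, where thermal noise dominates at this voxel size.
BOLD applies only at voxels belonging to a planted network map (~25 % of
GM). Because every amplitude (including thermal) scales with the voxel's
own baseline, the injected fractions are exact per voxel, which is what
makes parameter-recovery tests sharp. The price is a spatially varying
thermal SD, which real scanners do not produce; air voxels carry the
median GM thermal SD so background-based SNR estimation still works. This
is a deliberate accuracy-over-realism choice and a known limitation.

Physiological noise is quasi-periodic intensity modulation built from
first- and second-order Fourier terms of generated cardiac (~1.05 Hz) and
respiratory (~0.30 Hz) phase traces with slow phase jitter; per-voxel
coefficients are random. Motion parameters are six random walks with a
per-TR displacement norm of ~0.028 mm — the scale of still, healthy
volunteers — with optional injected spikes (> 0.2 mm persistent steps) to
exercise censoring. Drift is a random low-order Legendre polynomial per
voxel. Network time courses are unit-variance noise restricted to
0.01–0.08 Hz.

**What the phantom does not emulate:** realistic anatomy, k-space/EPI
artefacts (ghosting, distortion), Rician noise statistics (Gaussian is
justified at the simulated SNR but would bias very-low-signal voxels),
spatially displacing motion (motion enters only as nuisance waveforms),
and between-subject anatomical variability (subjects share one anatomy
and differ in noise and time-course realisations). Passing tests
therefore demonstrate correctness of the estimators and the internal
consistency of the physics, not performance on real cohorts; the
real-data gains reported for high-slew scanners remain empirical
observations this package can parallel but not reproduce.

## Echo combination and T2\* fitting

T2\* is fitted by ordinary least squares of log temporal mean on TE —
fast, standard, and exact on noise-free data. Nonlinear decay fitting
buys little at three echoes and is out of scope. Estimates are clamped to
[2, 300] ms; voxels with a nonpositive mean at any echo or a nonnegative
slope are invalid and receive the middle echo time as fallback T2\*,
which keeps combination weights defined (uniform weights are used at
invalid voxels). The SNR numerator is always the pre-regression temporal
mean, so TSNR (after regression) and TSNR0 (before) differ only in the
denominator.

## Nuisance regression and explained variance

The regressor families follow the conventional resting-state recipe:
13 physiological columns (sin/cos of cardiac and respiratory phase at
orders 1–2, plus RVT at lags 0–4 frames), 12 motion columns (6 parameters
and backward first differences), 3 CSF principal components, a per-voxel
local white-matter regressor (mean of eroded WM within a 15 mm sphere,
global-WM fallback when the neighbourhood is empty), and Legendre drift of
order `1 + floor(duration/150 s)`. Frames are censored when the Euclidean
norm of the per-TR parameter difference exceeds 0.2 mm, with rotations in
degrees taken as mm-equivalent (the AFNI enorm convention; no rotation
radius is assumed).

All groups are fitted **jointly in one OLS per voxel** rather than
sequentially. Sequential regression can re-introduce variance a previous
step removed; joint fitting makes the marginal explained-variance
partition exact: for each step,

$$R^2_\text{step} = 1 - SS_\text{total}/SS_\text{step},$$

with $SS_\text{total}$ the residual sum of squares under the full design
and $SS_\text{step}$ under the design omitting that group — nested, so
$R^2 \in [0,1]$. For the combination step, $SS_\text{step}$ is the
full-design residual of the mid-echo-only series and $SS_\text{total}$
that of the combined series; no time-course scaling is applied before
partitioning. The per-voxel local-WM column is handled by a rank-one
update after projecting out the shared design — algebraically identical
to refitting each voxel with its own column, at a fraction of the cost.
No prewhitening is applied (resting-state connectivity convention).

Two numerical properties of the statistic are worth knowing. First, it
carries a small positive offset of about $(1-f)\,p_\text{step}/(T-p)$
when the omitted group has $p_\text{step}$ free columns fitting $T$
frames of noise — about 0.025 for the 13 physio columns at 500 frames.
Second, the removed-by-combination series (combined minus mid-echo,
demeaned) is dominated by re-weighted thermal noise and should be nearly
uncorrelated with every regressor and with its spatial neighbours; the
package reports root-mean-square correlations to verify this, in contrast
to the local-WM regressor, which is strongly shared between neighbours by
construction.

## Connectivity and detection

Residuals are bandpass filtered by frequency-domain projection with hard
edges at 0.009–0.1 Hz (DC retained so series keep their means) and
smoothed with a separable 4 mm FWHM Gaussian (edge-renormalised).
Repeated runs are concatenated after per-voxel z-scoring. Correlations
are clipped to ±(1 − 10⁻⁷) before the Fisher transform. GCOR is computed
by the O(VT) mean-unit-norm identity, on the bandpassed series (the
pre/post-bandpass choice is not standardised anywhere; post is used and
stated). Group seed maps are one-sample tests with the centred GCOR as
covariate; paired edge screening requires both significance (uncorrected
p < 0.01) and magnitude (|Fisher z| > 0.3 in either group); edges with
zero-variance differences get p = 1 so identical groups yield no edges.

Group inference is parametric — voxelwise one-sample t with
Benjamini–Hochberg FDR at q = 0.001 and a positive-mean requirement —
rather than permutation testing, for desk-scale determinism; on the
phantom's independent-noise nulls the parametric assumptions hold by
construction. Dual regression is the standard two-stage least squares
(spatial, then temporal, both with intercepts) and is an exact inverse on
noiseless mixtures, which the tests assert at 10⁻⁸ relative error.

The scan-length analysis truncates each subject's series to the frame
count covering 2–9 minutes (ceiling convention), reruns dual regression
and group thresholding per length, and scores sensitivity, false-positive
rate and accuracy against the planted network supports. On the default
phantom sensitivity rises from ~0.5 at 2 min toward ~0.97 at 9 min while
FPR stays below 0.01 — the false positives are genuine neighbourhood
leakage from spatial smoothing at network borders, not threshold failure.

## Protocol arithmetic conventions

Three conventions are fixed by cross-checking against the reference
protocol's printed values:

* **Ernst angles are truncated**, not rounded, to whole degrees:
  arccos(e^(−700/1400)) = 52.68° prints as 52 (rounding would give 53)
  and arccos(e^(−940/1400)) = 59.22° as 59, at T1 = 1.4 s.
* **Frame counts use the ceiling**: 9 min covers 772 frames at TR 700 ms
  (round-half would give 771) and 575 at TR 940 ms.
* **Per-echo overhead is an explicit field**: the EPI readout is
  94/2 × 352 µs = 16.544 ms, while the achieved inter-echo spacing is
  17.9 ms; the 1.356 ms difference (fly-back, phase correction, ramps) is
  a `protocol_spec` field defaulting to the value that reproduces the
  reference timing, since gradient waveform detail is out of scope.
* **Efficiency scales as TSNR·√frames.** The scan-time comparison behind
  the "2.4× longer single-echo scan" figure is only consistent with
  square-root frame scaling (the standard detection-efficiency law), not
  with the literal product of TSNR and frame count: gains of 1.8/2.0
  yield 1.553/1.726, matching the printed 1.56/1.74 up to rounding of the
  per-subject gains, and 1.8² × (700/940) = 2.41 ≈ 2.4. The package
  reports full precision.

## Problem sizes

The package's test and default-study sizes are chosen so a complete run
fits comfortably on one CPU core: a 24 × 24 × 16 grid (~3500 head
voxels), 3 networks, 5 subjects sharing one anatomy, two 300-frame
multi-echo runs concatenated and truncated to 575 frames (9 min at TR
940 ms) against 772 single-echo frames, and a 2–9 min detection curve.
The full-resolution acquisition grid (94 × 94 × 52) is supported by the
same code paths but is not the default. The end-to-end study
(`run_study()`) is bit-reproducible under a fixed seed: all randomness
flows from named seeds, and every output table is stamped with the seed
and a configuration hash.

## Known limitations

* Gaussian (not Rician) noise; no EPI geometric distortion or ghosting;
  no slice-timing or realignment stage (synthetic motion never displaces
  voxels).
* The thermal noise SD varies spatially with baseline signal (exact
  variance fractions per voxel) instead of being spatially flat.
* Subjects share anatomy; between-subject variance is noise-only, so
  group t statistics are better behaved than in real cohorts — detection
  curves should be read as upper bounds on separability, not forecasts.
* TE-dependence denoising (separating BOLD from non-BOLD by S0 vs R2\*
  fits) is intentionally out of scope: the package isolates the value of
  the combination step alone.
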