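# meepi

Quantifying what multi-echo EPI buys in resting-state BOLD fMRI.

High-performance gradient systems make it possible to acquire three
echo-planar images per excitation (TE ≈ 11.9/29.8/47.8 ms) at the spatial
and temporal resolution (≤ 2.5 mm isotropic, TR < 1 s) that large
resting-state studies demand. The multi-echo images can be merged by
T2\*-weighted *optimal combination*,

&nbsp;&nbsp;&nbsp;&nbsp;*w<sub>e</sub> ∝ TE<sub>e</sub> · exp(−TE<sub>e</sub>/T2\*)*, normalised so Σ*w<sub>e</sub>* = 1,

which averages down thermal noise while preserving BOLD contrast, because
BOLD acts multiplicatively through T2\* in the mono-exponential signal
model *S(TE) = S0 · exp(−TE/T2\*)*. The open question for protocol design
is whether this gain survives the cost: the extra echoes stretch TR from
700 ms to 940 ms, so a single-echo acquisition collects ~34 % more frames
in the same scan time.

`meepi` is an R package for answering that question at desk scale, for
methodologists and sequence developers. It provides:

* **a synthetic multi-echo phantom** with fully known ground truth —
  tissue compartments with literature T2\* (GM 66 ms, WM 53 ms, CSF
  100 ms), a short-T2\* signal-dropout subregion, planted low-frequency
  network maps, and calibrated physiological / motion / drift / thermal
  noise fractions (`generate_phantom()`, `simulate_multiecho()`,
  `write_dataset()` for NIfTI + TSV + JSON output);
* **echo combination and its bookkeeping** — voxelwise log-linear T2\*
  fitting, matched-filter weights, SNR/TSNR summaries (`fit_t2star()`,
  `oc_weights()`, `combine_echoes()`, `snr_tsnr()`);
* **nuisance regression** — frame censoring at 0.2 mm/TR, 13 RETROICOR+RVT
  regressors, 12 motion regressors, 3 CSF principal components, a
  per-voxel local white-matter regressor, Legendre detrending, and the
  marginal explained-variance statistic
  *R²<sub>step</sub> = 1 − SS<sub>total</sub>/SS<sub>step</sub>*
  (`build_nuisance_design()`, `fit_nuisance_glm()`, `marginal_r2()`);
* **connectivity and network detection** — bandpass (0.009–0.1 Hz) and
  4 mm smoothing, Fisher-z ROI/seed maps, GCOR, dual regression against
  group maps, Benjamini–Hochberg FDR thresholds, and
  sensitivity / false-positive-rate / accuracy versus scan length
  (`roi_fc_matrix()`, `seed_fc_map()`, `dual_regression()`,
  `detection_metrics()`, `scan_length_curve()`);
* **acquisition-timing arithmetic** — inter-echo spacing, EPI readout
  duration, Ernst angles, frame counts, and TSNR-per-scan-time
  efficiency (`protocol_spec()`, `tsnr_time_efficiency()`);
* **an end-to-end study runner** (`run_study()`) producing the full set
  of single- vs multi-echo comparison tables, bit-reproducible under a
  fixed seed.

## Worked example

```r
library(meepi)

truth <- generate_phantom(seed = 1)                   # 24 x 24 x 16 phantom
sim   <- simulate_multiecho(truth, reference_protocol("multi"),
                            n_frames = 300, seed = 2)
head  <- phantom_mask(truth, "head")

t2  <- fit_t2star(sim$series, mask = head)
median(t2$t2star_ms[phantom_mask(truth, "gm")])       # 65.8 ms (truth: 66)

cmb <- combine_echoes(sim$series, oc_weights(t2))
des <- build_nuisance_design(
  300, 940,
  physio = build_physio_regressors(sim$physio),
  motion = build_motion_regressors(sim$motion),
  csf    = build_csf_regressors(echo_data(sim$series),
                                phantom_mask(truth, "csf")),
  censor = censor_frames(sim$motion)$keep)

tiss  <- list(gm = phantom_mask(truth, "gm"), wm = phantom_mask(truth, "wm"))
st_me <- snr_tsnr(cmb, tiss, design = des, air_mask = phantom_mask(truth, "air"))
st_oe <- snr_tsnr(echo_data(sim$series), tiss, design = des,
                  air_mask = phantom_mask(truth, "air"))
st_me[, c("tissue", "snr_mean", "tsnr0_mean", "tsnr_mean")]
#>   tissue snr_mean tsnr0_mean tsnr_mean
#> 1 gm         93.6       74.4     103.
#> 2 wm         81.9       71.8      92.6
st_me$tsnr_mean[1] / st_oe$tsnr_mean[1]               # GM TSNR gain: 1.69
```

The combined series has a grey-matter TSNR 1.69 times that of the middle
echo alone — inside the 1.6–2.2 band this phantom is calibrated to, and
short of the theoretical matched-filter ceiling only because the residual
still carries BOLD signal, which the combination rightly preserves. The
marginal explained variance of the combination step,

```r
vp <- marginal_r2(cmb, des, "combine", head, tissue_masks = tiss,
                  reference = echo_data(sim$series))
vp$tissue_summary
#>   tissue step    r2_mean  r2_sd
#> 1 gm     combine   0.621 0.0457
#> 2 wm     combine   0.639 0.0356
```

shows the combination removing ~62 % of the residual variance in GM and
slightly more in WM — white matter carries less BOLD, so a larger share of
its variance is thermal and hence removable. Frame-count economics of the
two protocols:

```r
tsnr_time_efficiency(1.8, 700, 940)
#> $efficiency_gain
#> [1] 1.553308
#> $scan_time_parity_factor
#> [1] 2.412766
```

at a TSNR gain of 1.8, the multi-echo protocol is 1.55 times more
efficient per unit scan time (TSNR·√frames scaling), i.e. the single-echo
arm would need ~2.4 times the scan time to match it.

The full comparison — coverage recovery in the dropout region, ROI-edge
screening, seed-FC extents with a GCOR covariate, and detection metrics
versus scan length for both arms — is produced by

```r
study <- run_study(study_config(seed = 1))
study$tables$curve       # sensitivity / FPR / accuracy, 2..9 min
```

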