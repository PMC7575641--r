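# v1tune

Analysis pipeline for awake-mouse primary visual cortex (V1)
electrophysiology centred on perceptual experience: after days of
repeated exposure to one grating, V1 develops familiarity-evoked theta
oscillations (4–8 Hz, stimulus-locked), and experience reshapes
orientation, spatial-frequency and contrast tuning. v1tune implements
the full measurement chain for such studies —

* **LFP**: zero-phase FIR preprocessing (1-kHz decimation, 60-Hz
  notch), layer-IV channel selection by the strongest early negative
  deflection, Morlet-wavelet time–frequency power (40 wavelets,
  2–80 Hz, cycles 3–10, dB-normalised to a pre-onset baseline), band
  power in theta/alpha/beta/low-γ/high-γ, and intertrial phase
  coherence $\mathrm{ITPC}_{tf} = |N^{-1}\sum_r e^{ik_{tf}}|$;
* **Single units**: PSTH (10-ms bins, Gaussian smoothing) and z-score
  $z = (FR - \overline{baseFR})/\mathrm{sd}(baseFR)$; Wilcoxon
  responsiveness; the oscillation-duration statistic (time of the last
  smoothed-z peak above 1.5); OSI
  $\sqrt{(\sum r_k \sin 2\theta_k)^2 + (\sum r_k \cos 2\theta_k)^2}/\sum r_k$;
  bounded multi-start least-squares fits of the double-Gaussian
  direction model, difference-of-Gaussians SF model and hyperbolic-ratio
  contrast model $R(c) = R_0 + R_{max} c^n/(c_{50}^n + c^n)$, gated by
  the fit-error statistic $\sum(y_i-f_i)^2/\sum(y_i-\bar y)^2 < 0.7$;
* **Decoding**: LDA on population spike counts (0.05–0.5 s) with
  stratified 4-fold × 5-repeat cross-validation and an enforced
  ≥ 30-trial test-fold floor;
* **Statistics**: Kruskal–Wallis omnibus + pairwise Mann–Whitney U
  comparisons across genotypes/conditions;
* **Synthetic cohorts**: a ground-truth-labelled generator
  (inhomogeneous-Poisson units with the same tuning models, multichannel
  LFP with a laminar evoked profile and phase-locked theta bursts,
  Phy-style sorted-output layout) encoding experience- and
  genotype-dependent effects, so every stage is verifiable without
  recorded data.

It is aimed at systems neuroscientists who want a tested, reusable
implementation of these analyses, and at anyone needing a calibrated
synthetic benchmark for them.

## Worked example

Simulate a two-genotype post-experience cohort, run the blind analysis,
and test the genotype contrast:

```r
library(v1tune)

cohort <- simulate_cohort(default_cohort_config(n_units = 30), seed = 51,
                          n_familiar = 200, orientation_repeats = 8,
                          sf_repeats = 8, contrast_repeats = 4,
                          conditions = "post_familiar",
                          genotypes = c("WT", "KO"))
res <- analyze_cohort(cohort, decoding = FALSE)
cmp <- compare_genotypes(res$units, metrics = c("osc_duration_s", "osi"))
cmp$osc_duration_s
cmp$osi
```

```
<group_comparison> osc_duration_s: Kruskal-Wallis chi^2 = 15.6, p = 7.63e-05
  n = KO:30, WT:30
  KO vs WT: U = 717.5, p = 7.87e-05 (higher)
<group_comparison> osi: Kruskal-Wallis chi^2 = 23.2, p = 1.44e-06
  n = KO:30, WT:30
  KO vs WT: U = 124, p = 1.49e-06 (lower)
```

The knockout units oscillate longer after experience (Mann–Whitney
p ≈ 8×10⁻⁵) and are less orientation-selective (lower OSI,
p ≈ 1.5×10⁻⁶) — the effect structure encoded in the generator's priors
and recovered here from spikes alone: the analysis path never reads the
ground truth.

## The analysis workflow

Numbered drivers under `analysis/` run the full study on a synthetic
cohort and write plain-text tables under `results/`:

| stage | script | output |
|---|---|---|
| 1 | `01_simulate_cohort.R` | `scratch/cohort/` (Phy-style recordings), `results/cohort_summary.tsv` |
| 2 | `02_lfp_spectral.R` | `results/lfp_band_power.tsv`, `results/itpc_summary.tsv` |
| 3 | `03_unit_tuning.R` | `results/unit_metrics.tsv` |
| 4 | `04_decoding.R` | `results/decoding.tsv` |
| 5 | `05_group_comparison.R` | `results/group_comparisons.tsv` |

Stages 2–5 read the written recordings (spike times, cluster labels,
flat-binary LFP + JSON sidecar, trial CSV) rather than in-memory
objects, so they double as a template for analysing real sorted
recordings in the same layout.

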