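---
title: "Methods: synthetic V1 cohorts, familiarity-evoked oscillations, tuning fits, and decoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic V1 cohorts, familiarity-evoked oscillations, tuning fits, and decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

v1tune implements the analysis chain used in awake-mouse V1
electrophysiology studies of perceptual experience: time-frequency
analysis of the layer-IV local field potential, single-unit tuning
quantification, a duration statistic for familiarity-evoked theta-locked
spiking, population decoding, and the nonparametric group-comparison
pattern that ties them together. Because such studies rarely deposit raw
recordings, the package pairs every analysis with a synthetic-cohort
generator whose ground truth makes each stage verifiable end to end.
This vignette documents the models, the conventions chosen where the
experimental literature leaves them open, and what the synthetic tests
do and do not establish about real recordings.

## The generative model

A ground-truth unit is an inhomogeneous Poisson process. Its rate on a
trial with stimulus $s$ is

$$\lambda(t) = r_0 + A(s)\, g(t)\, \big[1 + m \cos(2\pi f_{osc}
t)\big]_{t \in (0, d_{osc}]}$$

where $r_0$ is the baseline rate, $A(s)$ the tuned response amplitude,
and $g(t)$ a stimulus-locked envelope: a 20-ms linear ramp at onset,
sustained at 1 through the stimulus (and through the oscillation window
when enabled), then exponential decay with $\tau = 100$ ms. The
oscillatory factor — modulation depth $m$, frequency $f_{osc}$ (4–8 Hz),
duration $d_{osc}$ — is phase-locked to stimulus onset (cosine phase
zero at $t = 0$), which is what makes the oscillation survive trial
averaging and gives the characteristic banded PSTH. Spikes are drawn by
thinning against the analytic rate bound $r_0 + A(1+m)$, so the draw is
exact rather than discretised.

$A(s)$ comes from the three classical tuning models, which are also the
models the analysis side fits:

* **Direction**: double Gaussian
  $R(\theta) = R_0 + R_p e^{-d_p^2/2\sigma^2} + R_n e^{-d_n^2/2\sigma^2}$
  with $d_p = \theta - \theta_p$ and $d_n = \theta - \theta_p + 180$,
  both circular differences; a common width $\sigma$ for the preferred
  and null lobes.
* **Spatial frequency**: difference of Gaussians (excitatory minus
  inhibitory component, 7 parameters), evaluated on a log2-cpd axis.
* **Contrast**: hyperbolic ratio (Naka–Rushton)
  $R(c) = R_0 + R_{max}\, c^n / (c_{50}^n + c^n)$.

The simulated LFP is pink noise per channel plus a stimulus-evoked
negative transient peaking 50 ms after onset, scaled by
$e^{-|ch - ch_{IV}|/6}$ so the current sink is deepest at the nominal
layer-IV channel; post-familiar recordings add a decaying theta burst
with trial-consistent phase, and a 60-Hz sinusoid can be mixed in to
exercise the notch stage.

## Cohort priors: what the generator emulates

`default_cohort_config()` encodes the qualitative effect structure the
pipeline is designed to detect, as per-genotype, per-condition priors
(each a mean/SD pair; truncated-normal draws):

* Naive (`pre`) WT, HET and KO units are drawn from matched priors
  (tuning width 25 ± 5°, c50 0.30 ± 0.08, no oscillation), except that
  the cardinal-orientation preference bias (55%) is restricted to WT.
* After experience (`post_familiar`) all genotypes oscillate (depth
  0.8), but duration priors order WT < HET < KO (0.7, 1.0, 1.25 s);
  KO tuning width broadens to 42 ± 8° and its low-spatial-frequency
  suppression weakens (target LSFS 0.65 vs 0.35); HET carries the
  contrast effects (c50 0.45, exponent 1.6).
* `post_novel` units respond to the checkerboard without oscillation,
  with a weaker KO response amplitude.

Low-SF suppression is controlled mechanistically: the inhibitory DoG
component is anchored at the lowest tested spatial frequency and its
amplitude is solved per unit so the model's low-SF/preferred-SF response
ratio equals the drawn LSFS target (a negative inhibitory amplitude is a
low-SF shoulder — suppression weaker than the excitatory tail alone).
The analysis code never sees these priors: genotype effects live
entirely in the generator, and every group difference the pipeline
reports is recovered blind from simulated spikes.

## Stimulus protocols

The familiarity protocol presents one grating (30°, 0.04 cpd, 2 Hz,
full contrast, 0.4 s) in blocks of `n_per_day` × `n_days` with
interstimulus intervals drawn uniformly from 3–5 s; the first onset sits
one ITI draw after the session origin so every gap is a draw from the
stated range. Tuning protocols are balanced and pseudorandom: 12
directions at 30° spacing; 6 octave-spaced spatial-frequency bands
(0.0075–0.24 cpd) with ITIs of at least 4 s to avoid adaptation; 5
contrasts (6.25–100%) of a vertical static grating.

Spatial-frequency stimuli are band-pass filtered white noise. The
protocol fixes only the band centres, so band edges are a convention
here: geometric (half-octave) edges, which make the octave-spaced bands
abut exactly without overlap. Filtering uses a raised-cosine annular
mask in the 2-D Fourier domain (hard-edged masks ring), with a
half-octave roll-off; the image is rescaled to [0, 1] around an exact
mean of 0.5 by zeroing the DC component and scaling symmetrically. A
fresh exemplar is drawn per trial, mirroring how low-SF stimuli must
sample receptive fields.

## LFP analysis conventions

Raw traces are decimated to 1 kHz behind a zero-phase FIR anti-alias
filter, and 60-Hz noise is removed with a symmetric linear-phase FIR
band-stop (55–65 Hz, order 500) run forward and backward
(`signal::filtfilt`), so the net group delay is zero. The layer-IV
channel is the one whose trial-averaged trace is most negative within
100 ms of onset, ties to the shallowest channel; all-constant traces are
rejected as indeterminate rather than silently returning channel 1.

Time-frequency decomposition uses 40 complex Morlet wavelets, centre
frequencies log-spaced 2–80 Hz and cycle counts log-spaced 3–10 across
the family, unit-energy normalised. Power maps convolve the
trial-averaged (evoked) LFP by default — matching the analysis the
oscillation literature reports — with a per-trial (induced) option
behind the `evoked` flag; ITPC is necessarily per-trial:
$\mathrm{ITPC}_{tf} = |N^{-1}\sum_r e^{i k_{tf}}|$, summarised over the
first 0.5 s after onset and not computed above 40 Hz, where trial counts
and display refresh limit phase estimation.

Two choices here are conventions, not field facts: the dB baseline
window is −0.5 to −0.1 s before onset (ending early keeps wavelet
smearing of the onset response out of the baseline; low-frequency
wavelets extend ±0.5 s), and epochs are reflection-padded for the
convolution with the first/last few cycles treated as unreliable. Band
power averages the map over theta (4–8), alpha (8–12), beta (12–30),
low gamma (30–50) or high gamma (50–80 Hz) in a 0–1 s post-onset
window.

## Single-unit statistics

PSTHs use 10-ms bins pooled across trials, converted to Hz, and
smoothed with a Gaussian kernel of 100-ms width. The kernel width is
read as FWHM (SD ≈ 42.5 ms): a 100-ms SD would attenuate a 6-Hz
modulation by a factor of ~10³ and no theta-locked peak structure would
survive smoothing, so the FWHM reading is the only one consistent with
detecting theta-banded PSTHs at all. Smoothing renormalises the kernel
at the epoch edges, conserving area.

The z-score trace is $(FR - \overline{baseFR})/\mathrm{sd}(baseFR)$
with baseline statistics from the pre-onset window; zero-SD baselines
(silent units) are excluded from z-based analyses by an explicit error
rather than an Inf. Responsiveness is a one-sided paired Wilcoxon
signed-rank test of stimulus-window versus equal-length baseline-window
counts per trial (only upregulating units qualify; an all-zero
difference vector is fail-safe non-responsive).

Oscillation duration is the time of the last strict local maximum of
the smoothed z trace after onset that exceeds z = 1.5, and 0 when no
peak qualifies. No prominence threshold is applied — any strict local
maximum counts. Two consequences matter for interpretation: the
statistic saturates at the epoch length, and under few trials late
noise peaks inflate it (in both groups equally). The recovery suite
therefore operates at the 200-presentation scale of the familiarity
protocol, where the estimator's median error is well under 50 ms; the
cohort analyses use the same scale for the familiar block.

OSI is the resultant length on the doubled-angle circle,
$\sqrt{(\sum r_k \sin 2\theta_k)^2 + (\sum r_k \cos 2\theta_k)^2} /
\sum r_k$; negative mean responses are rectified to zero first (the
measure assumes nonnegative weights), and an all-zero curve yields NA
rather than 0/0.

Curve fits are bounded multi-start Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`): ≥ 9 deterministic starts per model (peak-anchored
location starts crossed with several width/slope starts), box bounds
$\sigma \in [5°, 180°]$, $c_{50} \in [0.01, 1]$, $n \in [0.5, 6]$,
positive DoG widths; the lowest-residual convergent start wins, ties to
the first. The DoG is fitted on the log2-SF axis by default (the levels
are octave-spaced; a linear-axis flag exists) and, because its 7
parameters exceed the 6 level means, it is fitted to the per-trial
responses; with means only, the points are duplicated — an equal
reweighting with the same least-squares optimum — to satisfy the
solver's residual-count requirement. Fit quality is
$\sum(y_i - f_i)^2 / \sum(y_i - \bar y)^2$ (0 perfect, 1 no better
than the mean) and downstream analyses include only fits below 0.7.
Derived metrics: tuning width $\sigma$; preferred SF as the empirical
argmax level; FWHM of the fitted DoG above its baseline, in octaves;
LSFS as the empirical lowest-SF/preferred-SF response ratio; $c_{50}$
and $n$ from the contrast fit. The tuning-curve response window is
0.05–0.5 s after onset, matching the decoding count window.

## Decoding

Population decoding uses linear discriminant analysis (`MASS::lda`) on
per-trial spike counts in 0.05–0.5 s, with stratified 4-fold
cross-validation repeated 5 times under reshuffled folds. Stratification
is a deliberate choice at small trial counts (balanced classes per
fold). A fold plan whose test folds would drop below 30 trials is an
explicit error naming the constraint, so protocol repeat counts are
chosen to satisfy it (12/20/24 repeats for orientation/SF/contrast).
Accuracy is reported as mean ± SEM over the 20 fold×repeat scores — the
unit of replication, since the reporting convention leaves it open.
Units with zero training variance are dropped per split; collinearity
warnings (more units than trials) are suppressed as expected; a
perfectly separated training fold (zero within-class variance) gets an
infinitesimal symmetric jitter to make the covariance estimable without
moving the decision boundary.

## Group comparisons

The comparison pattern is a Kruskal–Wallis omnibus across genotypes
followed by pairwise two-sided Mann–Whitney U tests, uncorrected by
default — mirroring common practice in this literature — with a Holm
option behind a flag for users who want familywise control. Effect
direction is the sign of the median difference. Units are pooled across
animals within genotype; the generator has no animal level, and the
unit-level n's reported in this literature indicate pooling.

## Problem sizes and numerical choices

The bundled analyses and tests run at deliberately modest sizes chosen
for tight feedback loops: cohorts of 25–30 units per genotype ×
condition, 200-trial familiarity blocks, 16-channel probes with
20-trial LFP blocks, 100-unit recovery suites, and 200-replicate null
calibrations with 25-unit groups. At these sizes the encoded effects
are detected with large margins and the null calibration brackets the
nominal 5% false-positive rate. Seeds thread explicitly through every
stage (`sub_seed` derives 32-bit per-recording, per-unit streams from
one master seed), so cohorts, analyses and cross-validation folds are
bit-reproducible.

## What the synthetic tests do and do not show

Passing recovery and calibration suites establish that the
implementation is faithful: formulas match their definitions exactly,
estimators recover known parameters at realistic noise levels, the
false-positive rate of the comparison pattern is nominal, and the
end-to-end pipeline detects effect structure it was never told about.
They do not establish that real V1 recordings satisfy the generative
assumptions — Poisson spiking (real units are over- or under-dispersed
and correlated), a shared envelope shape across stimuli, oscillations
phase-locked to onset with a single frequency, noise-free trial
alignment, or an LFP whose laminar profile is a clean exponential.
Drift, bursting, waveform-quality issues and animal-level variance are
explicitly out of scope. Conclusions about real data should rest on the
statistics' known robustness properties (rank tests, cross-validated
accuracy), not on the simulator.
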