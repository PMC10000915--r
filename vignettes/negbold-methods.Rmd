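---
title: "Methods: quantifying neurovascular decoupling under mild disinhibition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying neurovascular decoupling under mild disinhibition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negbold)
```

## Scope and model

`negbold` analyses block-design sensory-stimulation experiments in which
three modalities are recorded around a pharmacological manipulation of
cortical inhibition: BOLD fMRI trial series, raw extracellular voltage, and
tissue oxygen (PO2). The shared timing grammar is a `stim_paradigm`: 25
baseline + 20 stimulation + 20 post-stimulus images at TR 2 s, ten trials,
with the first five images of every trial discarded while the MR signal
reaches equilibrium. All three pipelines consume this object so that
stimulation windows, onsets, and the 150 ms trigger-to-stimulus delay are
defined once.

The package assumes registered inputs: volume registration is out of scope,
and residual head movement is handled purely as an exclusion criterion (a
centre-of-mass displacement metric per trial, limit 1 voxel by default).

## BOLD pipeline

**Averaging.** Trials surviving motion QC are averaged image-wise after
discarding the leading images. Voxel time courses are converted to percent
signal change about the post-discard baseline mean, so the baseline period
is 0% by construction.

**Response shape.** The synthetic generator and the mapping regressor share
one response model: the stimulation boxcar convolved with a single-gamma
impulse response (peak 4 s, shape 6 — a conventional ramped hemodynamic
kernel; both parameters are exposed). The convolved regressor is normalised
to unit *mean over the stimulation images* rather than unit plateau. This
choice reconciles two requirements: time courses ramp over several seconds
as measured BOLD responses do, and the stimulation-period mean of a
noiseless active voxel equals the amplitude parameter exactly, which makes
the magnitude estimator unbiased for the generator amplitude. Had the
plateau been normalised instead, the onset ramp would bias every recovered
magnitude low by roughly the kernel's mean lag divided by the stimulation
duration (~10% here) — an avoidable systematic.

**Mapping.** Activation mapping is unsupervised, formulated as outlier
detection. Stage 1 trains a one-class SVM (RBF kernel, rejection rate
`nu = 0.05`) on every voxel's percent-change time course; rejected voxels
are candidate actives. Stage 2 selects prototypes: candidates in the top
half by absolute correlation with the regressor become positives, and an
equal-sized sample of voxels with absolute correlation below the median
becomes negatives. Stage 3 trains a two-class SVM on the prototypes and
keeps the candidates it reclassifies as active. The published description
of the refinement stage leaves the selection rule open; the top-50% /
below-median quantile defaults here are our own and are config-exposed.
Because candidacy and prototype selection use the *absolute* correlation,
regions of either polarity map identically — necessary, since the analysis
must show that an inverted response preserves its area. Under a pure-noise
null the final map is a subset of the one-class rejections, so the active
fraction is bounded by `nu`.

**Metrics.** Magnitude is the stimulation-image mean of the region-mean
percent change; duration is the full width at half maximum around the
extremum of the absolute response, with the half level referenced to 0% and
crossings interpolated linearly (an ideal 40 s boxcar measures exactly
40 s; a triangle of base 40 s measures 20 s).

## Ephys cleaning

Gradient pulses contaminate the raw 32 kHz trace with ~30 ms interference
blocks once per TR. They are detected by amplitude thresholding followed by
one-dimensional morphology: erosion (default 32 samples = 1 ms) deletes
isolated supra-threshold excursions such as genuine action potentials, and
dilation (erosion length + 64 samples) restores and pads the surviving
blocks. The mask is monotone in the threshold, and flagged samples are
excised with a time map so every downstream spike time stays on the
original recording clock; events inside blocks are unrecoverable by
contract.

Spike detection thresholds at `k = 3` times a robust noise-SD estimate
(median absolute deviation scaled for Gaussian consistency — robust to the
spikes riding on the noise), with a 1 ms lockout matching the
interspike-interval floor. On a noiseless trace the MAD is zero and the
threshold falls back to a fraction of the largest excursion, keeping recall
at 100% on clean template trains. A 3-SD threshold on Gaussian background
unavoidably admits tens of bare noise crossings per second; in the manual
sorting workflow these form a low-amplitude cluster that the operator
deletes. Here that step is a defined rule: events with peak-to-valley
amplitude under three times the detection threshold (9 noise SDs) are
dropped before clustering, which sits well below any unit whose spikes are
reliably detected at 3 SDs in the first place.

Units are sorted by k-means in the (peak-to-valley duration, peak-to-valley
amplitude) plane, with the cluster count chosen in 1..6 by mean silhouette
width (minimum 0.6 to accept a split) — a defined, seeded replacement for
interactive cluster-cutting, adequate for the synthetic fixtures this
package targets. Cell types follow the awake-rabbit criteria: interneurons
have brief action potentials and sustained spontaneous firing (duration
< 0.5 ms and rate > 2 spikes/s), putative efferent neurons have broad
action potentials (>= 0.6 ms). The published duration criteria overlap
between 0.5 and 0.6 ms; rather than forcing that band into either class we
report it (and brief-but-slow units) as `unclassified`. That three-way
partition is our resolution of the ambiguity, flagged as such.

## Resting state and evoked responses

Rates are computed on 1 s bins and averaged (the 1 Hz smoothing
convention). Change classification uses strict inequalities, so equality at
exactly the threshold counts as `no_change` — conservative and
deterministic. The 30% bins are therefore always subsets of the 10% bins,
direction by direction, and the chi-squared comparison against control uses
the plain Pearson statistic without Yates correction on the 2x3 table with
df = 2. Bins empty in both groups contribute nothing but the design df is
kept; a fully homogeneous table reports statistic 0, p = 1. The "before"
window length is not fixed by the protocol and defaults to the 5 min
immediately preceding injection, config-exposed.

Peri-event histograms use 1 s bins (matching the rate convention) over a
[-10, 50) s window, normalised to a 100% pre-stimulus baseline;
normalisation is idempotent and the population histogram is the bin-wise
mean of unit histograms. Polarity calls use a 2-SD criterion on the
baseline bins — the published analysis never states its decision rule, so
the multiplier is ours and config-exposed. Pre/post magnitude comparison
averages per-unit post/pre ratios (whether the published 76% figure
averages ratios or takes a ratio of averages is unstated; we document the
former). Units excitatory only after injection are labelled
`newly_acquired` and excluded from the change mean because their ratio is
undefined; the symmetric case is `abolished`.

## PO2 pipeline

Oxygen traces (20 Hz) are block-mean downsampled to one sample per TR for
comparison with BOLD. Each trial is normalised to its *own* pre-stimulus
baseline (= 100%), since responses are defined relative to the baseline
before stimulation; a trial whose stimulation-period mean is strictly below
100% is `below_baseline`, with exact equality counting as above (documented
tie rule). Two averages mirror the standard presentation: above-baseline
trials only, and all trials. Whenever any below-baseline trial exists the
above-only average exceeds the all-trial average.

## Synthetic generators and what passing tests show

Every generator takes an explicit seed and draws from a single seeded
stream, so outputs are byte-reproducible. Defaults are the study
conditions: BOLD amplitudes ±(1.88, 1.97)% with 0.3% noise on a baseline of
1000 (baseline intensity and noise are not constrained by the protocol and
are config-exposed); spontaneous rates gamma-distributed with mean 3.21 and
SD 0.98 spikes/s; PO2 baseline 25.12 mmHg with 0.5 mmHg noise and plateau
responses of +4.71% (pre) or a mixture of nine +0.989% trials and one -8%
trial (post), whose true all-trial mean is 100.09% in closed form. The
resting-state change composition allocates 47 units by largest remainder
into strong/mild increase and decrease categories so the true binned
fractions reproduce 51/29% at the 30% threshold and 56/36% at the 10%
threshold simultaneously, with ratio bands kept clear of the thresholds so
Poisson rate noise rarely flips a bin.

Spike trains are Poisson with piecewise-constant rates (stimulation and
drug epochs are labelled intervals, not pharmacokinetic models) and a 2 ms
refractory default. For evoked-gain recovery the simulations use a zero
refractory period: refractoriness compresses high stimulation-period rates,
so with it the realised post/pre gain would be ~1.73 rather than the
nominal 1.76 — the refractory-free train is the condition under which the
multiplier is exact. Spike waveforms are biphasic difference-of-Gaussians
parameterised by peak-to-valley duration, the simplest shape carrying the
classification feature; gradient artifacts are dense alternating bursts
whose absolute amplitude holds at the artifact level for the whole block
width, as a saturated gradient-switching artifact does.

The generators emulate the statistical structure the analysis assumes —
they do not simulate MR physics, susceptibility artifacts near electrodes,
electrode drift, overlapping spike waveforms, bursting, or vascular
biophysics. Passing parameter-recovery tests therefore demonstrates that
the pipeline is a consistent estimator of the quantities it reports under
the assumed structure, not that it is robust to every artifact of real
acquisitions.

## Numerical choices and problem sizes

Percent change excludes voxels with non-positive baselines; empty
activation maps are flagged rather than silently summarised; FWHM of an
identically-zero curve is 0; k-means uses 10 restarts under a fixed seed
and identical snippets collapse to one cluster. Test and acceptance runs
use desk-scale problems chosen to keep the full suite around a minute
while leaving every estimator's error small against its tolerance: 40x40x1
or 20x20x1 grids with 6x6 or 3x3 active regions (the acquisition's voxel
size and paradigm are kept at full scale), 10-trial series, 20-seed
replications for BOLD recovery, 30-300 s spike recordings, and 10-trial
PO2 sessions.

## Known limitations

Unit sorting uses two waveform features and spherical k-means clusters;
heavily overlapping amplitude distributions or electrode drift would
require template matching, which is out of scope. The motion metric only
detects bulk displacement of structured intensity, not rotation about the
centre of mass. The chi-squared comparisons require the control group's
counts; published statistics whose control counts are not printed cannot be
reproduced numerically and are deliberately not asserted anywhere in the
test suite.
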