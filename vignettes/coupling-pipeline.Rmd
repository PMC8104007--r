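---
title: "EEG-fMRI band-power coupling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{EEG-fMRI band-power coupling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscoupler)
```

## The analysis in one paragraph

During an eyes-closed simultaneous EEG-fMRI session, the amplitude of EEG
rhythms fluctuates slowly. This package tests, voxel by voxel, whether those
fluctuations predict the BOLD signal: clean the in-scanner EEG, cut it into
one epoch per fMRI volume, summarize each epoch as absolute spectral band
power (delta 1-3, theta 4-7.5, alpha1 8-10, alpha2 10.5-13, beta 14-30 Hz),
convolve the z-scored per-volume power series with a canonical hemodynamic
response function, and use it as the parametric modulator in a voxelwise GLM.
Group differences are tested as undirected F contrasts on the subject-level
coupling coefficients with Monte-Carlo cluster-extent correction. A second,
EEG-independent measure — the amplitude of low-frequency fluctuation of the
BOLD signal itself (ALFF, 0.01-0.08 Hz; mALFF after spatial normalization) —
is mapped and contrasted the same way, whole-brain and restricted to regions
with coupling differences.

## EEG cleaning chain

In-scanner EEG is dominated by two artifacts. Gradient artifacts repeat at
every volume acquisition; they are removed by average artifact subtraction
(AAS): a sliding average of TR-locked artifact epochs (default 21 occurrences,
centered) is subtracted from each occurrence. A strictly periodic artifact
cancels to machine precision, and the sliding window tracks slow drift. The
cost is leakage: about 1/21 of the underlying signal power is subtracted with
the template, which the tests bound explicitly. The ballistocardiogram (BCG)
artifact is cardiac-locked; R peaks are detected on the ECG channel
(QRS-band energy with a 300 ms refractory period, peaks refined on the raw
trace) and the same sliding-template subtraction is applied in windows
starting 0.21 s after each R peak — a conventional pulse-artifact lag, since
the delay is a free parameter of the method.

Filtering is zero-phase throughout (forward-backward passes), so volume
triggers keep their alignment. The band pass is an order-2 Butterworth
(0.5-70 Hz); applied forward-backward it gives an effective 24 dB/oct rolloff,
which we read as the intended minimum slope rather than an exact filter
order. A 50 Hz notch and a narrow reject band at 18 +- 0.5 Hz (residual
slice-frequency artifact, kept configurable) follow, and the data land at
256 Hz. The final non-integer resampling (500 to 256 Hz) is done by exact
band-limited FFT resampling; polyphase resamplers imprint a 1-2% passband
gain ripple that shows up directly in amplitude-calibrated spectral tests.
Residual bad intervals are handled by a deterministic epoch-replacement
operation (nearest good epoch, earlier epoch on ties) rather than an
ICA-based cleanup: component selection with visual inspection is not
reproducible, and the simulated artifact set is fully handled by the
deterministic chain. ECG/EOG-labeled channels are excluded from the average
reference.

## Spectral regressors

Each volume epoch (2.1 s at 256 Hz = 537 samples) is analyzed with a single
discrete Fourier transform. A 2.1 s window cannot produce exactly 0.5 Hz bins,
so the estimator uses the first 512 samples (2.0 s) of each epoch — bins land
exactly at multiples of 0.5 Hz with no padding, and the epoch stays
volume-locked. A Hann-type taper covers the outer 10% of the segment (5% per
end). Spectra are stored as single-sided absolute amplitude, so a
unit-amplitude in-band sinusoid maps to amplitude ~1 minus taper loss.

Band values are means of the absolute amplitudes over in-band bins; a
`units = "power"` dialect squares them first. Because every modulator is
z-scored before entering the GLM, the choice only matters through a monotone
transformation of the regressor; both dialects are provided. Two regressor
families are computed: the global spectral power (GSP; per-epoch root mean
square of band power across all scalp channels) for each of the five bands,
and a regional alpha series (arithmetic mean over Oz, POz, Pz). The regional
band defaults to the union alpha band 8-13 Hz, since the regional analysis is
conventionally defined for "alpha" as a whole; sub-band options remain
available.

## First-level GLM

The design contains the HRF-convolved z-scored modulator (the parametric
modulation of an eyes-closed boxcar whose constant part is absorbed by the
intercept), six motion parameters, white-matter and CSF signals, a
discrete-cosine drift basis for periods above 128 s (6 columns at T = 185,
TR = 2.1 s), and an intercept. The HRF is the canonical double gamma
(response peak 6 s, undershoot peak 16 s, ratio 6), sampled at the TR.
z-scoring the modulator makes coefficients comparable across bands; whether
to center is configurable because acquisition software differs on this.

Serial correlation is modeled as AR(1) with one pooled coefficient per run.
The coefficient is estimated by restricted (REML) profile likelihood: the
lag-1 autocorrelation of OLS residuals — and even per-voxel plain ML — is
substantially biased toward zero here, because the drift basis absorbs
exactly the low-frequency fluctuations that identify the AR coefficient.
With REML, simulated AR(1) noise at rho = 0.3 is recovered to the third
decimal and the voxelwise null exceedance at p < 0.005 is nominal
(0.0051 over 1e5 voxel draws). With rho forced to 0 the fit reduces exactly
to ordinary least squares, which the tests exploit against a
normal-equations oracle.

One caveat the tests make explicit: the synthetic BOLD includes narrow-band
sinusoidal low-frequency components (the planted ALFF structure). These
violate the AR(1) noise model and inflate the voxelwise null rate mildly
(0.0057 measured at default amplitude). Real BOLD noise is closer to a
mixture of AR-like and oscillatory processes, so nominal voxelwise rates
should not be over-interpreted — which is precisely why inference is carried
by the cluster-level correction, whose null distribution is simulated rather
than assumed.

Second-level inference uses the summary-statistic route (one coefficient map
per subject): one-sample t within groups, and the undirected two-group
F(1, n-2) contrast — the square of the pooled two-sample t — between groups.
Between-group coupling differences are F-only because coupling is
bidirectional: a group difference can reflect a stronger positive correlation
or a weaker anticorrelation, and a directional t-test cannot separate the
two. F statistics on zero-residual toy inputs are capped at a finite sentinel
(1e6) and flagged `saturated`.

## Cluster-extent correction

The voxel height threshold (p < 0.005, two-sided by default, since F maps are
the use case) is combined with a minimum cluster extent derived by Monte-Carlo
simulation: 1,000 iterations of standard-normal noise on the analysis grid,
Gaussian smoothing at the nominal applied FWHM (8 mm), unit-variance rescaling
inside the mask, thresholding, 26-connectivity labeling, and the maximum null
cluster size per iteration. The reported threshold is the smallest extent
whose null exceedance is at or below 0.05. Noise is smoothed over the whole
grid and masked afterwards, matching the behavior of the classical simulation
tools and conservative at mask edges. Smoothness is taken as the nominal
applied FWHM; a residual-based estimator was considered and left out because
no estimator is prescribed for this analysis and the nominal value keeps the
null simulation interpretable.

On a synthetic 3 mm MNI-grid gray-matter mask (a cortical-shell-plus-
subcortex construction of ~25,600 voxels, about 690 cm^3 — the size class of
a smoothed gray-matter mask at this resolution) these settings yield a
minimum extent near 30 voxels. The exact value depends on mask details that
are never fully reported in practice, which is why the acceptance band is
wide (22-40).

A note on monotonicity: the minimum extent *increases* with the voxelwise p
(a more lenient height threshold produces larger null clusters), with the
smoothing FWHM, and with mask size. The test suite asserts these directions
over a small parameter sweep.

## ALFF / mALFF

ALFF is computed per voxel from the motion-residualized (OLS on an intercept
plus six motion parameters, voxel mean re-added), linearly detrended series:
an untapered full-length transform (no padding, so bins sit at k/(T*TR) ~
0.00257 Hz) and the mean single-sided amplitude over 0.01-0.08 Hz. mALFF
defaults to the subtractive dialect (ALFF minus the mask-wide mean, so the
mask mean of mALFF is exactly zero); the more common divisive dialect is one
configuration switch. Group contrasts are pooled-variance two-sample t maps,
cluster-corrected on the mask actually tested; the restricted variant uses
the union of all surviving coupling-difference clusters across bands.

## The synthetic cohort generator

The generator exists so that every downstream stage has a recovery target
with known ground truth. Per subject it draws, per band, a log-normal AR(1)
envelope held constant within each TR epoch (positivity is guaranteed and
the per-epoch power autocorrelation has a closed form the tests use as an
oracle); band-limited oscillators at the band centers with a deterministic
scalp topography (posterior-dominant alpha, frontal-dominant delta) ride on
1/f background noise. Artifacts are a fixed gradient waveform (fundamental at
the slice frequency, 30 slices per 2.1 s TR, RMS 20x the neural signal)
repeated at every trigger with optional timing jitter, and a fixed BCG
template at R-peak times with jittered RR intervals (mean 0.9 s, SD 0.04 s) —
enough structure to exercise AAS and QRS-locked subtraction exactly (zero
jitter) and approximately (defaults).

BOLD runs live on a 20 x 20 x 18 grid of 3 mm voxels with an ellipsoidal
"gray-matter" mask (~2,750 voxels) — small enough for desk-scale testing,
shaped like a 3 mm template grid. Coupled ROI voxels carry baseline 100 plus
beta x (HRF-convolved z-scored band power), so beta is directly in percent
signal change per unit z-scored power (default planted effect: beta = 0.8 in
a central "thalamus" sphere for group A, 0 for group B). Every mask voxel has
AR(1) noise (rho 0.3, SD 1% of baseline), random linear plus slow-cosine
drift, and a three-sinusoid low-frequency component (0.02, 0.045, 0.07 Hz,
total amplitude 0.5%) whose amplitude is multiplied by 1.5 inside a posterior
"pcc" sphere for group A — the planted mALFF difference. Background voxels
fluctuate with independent phases; the voxels of a named ROI share one phase
per frequency, because regional hemodynamic fluctuations are coherent — an
incoherent planted amplitude would largely cancel under the pipeline's own
8 mm smoothing and make the recovery target unrepresentative. Motion parameters
are smooth random walks; WM/CSF are low-pass noise.

What the generator does *not* emulate: realistic head-model EEG topography,
MR physics, physiological noise spectra, motion-by-susceptibility
interactions, or spatial autocorrelation of the BOLD noise (voxels are
independent before the pipeline's own smoothing). Passing recovery tests
therefore demonstrates correctness of the estimators under the stated
generative model, not performance on real data.

## Problem sizes and numerical choices

The default study conditions are 185 volumes at TR 2.1 s and 60 EEG channels
at 5 kHz. The test suite exercises the full chain at reduced scale (6
channels at 500 Hz, 20-185 volumes) and the cohort-level recovery tests use
20 seeded cohorts of 10+10 subjects in band-power mode (the generator skips
raw EEG synthesis and provides the per-volume power series directly), with
8 mm smoothing before the GLM; 10 matching null cohorts check the cluster
false-positive rate. The Monte-Carlo extent threshold uses 1,000 iterations
at acceptance scale and 100-500 in unit tests. Zero-residual statistics are
capped at 1e6 and flagged; AR(1) estimation is clamped to (-0.5, 0.95);
degenerate (constant) modulators produce an explicit warning and a zero
interest column rather than a silent rank-deficiency error.

## Known limitations

- The pooled (per-run) AR(1) coefficient is a deliberate simplification;
  voxelwise or spatially regularized serial-correlation models would be
  needed for data with strongly heterogeneous autocorrelation.
- Cluster correction assumes the nominal smoothness; if the effective
  smoothness of real data differs, the derived extent threshold shifts.
- The epoch-replacement operation repairs amplitude artifacts but duplicates
  neighboring physiology; heavy use biases spectral estimates toward the
  copied epochs.
- Regional regressors are implemented for arbitrary electrode sets but only
  the parieto-occipital alpha configuration is exercised by default.
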