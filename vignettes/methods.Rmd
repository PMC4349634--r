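---
title: "Methods: spike-triggered averaging of high-frequency epidural EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-triggered averaging of high-frequency epidural EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegsta)
```

## The estimation problem

A single cortical action potential contributes on the order of tens of
nanovolts to the epidural EEG — two to three orders of magnitude below the
high-frequency background. The only way to measure it is massive
averaging: extract the EEG around each of tens of thousands of spikes and
average. The statistical difficulties are (i) the evoked response is
time-locked to the stimulus and therefore leaks into any spike-triggered
average whose spikes are themselves stimulus-driven, and (ii) the
amplitude of interest is comparable to the sampling noise of the average
itself. `eegsta` addresses (i) with a shift predictor — recomputing the
average after assigning every spike to a random *different* trial while
keeping its post-stimulus latency, which preserves stimulus-locked but
destroys spike-locked structure — and (ii) with explicit SEM-based bands
and bootstrap tests.

## Pipeline and its assumptions

The high-frequency chain is: band-pass 800–3000 Hz → upsample to 10 kHz
(linear interpolation) → prune spikes closer than 6 ms to any neighbour →
extract ±3 ms segments (61 samples, inclusive endpoints, lag 0 at the
spike's first negative peak) → average; the wideband chain uses 3–3000 Hz,
±15 ms and 30 ms pruning. Assumptions: trials are exchangeable for the
shuffle null (stationary background across trials); the per-spike EEG
kernel is additive and identical across spikes of a cell; the background
in the averaging window is wide-sense stationary. Baseline correction
(subtracting the shift predictor) is applied to evoked-condition STAs but
deliberately *not* to late-window (200–290 ms) STAs or wideband spectra,
where the caller's contract is that no evoked baseline remains; the
`baseline_corrected` flag records what was done.

## Key tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| filter transition half-width | 117 | Hz | HWHM of the Gaussian smoothing the ideal mask; suppresses ringing |
| high-frequency band | 800–3000 | Hz | spike energy band; below 800 Hz synaptic potentials dominate |
| STA half-window / pruning | 3 / 6, 15 / 30 | ms | window must not contain a neighbouring spike |
| confidence multiplier | 2.58 | SEM | two-sided 99% normal coverage |
| peak-test window | −0.3…0.5 | ms | bracket of the triphasic deflection |
| shuffles / peak bootstrap / spectral bootstrap | 100 / 5000 / 500 | – | predictor precision vs. cost |
| spectral grid | 8 per octave, half-octave smoothing | – | stable estimates from sub-10 ms waveforms |
| multitaper bandwidth | 600 | Hz | full concentration bandwidth 2W (see below) |
| EEG noise SD (generator) | 700 | nV | high-band background of low-noise epidural recordings |
| trials × rate (generator) | ~1000 × 3 Hz | – | typical session geometry |

## Numerical choices

- **"Half-width 117 Hz"** is read as the half-width at half-maximum of
  the Gaussian convolved with the ideal band mask — the only reading that
  makes a single number of it. The mask is exactly 0.5 at each cutoff.
- **Edge handling.** The filter is a plain (circular) DFT multiplication
  with no padding. Trials are filtered whole and analysis windows
  extracted afterwards, so wrap-around affects only trial edges, which the
  window-fitting rule already discards. Trials are filtered individually.
- **Log-spaced spectra** cannot start at 0 Hz; the grid starts at
  `f_min = 2/duration` (two full periods must fit). Power is normalized by
  the Hanning window gain so a unit sine at a grid frequency has power 1;
  the half-octave moving average is applied to *linear* power.
- **Multitaper bandwidth** is interpreted as the full concentration
  bandwidth (`W = 300` Hz half-bandwidth), giving
  `K = floor(2 N W / fs) − 1` tapers; both are configurable. Slepian
  tapers are computed with the symmetric tridiagonal formulation.
- **Pruning is symmetric**: both members of a close pair are removed,
  because a neighbour on either side contaminates the segment. Spikes
  separated by exactly the minimum are retained. Pruning is idempotent.
- **Peak-test window.** At 10 kHz the inclusive −0.3…0.5 ms window spans
  9 samples; we use the inclusive grid throughout (an 8-sample half-open
  reading exists but breaks lag-grid symmetry).
- **Bootstrap peak test.** The observed unshuffled peak is compared
  against the bootstrap distribution of shuffled-STA peaks (each replicate
  resamples the shuffled segments with the segment count conserved). In
  null-calibration simulations this construction holds the 5% level
  almost exactly, whereas also resampling the unshuffled side makes the
  test conservative — the observed STA and each null replicate must
  average the same number of segments for exchangeability.
- **Robust noise SD** for spike detection uses the median absolute
  deviation (×1.4826), which is insensitive to the spikes themselves.
- **Grand averages pool spikes** (each spike one segment) rather than
  averaging per-cell STAs; per-cell weighting is available by averaging
  `eeg_sta()` results per cell.
- **Degenerate inputs**: zero-variance waveforms are rejected by the
  Mexican-hat fit; empty spike sets yield empty segment matrices, not
  errors; a single-trial session cannot form a shift predictor.

## What the synthetic generator emulates — and what it does not

`simulate_session()` produces per-trial EEG (6 kHz, nV) as band-limited
3–3000 Hz Gaussian noise scaled so that its 800–3000 Hz component has a
specified SD (default 700 nV), plus an evoked template at the stimulus
time, plus one copy of the per-spike Mexican-hat kernel inserted at every
spike with fractional delay by linear interpolation at the EEG rate —
deliberately *not* claiming sub-sample precision the acquisition would not
have. Spikes are inhomogeneous-Poisson on the 24 kHz unit grid with an
absolute refractory period enforced by deleting the later spike; the
default rate profile has an early driven response (5–50 ms) with a comb of
volleys repeating at 600 Hz in the 8–18 ms burst window and an exactly
stationary late window (200–290 ms). Pairwise synchrony is available via
shared jittered events, yielding a Gaussian excess cross-correlogram of
prescribed peak and half-amplitude width.

Not emulated: the 1/f shape of ongoing low-frequency EEG (the noise is
flat within its band — the high-frequency analyses are insensitive to
this, but wideband baselines are cleaner than real data); electrode
impedance and amplifier nonlinearity; spike-sorting errors (one
ground-truth cell per channel); slow drift of spike amplitude. Passing
tests therefore certify the *estimator* under the stated generative
assumptions, not robustness to sorting artefacts or nonstationary noise.

### The in-band recovery target

A Mexican hat of width 0.45 ms is not band-limited: sampling it at 6 kHz,
linearly interpolating to 10 kHz and band-passing 800–3000 Hz attenuates
its peak-to-peak amplitude to roughly two thirds of the analytic value,
exactly as acquisition would. The pipeline can only recover the kernel *as
acquired*, so recovery is assessed against the deterministic in-band
embedded waveform computed by `embedded_kernel_sta()` (the noiseless
filter→upsample→extract chain averaged over all spike phases of the unit
grid), and test kernels are calibrated so that this in-band target — not
the analytic amplitude — equals the nominal value. Amplitudes are
evaluated at the known extremum lags of the target waveform, which avoids
the selection bias of a max–min search over noisy lags, with the SEM of
the peak-to-trough difference estimated directly from the per-segment
differences (the two lags are correlated under band-passed noise, so
independent per-lag SEMs would be wrong).

## Test problem sizes

The suite exercises the chain at sizes chosen to make the statistical
assertions sharp while keeping the default run short: recovery studies use
250 trials × 400 ms at 30 spikes/s (≥2000 pruned segments, 100 seeded
runs); null calibrations use 200 noise-only sessions of 40 trials with
500-replicate peak bootstraps and 200-replicate spectral bootstraps; the
closed-form/oracle agreement sweeps a 10×10 parameter grid; the
neuron-count study forward-simulates 50 cells × 120 trials.

## Known limitations

- The circular-DFT filter assumes per-trial stationarity; very long
  kernels relative to the trial would alias across edges.
- The shift predictor assumes trials are exchangeable; slow drift across
  a session violates this and would leak into the corrected STA.
- The dipole model is a single homogeneous-medium point dipole with a
  fixed boundary/montage factor of 4; no layered head model is attempted.
- The correlation model treats all correlated neurons as sharing one
  kernel shape and one Gaussian correlogram; heterogeneity enters only
  through the linearity of the result in `N` and `a_xcf`.
- `fit_mexican_hat()` is a local optimizer; pathological waveforms (two
  equal peaks) can converge to either.
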