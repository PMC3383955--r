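---
title: "A synthetic pre-cued Fitts tapping study: generative model and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A synthetic pre-cued Fitts tapping study: generative model and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fittsERP)
```

## Overview

`fittsERP` simulates, end to end, a pre-cued rapid-aiming experiment and
its EEG analysis. On each trial a symbolic cue announces the upcoming
target (its width and side, or a no-go), a go signal follows after a 1 s
foreperiod, and the participant lifts a stylus and taps the target. The
package generates behavioural tables and multichannel EEG with known
ground-truth laws, then recovers those laws through a conventional ERP
pipeline. Because every generating coefficient is a documented default,
the pipeline's output can be checked against exact expectations — the
package is simultaneously a simulation laboratory and a regression-tested
analysis chain.

## The design

The design crosses three target widths (1, 2 and 4 cm) with three indices
of difficulty (ID = 2, 3 and 4 bits), where Fitts's index of difficulty is

$$\mathrm{ID} = \log_2\!\left(\frac{2A}{W}\right)$$

for movement amplitude $A$ and width $W$. Holding ID constant while width
varies decouples difficulty from movement distance, which is what lets the
analysis dissociate difficulty-tracking measures from amplitude-tracking
ones.

```{r design}
d <- buildDesign()
d
designCells(d)
```

Each block fixes the target width and presents seven cue types (three IDs
× two sides, plus no-go) nine times each in random order — 63 trials per
block, each cue type with probability 1/7. Twelve blocks (four per width)
make a session. Trial timing: 500 ms fixation, 150 ms cue, 1000 ms
foreperiod, 150 ms go signal, 4000 ms trial period.

## The generative model

### Behaviour

Movement time follows Fitts's law, reaction time is ID-independent with a
right-hand advantage:

* MT (ms) = 211 + 68·ID, trial-to-trial SD 40 ms;
* RT (ms) ≈ 360, with the right hand ~15 ms faster;
* subject-level intercept/slope variation around these laws.

RT is clamped to [50, 1000] ms and MT to [50, 1200] ms; trials outside
the response window become misses, and a small wrong-target rate is
simulated for directional cues.

### EEG

Recordings contain 13 EEG channels plus bipolar VEOG/HEOG at 500 Hz
(configurable). Ground-truth components, all expressed in µV on the
sampled grid so that noise-free recovery is exact:

* a posterior cue-evoked deflection over Pz/P1/P2/POz/PO3/PO4 whose
  310–370 ms window mean equals −2.3 + 1.6·ID — difficulty-graded target
  encoding;
* a lateralized horizontal-EOG step after the go signal whose 250–450 ms
  lateralized mean equals −133 − 3.8·A — the saccade to the target scales
  with distance, not difficulty;
* a central anticipatory negativity (CNV) during the foreperiod and a
  pre-movement lateralized readiness potential (LRP), both *independent*
  of ID — motor preparation proceeds identically across difficulty;
* Poisson blinks (0.05 Hz, 200 µV on VEOG) propagated to scalp channels
  with fixed coefficients, plus 1/f ("pink", SD 4 µV) and white (SD 3 µV)
  noise.

The intended dissociation mirrors the classic aiming literature: the
posterior component and MT track ID; the ocular component tracks
amplitude; motor preparation measures track neither.

```{r config}
generatorConfig()
```

`noiselessConfig()` zeroes every noise source; the pipeline then recovers
the generating coefficients to numerical precision, which the test suite
uses as an oracle.

## The analysis pipeline

`preprocessRecording()` applies, in order:

1. **Ocular correction** (regression-based, Gratton–Coles style): blink
   propagation coefficients are estimated on condition-residuals of raw
   cue-locked epochs and subtracted from the continuous data. By default
   only VEOG enters the model. Horizontal-EOG correction is opt-in
   (`eogChannels = c("VEOG", "HEOG")`) because residual RT jitter makes
   lift-locked motor activity covary with the HEOG regressor; the biased
   coefficient then injects lateralized ocular activity into central
   channels, which masquerades as an LRP. This is a real failure mode of
   regression-based correction, reproduced faithfully by the simulation.
2. **Band-pass filtering** of the continuous recording (0.05–60 Hz,
   zero-phase). Filtering precedes epoching because the high-pass time
   constant (~3 s) exceeds the epoch length.
3. **Epoching**: cue-locked (−300 to 1500 ms, baseline −200 to 0 ms) and
   lift-locked (−800 to 200 ms, baseline −800 to −600 ms).
4. **Artifact rejection**: epochs whose peak-to-peak amplitude *exceeds*
   100 µV on any EEG channel are flagged (exactly 100 µV is kept).

`subjectErpMeasures()` then computes, per width×ID cell with incorrect
responses and rejected epochs excluded: the posterior ROI window mean
(N2/P3b), the motor CNV (action minus no-go over central channels,
800–1000 ms after the cue), the lateralized HEOG, and the LRP from the
double subtraction of the two hands' lift-locked averages over C1/C2 and
C3/C4. `runPipeline()` wraps simulation, preprocessing, measurement,
grand-averaging and all regressions into one deterministic report.

```{r pipeline, eval = FALSE}
report <- runPipeline(config = generatorConfig(nSubjects = 4L, seed = 1L),
                      blocksPerSubject = 2L)
report$erp$regressions$n2p3b_id[c("slope", "intercept", "r2")]
writeReportJSON(report, "report.json")
```

Behavioural reduction follows lab convention: RT/MT below 100 ms are
removed, then a single-pass ±2 SD trim per subject×condition cell;
`fittsRegression()` fits MT on ID (and, as a control, on amplitude) over
the nine cell means.

## Numerical choices

**Frequency-domain filtering.** The 0.05 Hz high-pass is applied in the
frequency domain using the squared Butterworth magnitude response — the
exact transfer function of a forward–backward pass — after removing the
least-squares linear trend and zero-padding by ten time constants. A
time-domain IIR recursion was rejected deliberately: at 0.05 Hz and
500 Hz sampling the poles sit so close to $z = 1$ that the recursion
behaves as a near-double-integrator of rounding noise, and both direct
form and cascaded-biquad implementations corrupt the passband by tens of
percent. The FFT implementation keeps passband deviation below 1 % and
removes constants exactly.

**Exact inversion.** Generator amplitudes are pre-divided by the window
gain of each component on the sample grid, so the analysis windows
recover the nominal coefficients exactly in the noise-free limit — the
basis of the package's strongest tests.

**Statistics.** `olsFit()` is a closed-form simple regression (validated
against the normal equations to 10⁻¹⁰) carrying slope confidence
intervals used by the null checks on CNV and LRP.

## Realism and limits

The generator is a measurement model, not a biophysical one: components
are fixed waveforms with linear laws, noise is stationary, electrode
geometry is nominal, and ocular propagation is constant across time. It
reproduces the statistical structure a real study of this design exhibits
— including the HEOG/LRP contamination trap — but not single-trial
waveform variability beyond amplitude noise.

Examples and tests that sweep many seeds run at reduced size (fewer
subjects and blocks, 200 Hz) purely for runtime; the defaults
(17 subjects, 12 blocks, 500 Hz) are used where a single run suffices.

## Reproducing the headline results

```sh
Rscript scripts/acceptance.R --seed 1 --out results.json
```

writes the design constants, the recovered MT law (median over 20
replicate studies), the RT hand advantage, the recovered N2/P3b and
LHEOG laws from a full-scale EEG run, and the dissociation/null
percentages over a 50-seed sweep.
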