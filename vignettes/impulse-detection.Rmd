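---
title: "Counting borer impulses in tree vibroscapes: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting borer impulses in tree vibroscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibroscout)
```

## The detection problem

A recording from a probe inside a trunk is modelled as a two-hypothesis
problem: under the null the waveform is background vibration only,
`y[n] = s[n]`; under the alternative it additionally carries borer
activity, `y[n] = x[n] + s[n]`, where `x[n]` is a pulse or pulse train
from wood-fiber fractures. The background `s[n]` is broadband,
time-varying and non-stationary — rain, wind, traffic, voices, barks —
so classical detectors that assume Gaussian or stationary colored noise
do not apply. Two robust observations carry the whole method instead:

* fiber-fracture impulses are *brief* (raw duration 2–12 ms) for every
  woodboring species, because fracture mechanics does not depend on the
  insect; ambient interferers are orders of magnitude longer, except
* rain, whose individual drops are impulse-like, but whose *aggregate
  energy* floods the recording.

Hence a two-stage design: an energy gate handles rain and wind at the
whole-recording level, and a duration gate separates impulses from the
remaining long interferers at the event level. Larvae stay in the trunk
for months and fracture fibers continually, so discarding noisy
recordings costs nothing: the monitoring device simply waits for a quiet
"clear shot".

## The processing chain and its parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| `e_sil` | mean energy per sample of silence | amplitude² | 1e-8 |
| `theta1` | energy-gate rejection multiplier | — | 300 (lab), 185 (field) |
| `window_ms` | moving-average window | ms | 12.5 (= 200 samples at 16 kHz) |
| `n_segments` | noise-floor chunks per recording | — | 10 |
| `a` | noise-floor multiplier | — | 3 (lab), 7 (field), 10 (strict) |
| `d_min_ms`, `d_max_ms` | duration gate, inclusive | ms | 10, 20 |
| `rate` | sampling rate | Hz | 16000 |

Amplitudes are normalized by dividing 16-bit integers by 32768, and every
energy quantity lives on that normalized scale. `e_sil` is a deployment
calibration constant (`calibrate_silence()` averages the mean energies of
quiet recordings); absolute values depend on the sensor chain and must be
measured, not assumed. The package default matches its own synthetic
generator's quiet background (RMS 1e-4).

The gate comparison is strict (`>`): a recording at exactly
`theta1 * e_sil` is accepted. The duration gate is inclusive at both ends.
Both choices are deliberate tie-breaks and are pinned by unit tests.

**Smoothing.** The envelope is the causal length-`N` moving average of
`y²`, computed via cumulative sums. An isolated impulse at sample `n`
produces a plateau starting at `n`; signals are treated as zero outside
their support. `N` is expressed in milliseconds (12.5 ms) and scales
proportionally at sampling rates other than 16 kHz, where it equals the
canonical 200 samples. Smoothing exists to merge the attack–sustain–release
sub-peaks of one fracture into a single countable bump; a Hilbert-envelope
would serve the same purpose with no practical advantage and more
machinery, so the rectangular kernel stays.

**The detection statistic is `y_sm²`.** The per-chunk noise floor is
`a` times the chunk mean of `y_sm²`, and the statistic compared against it
is `y_sm²[n]` — the square of the already-squared-and-smoothed signal.
One could argue `y_sm` itself with floors `a · mean(y_sm)` is the more
natural scale; the two versions are monotone-equivalent within a chunk
only under a rescaling of `a`, so they are genuinely different detectors
across chunks. This package implements the squared form. Counting is
consequently invariant to scaling the waveform by any constant `c` (both
the statistic and the floors scale by `c⁴`); only the energy gate is
scale-sensitive, as it must be.

**Run semantics.** A run opens at the first sample whose statistic
exceeds the floor of the chunk *containing that sample* and keeps that
start-chunk's floor until the statistic falls back to or below it, even
across chunk boundaries — the single-pass reading of the counting step.
A run still open at the signal's end is closed and reported there. When
the envelope length is not divisible by `n_segments`, the last chunk
absorbs the remainder, so there are always exactly `n_segments` chunks.

**Duration gate on smoothed durations.** Raw fractures last 2–12 ms, but
what the detector measures is the above-threshold run of the *smoothed*
statistic, which the 12.5 ms window widens by roughly its own length.
The 10–20 ms default brackets that smoothed distribution; on the
synthetic scenarios the acceptance script reports its mode (about 13 ms
under the generator's defaults). Event energy is
`10 log10(mean(y_sm))` over the run, floored at −200 dB to avoid `-Inf`
on silent stretches.

Rejected recordings report `count = 0` rather than `NA`, so cumulative
series stay defined everywhere; the `status` field keeps the distinction.

## What the synthetic vibroscape emulates

`generate_scenario()` builds `y[n] = x[n] + s[n]` explicitly: white
Gaussian background at a configurable RMS (default 1e-4), plus injected
impulses, plus named interferers, with every component logged as ground
truth. Scenario waveforms are exactly the sum of their logged components,
and the same spec and seed reproduce a scenario bit for bit.

* **Impulses** are exponentially damped white-noise bursts of the
  requested raw duration. Within a scenario, each block is rescaled so
  that its peak RMS over one smoothing window equals the drawn
  "amplitude" (default range 0.001–0.002, i.e. 10–20× the background
  RMS). Parametrizing strength by window RMS rather than raw peak makes
  detectability uniform across the 2–12 ms duration range. The range
  ratio is kept modest (2×) on purpose: the noise floor is `a` times a
  chunk *mean*, so a very strong impulse inflates the floor of its chunk
  and can mask a much weaker one — a real property of the detector, and
  one the recovery tests must not trip over. Onsets keep a minimum
  spacing of one maximal impulse plus two smoothing windows and stay
  clear of interferer spans, which is what makes exact `k`-for-`k`
  recovery a *constructed* guarantee rather than a statistical hope.
* **Barks** (100–500 ms) use a constant-instantaneous-energy broadband
  (Rademacher) carrier under a flat-top envelope with 5 ms tapers and
  shallow 8 Hz syllable modulation. The deterministic carrier energy
  matters: with a Gaussian carrier the smoothed envelope fluctuates with
  correlation length equal to the smoothing window — 12.5 ms, inside the
  duration gate — so wherever a burst's envelope hovers near the noise
  floor it would occasionally shed gate-length fragments. The steep
  tapers keep the passage through the threshold band brief.
* **Traffic** is a multi-second single-tone rumble (50–90 Hz) under a
  flat-top envelope with 40 ms tapers: its residual energy ripple sits at
  twice the fundamental (period ≤ 10 ms, below the gate) and its envelope
  varies over seconds (above the gate).
* **Rain** is a dense train (300 drops/s) of 2–6 ms damped impulses with
  lognormal drop energies, rescaled so the recording's mean energy equals
  a pinned multiple (default 500) of the reference silence energy — above
  the default `theta1 = 300`, so rejection is guaranteed by construction.
  The heavy tail matters for the evaluation-policy comparison: if the
  energy gate is disabled, the large drops stand clear of the inflated
  noise floor and are counted as dozens of spurious impulses, which is
  exactly the failure mode the gate exists to prevent.
* **Monitoring series** draw per-recording impulse counts from a Poisson
  law (default mean 3) for infested trees and rare singletons
  (probability 0.02) for healthy ones, at a 15-minute duty cycle with
  device-convention filenames.

What the generator does *not* emulate: wood-acoustic propagation and
dispersion, probe coupling resonances, non-white sensor noise, drifting
background levels (an option exists but defaults off for determinism),
overlapping impulse trains from many larvae, and real annotator error
(synthetic "annotations" are exact ground truth). Passing the recovery
and separation tests therefore demonstrates the chain's correctness and
its behaviour under the modelled interference classes — not field
performance on any particular tree, which additionally depends on
sensor placement, wood type and larval instar.

## Evaluation and analytics choices

`evaluate_folder()` scores detector counts against annotations under
three policies: `no_reject` (gate disabled, everything counted),
`reject_all` (gate active, rejected recordings scored as predicted 0, all
files evaluated) and `accepted_only` (rejected files dropped before
scoring). Scoring rejected recordings as 0 in `reject_all` is the reading
under which the three policies form a strict error ordering — disabling
the gate inflates MAE through rain, and excluding rejected files removes
the residual error of impulses the gate forwent. Binary labels are
`count > 0` on both sides; both classes are reported with precision,
recall, F1 and support, plus accuracy and standard macro/micro averages
(micro-averaged precision and recall equal accuracy on exhaustive
two-class labels, and the package emits the standard definitions without
forcing anything else). Zero-denominator metrics are reported as 0 with
an explicit flag.

`classify_tree()` reduces the cumulative impulse curve to its slope:
below `min_accepted` (default 20) accepted recordings the verdict is
`indeterminate`; otherwise `infested` when impulses per accepted
recording reach `rate_threshold` (default 0.5). Both knobs are heuristics
— the slope separation between the synthetic infested (≈ 3/recording)
and healthy (≈ 0.02/recording) regimes is two orders of magnitude, so any
threshold well inside that gap serves; 0.5 sits comfortably above the
healthy false-event rate while catching light infestations. Rejected
recordings are excluded from the denominator because they carry no
counting information. Hourly activity bins each impulse by the hour of
its absolute timestamp (file timestamp plus in-recording offset; for 30 s
files this reduces to the file hour).

## Numerical notes and test design

Smoothing uses cumulative sums (exact up to double-precision accumulation
over ≤ 10⁶ samples); the test suite checks it against a direct O(M·N)
convolution at 1e-12 relative tolerance, and run extraction against a
per-sample state-machine oracle for exact equality. Scale-invariance
tests use power-of-two factors so floating-point equality is exact.
Checks that need statistical room state their sizes explicitly: recovery
uses five seeds per `k` in 0..20 at full 30 s × 16 kHz scale (105
scenarios, plus 40 rain, 30 bark and 25 traffic); tree separation uses
ten seeds of 25-recording series per condition; the hourly-uniformity
check uses 20,000 events, where the max/min bin ratio concentrates well
inside 1.2.

## Known limitations

* Dynamic-range masking: a strong impulse raises its chunk's floor and
  can hide a simultaneous much weaker one; counts are a lower bound
  during loud activity. The pulse-train habit of larvae compensates over
  a monitoring series.
* At high `a` (field/strict presets) a burst whose own level lands
  *inside* the floor's fluctuation band can fragment; on synthetic barks
  at `a = 7` this very occasionally yields a single spurious count. The
  same strictness is what suppresses false alarms overall.
* mp3 input is not decoded in this build (no decoder backend);
  `read_recording()` says so explicitly. WAV round-trips are exact to one
  16-bit LSB, which is why fixtures are WAV.
* No spectral features, species identification or localization: the mean
  energy and event durations are deliberately the only two features used.
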