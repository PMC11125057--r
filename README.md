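# vibroscout

Automated vibroacoustic detection of woodboring insect larvae in trees.

Larvae of xylophagous beetles (for instance the mulberry borer
*Xylotrechus chinensis*, Cerambycidae) feed and tunnel under the bark for
months. Each wood-fiber fracture they cause emits a brief broadband
micro-vibration — an **impulse** of raw duration 2–12 ms — that a
piezoelectric probe inside the trunk can pick up. The practical problem is
that the tree's *vibroscape* also contains rain, wind, traffic rumble, dog
barks and voices. vibroscout counts borer impulses in the presence of that
interference and aggregates the counts into a tree-level infestation
verdict, so that phytosanitary teams can find infested trees before the
canopy dies.

## Method

For a recording `y[n]` of `M` samples (default 30 s at 16 kHz, amplitudes
normalized to [−1, 1)):

1. **Energy gate.** Reject the recording outright if

   `(1/M) Σ y²[k] > θ₁ · E_sil`

   where `E_sil` is the calibrated mean energy per sample of silence and
   `θ₁` a rejection multiplier (default 300; field preset 185). Rain and
   wind flood the whole recording with energy; counting waits for a quiet
   "clear shot". Comparison is strict, so equality accepts.

2. **Envelope smoothing.** `y_sm[n] = y²[n] ⊛ w[n]`, with `w` a causal
   rectangular moving-average kernel of `N` samples (200 at 16 kHz,
   i.e. 12.5 ms). This turns each multi-peaked attack–sustain–release
   burst into a single smooth bump, so one fracture is counted once.

3. **Segment-wise noise floors.** The envelope is split into 10 equal
   chunks (48,000 samples each for 30 s at 16 kHz) and each chunk `i` gets
   the adaptive threshold

   `θ₂[i] = a · mean(y_sm²[k])` over chunk `i`,

   with `a` a false-alarm multiplier (lab 3, field 7, strict 10). Because
   impulses occupy well under 1% of a chunk, the chunk mean is a faithful
   local noise floor even when impulses are present.

4. **Run extraction and duration gate.** Maximal runs where `y_sm²[n]`
   exceeds its chunk's floor are delimited (a run keeps the threshold of
   the chunk it started in; a run still open at the end of the signal is
   closed there). Only runs whose duration lies inside `D_min ≤ D ≤ D_max`
   (default 10–20 ms on the smoothed duration) are counted as impulses —
   barks, voices and traffic produce much longer runs and are discarded.

Evaluation follows the field protocol: per-file MAE and RMSE of counts
against a human annotator, and per-recording binary (pulses / no-pulses)
precision, recall, F1 and accuracy, under three policies (reject noisy and
score everything, score only accepted recordings, or disable the gate).
Tree-level analytics turn a duty-cycled recording series into cumulative
impulse curves, hour-of-day activity profiles, duration histograms,
duration–energy scatters and a rate-based infested/healthy/indeterminate
call.

A built-in synthetic vibroscape generator produces all of these scenarios
with exact ground truth (impulse trains, barks, traffic, wind, rain with a
pinned energy ratio), so the entire chain is testable without field data.

## Worked example

```r
library(vibroscout)

scn <- generate_scenario(scenario_spec("quiet_infested", n_impulses = 5, seed = 42))
cfg <- detector_config()          # E_sil = 1e-8, theta1 = 300, a = 3, gate 10-20 ms
res <- detect(scn$recording, cfg)
res
#> <detection_result> accepted: 5 impulse(s), mean energy 1.35e-08
res$events[, c("start", "duration_ms", "energy_db")]
#>    start duration_ms energy_db
#> 1 113150     14.1875 -58.99250
#> 2 146087     14.0000 -57.93404
#> 3 375453     14.2500 -59.47348
#> 4 388114     14.0625 -58.77407
#> 5 401873     15.0625 -57.24593
```

All five injected impulses are recovered (ground-truth onsets 113146,
146082, 375453, 388111, 401864 — the detected starts sit a few samples
later, where the envelope first clears the noise floor). The smoothed
durations of ~14–15 ms are the raw 2–12 ms fractures widened by the
12.5 ms moving-average window; `energy_db` is the mean envelope power over
the event, so nearer/stronger larvae score higher.

A week of monitoring collapses to one verdict:

```r
series <- monitoring_series(
  lapply(generate_monitoring_series(TRUE, 25, mean_rate = 3, seed = 7),
         function(x) detect(x$recording, cfg)),
  tree_id = "mulberry-1")
tree_report(series)
#> <tree_report> mulberry-1: infested
#>   82 impulses over 25 accepted (+0 rejected) recordings (3.28 / recording)
```

The shell interface wraps the same functions:

```sh
Rscript inst/scripts/vibroscout detect recordings/ --preset field --out results/
Rscript inst/scripts/vibroscout monitor recordings/ --out tree1/
Rscript inst/scripts/vibroscout evaluate recordings/ --annotations counts.csv --policy accepted_only --out eval/
```

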