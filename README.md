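# cuephys

Spike-train and behavioral analysis of dopamine cue reactivity in rat VTA
recordings.

A central question in addiction neuroscience is whether opioid exposure
selectively inflates dopamine responses to drug-predictive cues (as the
noncompensable reward-prediction-error account of cue reactivity predicts)
or raises responsiveness across the board. Answering it requires a specific
analysis chain for single-unit recordings in Pavlovian and operant
cue-reward tasks, and `cuephys` implements that chain as a tested,
reusable R package for electrophysiologists working with this class of
data:

- a documented **session format** (CSV directory or JSON) for spike trains,
  event tables and trial tables, with strict validation and bit-exact
  round-trips;
- **peri-event quantification**: 10-ms PSTHs with exact count conservation,
  causal exponential smoothing (200-ms support, unit-sum kernel), baseline
  rates, and windowed baseline-subtracted responses
  (r(t ∈ [30, 500] ms) − r(t ∈ [−1000, 0] ms), detection/valuation phases,
  omission periods);
- **auROC normalization**: per-bin area under the ROC curve against a
  pre-event baseline — the Mann–Whitney statistic U/(n₁n₂) with ties at ½ —
  so 0.5 is no change, 1 maximal excitation, 0 maximal inhibition;
- the **putative-dopamine classification cascade**: cue-responsiveness
  screen → PCA of the auROC response matrix → Ward-linkage hierarchical
  clustering into excited/inhibited/phasic groups → exclusion of baseline
  > 12 Hz → k-means refinement on (log peak time, log ISI CV, inhibition
  index (R−B)/(R+B)) to remove the atypical delayed/labile subpopulation →
  manual exclusions, with exact stage-count bookkeeping;
- **behavioral cue-reactivity metrics**: lever-press hazard curves
  P(press = t | press ≥ t) in 100-ms bins, port-occupancy traces, trial
  accuracy and first-entry congruence indices, cumulative congruent
  entries, progressive-ratio breakpoints;
- the **case-control similarity test**: PCA of four composite measures, a
  bootstrapped centroid-distance score (negative ⇒ closer to the naive
  group), a 50,000-relabeling null distribution and a two-tailed 95%
  percentile test;
- a **synthetic session generator** (inhomogeneous gamma-renewal spiking
  with planted unit classes, task schedules and behavioral draws) so every
  stage is validated against known ground truth without any recorded data.

## Worked example

Simulate the reference 200-unit session (60 canonical phasic, 40 sustained
excited, 30 inhibited, 30 atypical, 40 high-baseline units; 40 sucrose and
20 neutral trials) and run the identification cascade:

```r
library(cuephys)

sim <- simulate_pavlovian_session(generator_config("pavlovian"), seed = 101)
rep <- classify_units(sim$session, "pavlovian", seed = 101)
rep
#> <classification_report> sim_pav_s101 (pavlovian): 200 units; 200 screened in;
#>   130 phasic (40 excited, 30 inhibited); excluded 40 high-baseline,
#>   30 atypical, 0 manual -> 60 putative dopamine
```

All 200 units pass the responsiveness screen; the functional clustering
separates the 40 sustained-excited and 30 inhibited units; within the
130-unit phasic cluster the 40 high-baseline units are excluded at the
12-Hz criterion and the 30 atypical units by the k-means refinement,
leaving exactly the 60 planted canonical dopamine-like units. The counts
telescope: 130 = 60 + 40 + 30 + 0.

Per-unit quantification of the first canonical unit:

```r
s <- sim$session
tr <- s$spike_trains[[1]]
cues <- s$events$time[s$events$event_type == "cue_on" & s$events$label == "sucrose"]
phasic_response(tr, cues)
#> <phasic_measure> unit u001: 3.939 Hz (sem 0.602, 40 trials)
extract_features(tr, s, "pavlovian")
#>   unit_id peak_time    isi_cv  inhibition baseline_hz n_isi_used
#> 1    u001       0.1 0.8177477 -0.02511012    5.047266      26221
```

The cue raises this unit's rate by ~3.9 Hz over the 30–500 ms window
(the planted 25-Hz, σ = 30 ms bump spread over the 470-ms window), its
peak firing time is recovered at the planted 100 ms, its ISI CV of 0.82
reflects the planted gamma shape 1.5, and its inhibition index is near 0
(no planted reward pause).

The published exclusion-cascade arithmetic is reproduced by the same
bookkeeping:

```r
exclusion_cascade(n_phasic = 165, n_high_baseline = 39, n_atypical = 21, n_manual = 6)$n_putative
#> [1] 99
```

See `vignette("cuephys-methods")` for the full model description,
parameter semantics and design decisions.

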