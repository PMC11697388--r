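---
title: "Methods: spike-train and behavioral analysis of dopamine cue reactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spike-train and behavioral analysis of dopamine cue reactivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuephys)
```

`cuephys` implements the analysis chain used to study how ventral tegmental
area (VTA) dopamine neurons respond to cues predicting opioid versus natural
rewards: peri-event firing quantification, an activity-based classification
of putative dopamine neurons, behavioral cue-reactivity indices, and a
case-control similarity test. Because the questions it answers are about
recovery and calibration of the *methods*, the package ships a synthetic
session generator with planted ground truth; every stage is validated
end-to-end against what was planted.

## Data model

A `session()` holds spike trains (seconds from session start), a long-format
event table (`cue_on`, `reward_delivery`, `lever_extension`, `port_entry`,
...), and a trial table referencing event rows. Two tasks are modeled:

* **Pavlovian**: three 5-s auditory cues predict oral sucrose, an
  intravenous opioid infusion, or nothing; rewards are omitted on 10% of
  rewarded-cue trials; intertrial intervals are 11–150 s after
  sucrose/neutral trials and 110–320 s after drug trials (letting the drug
  effect clear).
* **Operant**: trial light → +2 s lever extension → lever press → +1 s one
  of three auditory cues → a port entry after cue offset that must match the
  cue's side → confirmation light → dual water reward (the drug cue adds an
  infusion during training; the second reward is omitted in block 2 of
  recording sessions).

All times are seconds internally; windows quoted in milliseconds in the
literature are converted at the interface, which avoids unit mistakes (one
published window is printed as "1000–2000 s" where only ms are physically
possible; we read it as 1000–2000 ms and expose the window as a
configuration value). On disk, times are stored at microsecond resolution
and the reader/writer pair round-trips sessions exactly, including through
JSON (numbers are canonicalized through their 6-decimal representation
because JSON parsers may differ from `strtod` by one ulp).

Port occupancy is reconstructed from paired entry/exit events; an entry
left open at the end of a session is closed at `session_end` (the source
procedures do not state how truncated bouts are handled).

## Peri-event quantification

Spike counts are binned at 10 ms in half-open bins `[left, right)`; a spike
exactly on an edge belongs to the right-hand bin. Binning conserves counts
exactly — a property tested as an invariant.

Smoothing uses a causal exponential kernel with 200 ms support; the decay
constant is not fixed by the description we follow ("a causal exponential
kernel over 200 ms"), so it defaults to τ = 50 ms and both support and τ
are arguments. The kernel is normalized to unit sum and the left edge is
renormalized by the partial kernel mass, so a constant-rate input is
returned unchanged everywhere while strict causality is preserved; an
impulse placed at least one kernel support inside the window keeps its mass
to within 1e-9.

Phasic responses are mean rates 30–500 ms after an event minus the mean
rate 0–1000 ms before the trial's baseline event, computed per trial and
averaged. In the Pavlovian task the baseline event is cue onset; in the
operant task lever extension serves as baseline for lever/auditory-cue
responses and the pre-light-cue period for light/reward responses.
`windowed_response()` generalizes this to the detection (30–180 ms) and
valuation (180–500 ms) cue phases, the reward response (0–400 ms after cue
offset) and the omission periods (0–200 and 200–1000 ms).

## auROC normalization

Each bin's across-trial count distribution is compared to a pre-event
baseline distribution by the area under the ROC curve — equivalently the
Mann–Whitney U statistic divided by the product of sample sizes, ties
counted one half. 0.5 means no change; excitation pushes values toward 1,
inhibition toward 0. The implementation is rank-based and is required, in
tests, to match a brute-force all-pairs enumeration to 1e-12 and to satisfy
`auroc(a,b) + auroc(b,a) = 1` exactly.

The reference description does not say whether the baseline sample is
pooled across the pre-event bins or kept per bin; we default to pooling
(which stabilizes the reference at 10-ms bins where counts are sparse) and
expose `baseline_mode = "per_bin"` as the alternative.

## The classification cascade

`classify_units()` follows the activity-based identification pipeline:

1. **Screen for cue responsiveness.** A unit passes if any bin of its auROC
   trace in the first 500 ms post cue leaves the band [0.35, 0.65]. The
   screening trace is computed on 100-ms counts (`screen_bin`), not the
   10-ms analysis bins: with 10-ms bins the counts are nearly binary and
   the auROC of even complete silencing is floored at
   0.5·P(baseline bin empty) ≈ 0.46 for baselines under 12 Hz, so no
   moderate-rate inhibited unit could ever be flagged. The band, window and
   bin are configurable, and the screen is permissive by design — its
   outcome is logged per unit.
2. **Response matrix.** Pavlovian: the unit's auROC trace from 0.5 s before
   to 5.5 s after sucrose cue onset (600 bins). Operant: the trace around
   lever extension (−250 to 1000 ms) concatenated with the trace around
   reward delivery (−250 to 500 ms), 200 bins, each segment normalized
   against its own pre-event counts.
3. **Functional clustering.** Column-centered, unscaled PCA; the first
   three component scores are clustered agglomeratively with Ward linkage
   on Euclidean distances (`hclust(method = "ward.D2")`) and cut at three
   clusters. Labels are assigned automatically (the published pipeline
   assigned them by inspection): the cluster with the lowest mean post-event
   auROC is `inhibited`; of the remaining two, the one with the larger
   early-peak (first 250 ms) minus late-mean contrast is `phasic`; the
   third is `excited`. A manual override is possible by re-mapping the
   returned assignment.
4. **Baseline exclusion.** Units with baseline firing above 12 Hz
   (intertrial-interval rate by default) leave the phasic cluster.
5. **k-means refinement.** Within the remaining phasic units, features
   log(peak firing time 50–1000 ms post cue, 20-ms bins, earliest bin on
   ties, bin midpoint reported), log(ISI CV computed over the whole session
   excluding ISIs touching the 500 ms after any cue or reward event), and
   the inhibition index (R−B)/(R+B) are z-scored, reduced to two principal
   components and split by k-means (k = 2, Euclidean distance, 20 seeded
   replicates, best by within-cluster sum of squares, ties to the lowest
   replicate). The cluster whose centroid has the larger mean log peak time
   (tie-broken by more negative inhibition) is flagged atypical — the
   delayed, labile, reward-inhibited subpopulation. Rows are canonically
   ordered before clustering so the flags are invariant to input order.
   In the Pavlovian variant R is the mean rate 1–2 s after reward; in the
   operant variant R is the lower of the mean rate 0–1 s before or after
   reward.
6. **Manual exclusions** are an explicit input list, never inferred.

The report telescopes exactly: screened units split into the three
functional clusters, and the phasic cluster into putative + high-baseline +
atypical + manual. Applying the published stage counts (165 phasic, 39
high-baseline, 21 atypical, 6 manual) reproduces the published total of 99
putative dopamine neurons; tests assert this arithmetic and the
determinism of the whole cascade under a fixed seed.

Waveform analysis (amplitude ratio of the first positive peak before the
first negative peak to that negative peak, −1 when no positive peak
precedes; half duration from the first negative peak to the next positive
peak or the 1.1-ms waveform end) and two-threshold burst detection (onset
ISI ≤ 80 ms, continuation ≤ 160 ms — a field convention; the source does
not state its criterion) are provided as companions. Note that slowing a
train can split one long burst into several, so the burst *count* is not
monotone under time dilation; the spikes-in-bursts fraction is, and that is
the invariant tested.

## Behavioral metrics

Lever-press latencies (one press per trial; non-responses censored at the
10-s deadline) are summarized as a hazard curve in 100-ms bins:
`P(press = t | press ≥ t)`. Bins with nobody at risk report an undefined
hazard rather than zero so session means are not biased. The cumulative
press fraction derived as `1 − Π(1 − h)` equals the empirical cumulative
fraction on any input — an algebraic identity the tests exercise.
`mean_hazard()` averages the defined bins over 0–2 s.

Cue-reactivity indices: the relative trial accuracy index (% correct
drug-cue trials / % correct water-cue trials), first-entry congruence
(among correct trials, the probability that the first feeder entry at or
after cue onset is on the cue's side), the ratio of total congruent entries
B/A accumulated from cue onset to 1 s past offset (with a least-squares
slope over the cue segment; a per-trial-averaged reduction is available —
the source does not state which reduction its curves use, so both are
exposed with session-sum as default), and the progressive-ratio breakpoint
read off the printed 25-step exponential schedule. All indices are
invariant to trial order.

## The similarity test

To ask whether one subject's profile resembles the naive rather than the
exposed group, four measures per session (behavioral: cumulative entry
ratio, trial accuracy index, mean hazard, congruence ratio; or firing:
mean responses to lever extension, auditory cues, light cues, rewards) are
z-scored — they carry heterogeneous units, and unscaled PCA would be
dominated by one column; an unscaled variant is a flag — and reduced to two
principal components. The observed score resamples the naive and exposed
rows with replacement (2000 draws), computes each group's mean Euclidean
distance to the target centroid, and averages the difference
`mean_dist(naive) − mean_dist(exposed)`; negative values mean the target
sits closer to the naive group. The published formula sentence is
grammatically ambiguous about the sign; we fix the convention so that its
interpretive sentence ("negative values reflecting greater similarity … to
the naive group") holds literally.

The null distribution relabels the pooled sessions 50,000 times preserving
group sizes. Each null score is the direct relabeled distance difference;
nesting a full 2000-draw bootstrap inside each relabeling (10^8 draws) is
available as `inner_mode = "bootstrap"` for fidelity checks at reduced
size. Significance is two-tailed at 95% on the percentile of the observed
score. Each group's bootstrap RNG stream is keyed to its group label rather
than its role, which makes the score flip sign *exactly* when the naive and
exposed roles are swapped. Calibration is tested by simulation: under
exchangeable groups the test rejects at the nominal 5% (±2% over 500
datasets at a reduced null of 2000), and under the generator's planted
target–naive affinity the observed percentile falls below 2.5 in at least
80% of seeded runs.

## The synthetic generator

Spiking is a time-rescaled gamma-renewal process over an inhomogeneous rate
function: constant baseline, additive Gaussian bumps and box kernels locked
to events, multiplicative pauses, floored at zero. Gamma shape 1 is an
inhomogeneous Poisson process; shape below 1 inflates the ISI CV (labile
firing), above 1 regularizes it. The rate is integrated on a 5-ms grid and
inverted by interpolation; a stationary 5-Hz unit over 600 s reproduces the
Poisson count law within Monte-Carlo error (tested).

Planted classes and their defaults (chosen once, by forward calculation of
Poisson-auROC separability at the task's trial counts, to mirror the
qualitative contrasts the published figures show; they are configuration
values, not estimates of the recorded data):

| class | baseline | event kernels | ISI shape |
|---|---|---|---|
| canonical phasic | 5 Hz | cue bump 25 Hz, latency 100 ms, σ 30 ms; reward bump 20 Hz | 1.5 (CV ≈ 0.8) |
| sustained excited | 6 Hz | +8 Hz box over the cue | 1 |
| inhibited | 8 Hz | ×0.15 pause over the cue | 1 |
| atypical | 5 Hz | bump 15 Hz at 600 ms, σ 250 ms; ×0.15 pause 0–2 s post reward | 0.45 (CV ≈ 1.5) |
| high baseline | 18 Hz | canonical bumps ×1.4 | 1 |

Opioid exposure is modeled as a multiplicative gain (default 1.3) on
baselines and bump amplitudes — the source reports no quantitative effect
size, so this is a placeholder for testing direction, not an estimate.
Behavior is generated from planted draws: geometric press latencies over
100-ms bins (hazard 0.35 exposed / 0.20 naive), an anticipatory during-cue
port entry on every completed rewarded trial whose side follows the planted
congruence probability (A 0.80 / B 0.95 exposed; symmetric 0.85 naive), and
a post-cue decision entry following the planted accuracy. The anticipatory
entry occurs on every trial so the first-entry congruence estimator reads
the planted probability directly. The operant auditory cue lasts 2 s (its
duration is unstated in the source procedures). Intertrial intervals are
uniform within the published ranges ("pseudorandomly" is not otherwise
specified).

What the generator does *not* emulate: spike sorting artifacts, drift and
unit loss, correlated noise across units, pharmacokinetic dynamics beyond a
configurable diffuse envelope, and any within-session learning. Passing
tests therefore demonstrate that the pipeline recovers structure of this
statistical form at these effect sizes — not that the pipeline is robust to
every pathology of real recordings.

## Reference problem sizes and numerical choices

The reference roster is 200 units (60 canonical, 40 sustained, 30
inhibited, 30 atypical, 40 high-baseline) in a Pavlovian session with 40
sucrose and 20 neutral trials at the task's stated intertrial intervals;
under a fixed seed the cascade recovers the planted classes with balanced
accuracy ≥ 0.90 (in practice ≥ 0.98) and peak times within one 20-ms bin
for ≥ 90% of canonical units. Calibration simulations use 500 datasets with
the null reduced to 2000 relabelings, and 50 seeded power runs. Degenerate
inputs are refused loudly: zero-variance feature sets are never split
arbitrarily, empty groups and zero-duration baseline epochs are errors,
all-tied correlations return an undefined flag. k-means determinism comes
from seeded replicate initializations with ties broken by replicate index;
row order is canonicalized first.

## Limitations

The functional cluster labels are assigned by an automated heuristic where
the original pipeline used visual inspection; with response profiles unlike
the planted archetypes the heuristic's early/late contrast could mislabel,
which is why the full assignment object (dendrogram, PC scores, cluster
means) is returned for audit. The published unit counts are internally
inconsistent in places (a 77 vs. 75 exposed-unit count; an operant cascade
whose printed stages do not subtract to its printed total); the report
reproduces arithmetic from its own inputs and does not force agreement with
any published total.
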