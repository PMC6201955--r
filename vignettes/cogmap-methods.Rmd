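---
title: "Methods: population imaging analysis of multimodal encoding in the commissural ganglion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population imaging analysis of multimodal encoding in the commissural ganglion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cogmap)
```

## Scope and model of the data

The package analyses multineuron voltage-sensitive-dye (VSD) recordings
of commissural ganglion (CoG) somata sampled at 250 frames/s in 20-s
sweeps, under three sensory conditions: chemosensory IV trains (40 Hz),
mechanosensory VCN trains (15 Hz), and simultaneous bimodal trains, each
lasting 6 s. Three analysis windows are defined per sweep, all half-open
`[start, end)`: `stim_PRE` (the 6 s before onset), `stim_ON` (the train)
and `stim_POST` (6 s beginning after a post-train exclusion gap).

A fluorescence trace is modelled as the sum of

1. a slow baseline drift, modelled and removed as a degree-6 polynomial;
2. optical spike transients, one biexponential kernel per action
   potential;
3. slow subthreshold membrane-potential changes, which in this dye
   signal are often larger than the undersampled spikes; and
4. white measurement noise.

The detection chain and the coherence analysis deliberately consume
different parts of this decomposition: spikes are detected on the
high-passed trace (components 3 and 1 removed), while pairwise Pearson
coherence is computed on the drift-removed but *not* high-passed trace,
where the shared subthreshold component carries the co-fluctuation
information.

## Synthetic data: what it emulates, and what it does not

`generate_population()` draws, per neuron: a modality class
(multimodal / unimodal / nonparticipant, defaults 0.80 / 0.18 / 0.02), a
spontaneous rate uniform in 0.33–6.8 Hz, per-condition response labels,
evoked rates (≤ 14 Hz), response latencies (truncated normal, IV
29.7 ± 11.4 ms, VCN 31.9 ± 7.7 ms), and a soma position uniform in a
convex region (no spatial structure, matching the observed null).
Spikes come from a piecewise-constant-rate Poisson process that steps
from baseline to the evoked rate at onset + latency, thinned by a 4-ms
absolute refractory period — action potentials cannot recur within one
camera frame, and a pure Poisson process would otherwise place a few
percent of spikes at physically unresolvable sub-frame intervals.

Choices worth flagging:

* **Joint sign structure.** For multimodal neurons the IV and VCN signs
  are drawn from the joint distribution determined by the per-condition
  excitation probabilities (IV 0.51, VCN 0.55, derived from the
  per-ganglion excited/inhibited percentages) *and* the 46.15%
  sign-switch probability; all three printed marginals are honoured
  simultaneously.
* **Bimodal labels.** Where the additive rule table yields an
  expectation, the observed bimodal label matches it with probability
  0.512 (the observed congruent share among ruled neurons); incongruent
  neurons draw from the observed bimodal composition (59.19% excited,
  33.56% inhibited, 7.25% nonresponsive) restricted to labels differing
  from the expectation. The `bimodal_rule = "additive"` mode instead
  makes the population perfectly additive, which downstream congruency
  scoring must recognise as 0% incongruent.
* **Minimum evoked step (1.5 Hz).** The generator is required to admit
  ≥ 95% downstream label recovery. An excited neuron whose evoked rate
  exceeds its baseline by less than ~1.5 Hz is statistically
  indistinguishable from Poisson jitter in 6-s windows over six sweeps
  (z ≈ 1.6 at the upper baseline rates), so weaker steps would make that
  closure requirement unattainable, not merely hard.
* **Spike kernel.** Biexponential with 1.5-ms rise and 5-ms decay
  (~4 frames wide), so that 250-frames/s point sampling retains ≥ 84% of
  the peak at any frame phase. The kernel peaks
  `kernel_peak_delay()` ≈ 2.6 ms after the spike; peak-based latency and
  spike-time validation subtract this known rendering constant.
* **Shared co-fluctuation.** Responsive neurons within a sweep share a
  slow rate modulation (SD 0.3 of the evoked-rate deviation) and a
  corresponding subthreshold trace component
  (`subthreshold_gain = 1.5` kernel amplitudes per modulation unit).
  The gain is set so that thresholded functional graphs land at a
  realistic few-percent density while detection recall stays ≥ 95%.
  Simulated graph metrics are self-consistency outputs, not calibrated
  targets.
* **Not emulated:** dye bleaching and photodynamics, focal-plane
  bleed-through, electrode artefacts, biophysical spike shapes,
  trial-to-trial adaptation (a lognormal evoked-rate dispersion
  parameter exists but defaults to 0 because the source data do not
  constrain it). Passing tests therefore certify the analysis logic
  under the stated statistical conditions, not robustness to these
  unmodelled features of real recordings.

The pyloric generator builds a triphasic PD → LP → PY rhythm (period
1 s; phases 0 / 0.4 / 0.7 of the cycle) with evenly spaced spikes in
each burst, and applies requested relative changes after the train.
Spikes per burst are integers, so only relative changes mapping to whole
spikes are exactly representable; recovery checks use such changes.

## Detection and classification parameters

| parameter | default | units | rationale |
|---|---|---|---|
| drift polynomial degree | 6 | — | matches the drift model; fit is idempotent |
| high-pass candidates | 5, 10, 20, 40 | Hz | per-neuron tuning range below Nyquist |
| threshold multiplier `k` | 4 | robust SDs | `k·median(|x|)/0.6745`, the standard robust estimate |
| refractory | 0.004 | s | one frame; prevents double counts of undersampled spikes |
| classification dead-band | adaptive | spikes | `max(1, 2.33·SE)`, see below |
| coherence threshold | 0.45 | — | fixed empirical threshold; positive correlations only |
| ratio histogram bin | 0.1 | — | max-normalized per preparation, then averaged |
| post-stimulus exclusion | 1.5 | s | inside the observed 1–2-s dissipation of direct effects |
| burst gap threshold | 0.2 | s | ~20% of the pyloric period; ≥ 2 spikes per burst |

**Adaptive dead-band.** A fixed 1-spike dead-band cannot absorb Poisson
jitter across the stated baseline range: at 6.8 Hz the 6-s count SD is
~6 spikes, and a fixed band mislabels a large share of nonresponsive
condition labels, inflating the multimodal proportion. The default band
is therefore `max(1, 2.33·s)` with
`s = sqrt((mean PRE count + mean ON count)/n_sweeps)`, holding the
false-call rate near 2% at every baseline rate; a fixed numeric band
remains available.

**High-pass tuning score.** For each candidate cutoff the trace splits
into a fast band and a slow residual; the selected cutoff maximizes
`max(|fast|) − max(|slow residual|)`, ties going to the lowest
candidate. For a trace with no fast content the leakage of the slow
component into the fast band shrinks as the cutoff rises, so the score
*decreases* with the cutoff and the lowest candidate is selected — a
direct consequence of the score definition.

**Spike-train matching.** Validation against reference trains uses
greedy globally-nearest-neighbour pairing within one frame; unpaired
test spikes are overdetections, unpaired reference spikes
underdetections. Because detection reports optical peak times, matched
times are first shifted by the known kernel peak delay.

## Numerical and convention choices

* All spike-count windows are half-open `[start, end)`.
* Frequency ratios are undefined (omitted) when the prestimulus
  frequency is zero; frequency differences keep those neurons.
* Latency is the argmax of the trial-averaged trace in a 100-ms window
  after the pulse; ties resolve to the earliest sample; a flat trace
  yields the window start.
* Constant traces have undefined correlations; they are reported as 0
  with a warning flag rather than erroring the whole matrix.
* Only positive correlations above threshold form edges; the optional
  significance gate is the conventional correlation t-test with `n − 2`
  degrees of freedom (the exact pairing of a p-value with the fixed
  threshold is not documented for this preparation, so the gate is a
  toggle, off by default).
* Disconnected pairs contribute 0 to global efficiency (the standard
  convention); shortest paths come from per-source breadth-first search,
  cross-checked against Floyd–Warshall and `igraph`.
* Percentages are reported at one decimal by truncation toward zero:
  the worked example 2m/(K(K−1)) = 162/6320 = 2.5633% is printed as
  2.5% in the source tables, which rounding (2.6) would not reproduce.
* The polygon contour is the convex hull; the centroid is the polygon
  *area* centroid by default (vertex mean available as an option); the
  border distance is measured along the ray from the centroid through
  the neuron, the only reading that keeps `d_ratio ≤ 1` for interior
  points. Angular variance is the circular variance `1 − R̄`.
* Unique-response scoring omits neurons with identical labels in all
  three conditions (not unique participants) and flags/omits the case of
  three pairwise-distinct labels, which the verbal definition does not
  cover; guessing a convention would silently change the reported
  proportions.
* Classification uses mean spike counts across the available sweeps
  (six per condition in the emulated protocols).
* Coherence is computed over the 6-s stimulation window by default —
  the functional maps describe activity *during* stimulation — with the
  window exposed as an argument.

## Problem sizes

The test-suite and acceptance computations run at desk scale, chosen to
keep every check sharp while remaining quick: detection and label
recovery on 20–30-neuron populations (one or six sweeps per condition);
population composition across 12 simulated ganglia of 73 neurons
(~876 neurons, matching the scale of the pooled study sample); 50-seed
null ensembles for the K-S and spatial-null rates; 50 random graphs
(K ≤ 12) for the efficiency oracle; latency on 60 neurons of six
averaged trials per condition.

## Known limitations

* The generator's correlation structure is a single shared slow
  co-fluctuation per sweep; real CoG networks presumably have richer
  (e.g. cluster-structured) covariance, so simulated graph topology
  should not be over-interpreted.
* Weak inhibition at very low baseline rates (≤ 0.5 Hz) is close to the
  information-theoretic detection floor in 6-s windows; a few percent of
  such labels are unavoidably misclassified, slightly deflating
  responsive proportions.
* Group-level hypothesis testing beyond the K-S comparisons (paired
  t tests, repeated-measures ANOVA with post-hoc corrections) is out of
  scope; the pipeline emits the per-ganglion tables such tests would
  consume.
* The command-line surface is the set of numbered scripts under
  `analysis/` plus `run_pipeline()`; there is no separate shell binary,
  as the intended users drive the analysis from R.
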