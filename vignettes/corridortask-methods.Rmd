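---
title: "Methods: analysing V1 population activity in a virtual-corridor reward task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing V1 population activity in a virtual-corridor reward task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corridortask)
```

## The task and the data model

Head-fixed mice run on a cylindrical treadmill that drives a virtual linear
corridor. The walls carry a grating pattern; at 80 cm of virtual distance the
walls turn black, marking the reward zone. A lick within the first half of
the zone (80–100 cm) triggers an *early* reward at the lick position
(a successful trial); otherwise a *default* reward is dispensed at 100 cm.
Two manipulations probe what drives the behaviour and the neural responses:

* **Uncued trials** (one in five): the black-wall landmark is removed, so the
  animal must locate the reward zone from self-motion alone.
* **Gain trials** (one in five): the treadmill-to-virtual gain drops from 1
  to 0.75, so 80 cm of physical running corresponds to only 60 cm of virtual
  corridor. A response anchored to physical distance then dissociates from
  one anchored to the visual scene (80 cm virtual ≈ 107 cm treadmill).

The package consumes a *session bundle*: per-frame behaviour at the imaging
rate (40 Hz), per-trial records, lick events, and a neurons-by-frames raw
fluorescence matrix. Traces are assumed motion-corrected and
neuropil-decontaminated; ROI extraction is out of scope.

Because both the uncued and the gain schedule are fixed period-5 cycles, two
cycles on the global trial index would be either identical or disjoint —
uncued gain trials would never exist, yet the gain analysis is defined on
uncued trials. The generator therefore cycles the gain schedule *within*
each cue class: every fifth cued and every fifth uncued trial runs at the
reduced gain. The 1-in-5 marginal rates are preserved and all four
cue-by-gain combinations occur.

## The synthetic-session generator

`simulate_session()` produces bundles with known ground truth. It emulates:

* **Kinematics.** Per-trial mean speed is log-normal (median 15 cm/s,
  sdlog 0.4 — the source experiments report no speed statistics, so these
  are chosen as typical for trained head-fixed mice), modulated smoothly
  within the trial, with a slowdown to 55% once the animal enters the
  reward zone (mice decelerate to lick). The slowdown is what couples
  running speed to task phase; without it, speed-coupled neurons would
  never show pre/post differences.
* **Licking.** Policies range from `uniform` (novice-like, spatially
  indiscriminate) to `expert` (Gaussian around a target just past the zone
  onset, with a small uniform `stray_frac` of residual novice-like licks).
  On cued trials the expert target is anchored in virtual coordinates (the
  animal follows the landmark); on uncued trials in treadmill coordinates
  (path integration). After each reward a flagged burst of drinking licks
  is added, so behavioural metrics can exclude consumption licking. Policy
  licks beyond the reward event are replaced by the drinking burst, which
  conditions the recorded pre-reward lick set exactly the way real
  recordings are conditioned.
* **Neural tuning.** Each neuron is an inhomogeneous-Poisson event source:
  grating-driven (`corridor`), speed-driven (`locomotion`), lick-driven
  (`lick`), reward-zone (`reward_zone`, virtual frame, cue-independent),
  wall-transition-only (`grating_offset`, cued trials only),
  treadmill- or virtual-anchored Gaussian bumps for the gain analysis,
  `time_locked` bumps for the distance-vs-time control, and `untuned`.
  Default peak rate 8 events/s over a 0.3 events/s baseline gives window
  effect sizes far above 3x the frame noise.
* **Calcium indicator.** Events are convolved with a single-exponential
  kernel (tau = 0.4 s, GCaMP6f-like), scaled onto a baseline fluorescence
  of 100 with 0.2 dF/F0 per event, plus Gaussian noise (SD 1.5% of
  baseline). The bundle retains the noise-free signal (`clean`) and the
  rate functions (`rates`) so downstream stages can be validated against
  ground truth.

What a green test does *not* establish: the generator has no slow drift,
no neuropil residue, no correlated (shared) noise across neurons, no eye or
pupil signals, and its lick and speed parameters are plausible rather than
fitted. Green recovery tests certify the analysis logic on this stated
world, not performance on any particular real dataset.

## Behaviour: success rate and spatial modulation index

`success_rate()` is the fraction of early rewarded trials; the expert
criterion is strictly greater than 75%. The **SMI** corrects the success
rate for indiscriminate licking: per permutation, each trial's pre-reward
licks (drinking excluded) are re-placed uniformly over the pre-reward
corridor [0, 100) cm, keeping the per-trial count; a permuted trial
succeeds if any lick lands in [80, 100). The SMI is the observed success
rate divided by the mean permuted success rate over 1,000 permutations.
Uniform licking gives SMI near 1, few well-placed licks SMI > 1, frequent
off-target licking SMI < 1. The permutation null has a closed form — with
`k` licks the per-trial success probability is `1 - (1 - w/L)^k` — which
the tests use as an independent oracle. Whether the original analysis
permuted positions or times is not recorded; this package re-places
*positions* uniformly and says so in the report metadata. When no trial
has a pre-reward lick the null mean is 0 and the SMI is reported as
undefined (`NA`), never infinity.

```{r smi}
g <- task_geometry()
tl <- trials_from_licks(lapply(1:20, function(i) runif(3, 80, 100)), g)
compute_smi(tl$trials, tl$licks, g, 1000, seed = 1)
```

## dF/F0 extraction and spatial binning

The raw trace is smoothed with a zero-phase low-pass FIR filter (1 Hz
cutoff, 60th order). The design method is not recorded in the source;
a Hamming-window windowed-sinc design is used, applied forward-backward
(for a symmetric linear-phase kernel this equals two centred convolutions;
edges are handled by reflection). The baseline F0 is the 5th percentile of
the smoothed trace and dF/F0 = (F - F0)/F0 on the raw trace, which is
invariant to uniform rescaling of F and zero on constant traces.

Spatial binning uses half-open 2-cm bins by default (no bin width is
recorded in the source; 2 cm resolves the 25-cm gain window and its ±5 cm
boundaries), positions are 0-based at trial start, and unvisited bins are
`NA`, never zero-filled. Binning can run in virtual or treadmill
coordinates; at gain 0.75 the same frames appear at positions related by
the factor 0.75.

## Neuron classification

* **Task-responsive**: per-trial mean dF/F0 in [onset − 20, onset) cm
  (R_pre) vs [onset, onset + 20) cm (R_post) — the 20-cm width matches the
  early-window width; paired two-sided Wilcoxon signed-rank across trials,
  flagged at p < 0.001 (per-neuron alpha, no multiple-testing correction,
  by design). All-tied differences give p = 1. When the smallest attainable
  exact p (2/2^n two-sided, 1/2^n one-sided) is not below alpha the neuron
  is reported underpowered and never flagged.
* **Category cascade** (the fine-grained criteria are not printed in the
  source; these are reconstructions, flagged as such): decrease-type
  neurons are `locomotion` when the dF/F0–speed Pearson correlation is
  ≥ 0.3 *within the grating section* — restricting to the grating section
  breaks the confound between position and the reward-zone slowdown, which
  otherwise makes every speed-coupled neuron look corridor-driven — else
  `corridor` when grating-section activity exceeds reward-zone activity.
  Increase-type neurons are `lick` when the lick-response control is
  positive, else `reward_zone`.
* **Lick-response control**: mean dF/F0 in ±250 ms around corridor licks
  vs duration-matched non-lick windows, paired signed-rank across events.
  Qualifying licks exclude drinking and anything within 15 cm of the zone
  onset (licks near the onset coincide with wall-transition responses);
  controls are drawn from the same corridor section, ≥0.5 s from any lick.
  Fewer than 10 qualifying licks skips the test with a notice.
* **Reward-location**: one-sided (R_post > R_pre) signed-rank tests run
  separately on cued and uncued (gain-1) trials, flagged only when both
  reach p < 0.001. Grating-offset neurons fail the uncued test (no wall
  transition there) and are excluded implicitly. Fewer than 6 uncued
  trials, or an underpowered test, yields an undetermined (`NA`) flag.
* **Gain-modulated**: trial-averaged profiles in *treadmill* coordinates
  (so the gain-1 window and the expected-onset window coincide at
  [75, 100) cm; inclusive lower, exclusive upper bound), uncued trials
  only; flagged when both argmax positions fall in the window. The flag
  depends only on argmax positions, hence is invariant to response
  scaling.
* **Distance vs time**: per-trial response peaks after aligning by
  position bins and by time-from-onset bins; the across-trial coefficient
  of variation of the peak location is reported for both alignments
  (the original supplementary metric is not printed; this reconstruction
  is the package's own).

## Template-matching decoder

Features are per-neuron window means in [onset − 20, onset + 20) cm;
missing entries are imputed with the neuron's across-trial mean and trials
with >50% missing are dropped. Features are z-scored per neuron — plain
Pearson correlation across neurons is not invariant to per-neuron affine
rescaling, so the standardization is what delivers that invariance
exactly. Leave-one-out cross-validation: class templates are mean vectors
excluding the held-out trial; the held-out trial takes the label of the
most correlated template (ties to the first class level; zero-variance
vectors fall back to negative Euclidean distance). Unbalanced classes are
subsampled to the minority count 100 times and the mean accuracy reported;
chance (1/number of classes) is reported alongside. The similarity
function of the cited template-matching variant is not printed in the
source; correlation is a reconstruction and is recorded in the report.
Note that for weak signals and few trials the LOO estimate is biased
*below* chance (excluding a trial shifts its own class template away from
it); the chance-level tests therefore use the stated 200-trial size.

## End-to-end runs

`run_experiment()` chains simulate → dF/F0 → behaviour → classify → decode
over a multi-day schedule. Learning is emulated by two coupled dials: the
lick policy (uniform → focused expert) drives the SMI, and a per-day
`tuning_scale` on planted peak rates drives the recruitment of
task-coupled activity — which is what produces the positive correlation
between the fraction of task-responsive neurons and the SMI across days.
Everything derives deterministically from the config seed.

## Numerical choices and degenerate inputs

Half-open windows and bins throughout; argmax ties resolve to the first
bin; `findInterval` semantics for binning; all stochastic operations take
explicit seeds and restore the caller's RNG state; session CSVs carry 17
significant digits so bundles round-trip bit-exactly. Empty neuron lists
produce a valid zero-row bundle; non-positive trial counts, non-positive
fluorescence, traces shorter than the filter, single-class decoder labels
and missing uncued successes raise the specific errors documented on each
function.

## Known limitations

No deconvolution or spike inference; no neuropil model; no multi-day ROI
identity tracking; the decoder is deliberately the simple template matcher
(no regularized or probabilistic classifiers); real-data ingestion is
limited to the documented session-bundle format.
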