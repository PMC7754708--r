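---
title: "Methods: quantifying all-optical place-cell perturbation sessions"
author: "optoplace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying all-optical place-cell perturbation sessions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`optoplace` quantifies experiments in which head-fixed mice navigate a
200-cm virtual linear track while CA1 pyramidal cells are imaged with a
calcium indicator at 30 Hz and a chosen ensemble of them is photostimulated
each time the animal crosses a trigger point at 105 cm. This vignette is
the package's own account of the models and procedures it implements, the
parameters that matter, the numerical choices made where the design was
genuinely open, and what its synthetic sessions can and cannot certify.

## The task and the session

The animal must dwell at least 3 s and lick at least 3 times inside the
reward zone (160–178.6 cm) to receive reward; licking more than 10 times
outside the zone, or running into the back wall, aborts the trial.
Successful trials are followed by a dark timeout of at least 5 s, failures
by a white timeout of at least 10 s, and a new trial requires 3 s without
licking. A session consists of four epochs — baseline (15 min), pre
(5 min), stimulation (10 min), post (5 min) — laid out contiguously in
session time by `epoch_set()`. During the stimulation epoch, each crossing
of the 105-cm point triggers a 1045-ms bout in which five target clusters
are each illuminated for 100 ms (5-ms gaps) twice over.

Behaviour is sampled at 100 Hz (`behavior_timeseries()`), fluorescence at
30 Hz (`trace_matrix()`), and `build_trial_table()` derives one record per
in-world segment with the outcome assigned strictly by the rules above.

## The synthetic session generator

No public dataset accompanies this preparation, so the generator
(`make_session()`) is a first-class, tested component: it emulates the
study conditions and plants every quantity the analyses later recover.

**Behaviour.** Running is piecewise-constant-velocity (segments of
0.5–1.5 s, speeds drawn around 11.6 cm/s, truncated at 6 cm/s) with a
linear deceleration over the last 15 cm before a stochastic stop inside
the reward zone on correct trials. The mean segment speed was chosen
analytically so that a 10-min stimulation epoch completes about 19
"good" trials (trials reaching the trigger point), matching the task's
reported throughput; trial outcomes are drawn with a 61% success
probability. Licks are Poisson with state-dependent rates (planted licks
guarantee the 3-lick reward precondition; lick-failure trials place
exactly 11 out-of-zone licks and terminate at the 11th). Rule obedience
is absolute by construction and is re-checked in the tests by an
independent replay oracle over the raw event log. An optional planted
lick-rate increase inside the stimulation zone, and an optional planted
slowdown whose centre can move across trials, drive the behavioural-effect
and deceleration-progression analyses.

**Calcium.** Each neuron emits Poisson transients convolved with a
single-exponential indicator kernel (decay 0.4 s, instantaneous rise) plus
Gaussian noise (SD 0.05 dF/F); raw fluorescence is `F0 * (1 + dF/F)` with
per-neuron `F0`. Place cells (27% of 600 neurons by default, including
~44 start-zone and ~49 reward-zone cells) modulate their event rate as a
Gaussian bump over position (SD 6–14 cm, peak rate 2 Hz, expressed while
running). Planted remapping displaces field centres by `post_shift` cm in
the post epoch only.

**Ground-truth zone labels.** The label planted for each cell is computed
from the *expected trial-averaged map* implied by the generative model:
the Gaussian rate bump convolved with the forward exponential kernel
(spatial length = running speed × decay ≈ 4.6 cm — calcium smears fields
forward along the track) and with the pipeline's 3-bin spatial smoothing.
The map, not the rate bump, is what the classifier sees, so truth is
defined at that level; it is computed from model parameters alone, never
from a simulated realisation.

**Stimulation.** Targets fire a transient of `response_amp` (default 0.6,
deliberately below the mean planted in-field amplitude of ~0.7 so evoked
responses stay smaller than natural place-field activity) with per-trial
probability 0.8, time-locked to the completion of their cluster's two
illuminations. Frames overlapping the bout are flagged in the artifact
mask. Planted network perturbations come in two forms chosen for
identifiability under the analysis pipeline: *suppressed* cells have
their activity above `F0` scaled down from the onset to the end of the
trial, participating on 60% of trials (a perfectly uniform multiplicative
change would be absorbed by within-epoch standardisation and is
undetectable in principle); *enhanced* cells — including targets when
`target_perturb = "enhanced"` — gain additive stimulation-coupled
transients after the onset, which changes the spatial activity profile the
way enhanced cells appear in stimulus-triggered averages. Suppressed and
enhanced cells have their fields placed in the window after the
stimulation zone (124–148 cm), because the perturbation assay scores
activity there; suppression of a cell that is silent in that window is
unrecoverable by any estimator. Optional off-target responders are placed
within a configurable distance of a beamlet to exercise the proximity
filter.

## Fluorescence processing

`compute_dff()` removes slow drift by normalising each frame by the 8th
percentile of the raw trace in a 10-s window centred on the frame and
truncated at the recording edges (an order-statistics sliding window in
C++, interchangeable to machine precision with a brute-force per-frame
percentile). Analysis frames are restricted to running (> 5 cm/s, strict)
via `velocity_mask()`. `spatial_tuning_map()` averages dF/F per trial in
2.27-cm bins (88 bins; positions beyond the last full bin fall into it)
and smooths with a Gaussian kernel of SD 3 bins, truncated and
renormalised at the track ends — the track is linear, so no wraparound.
Bins without filtered occupancy are missing, never zero-filled, and are
excluded from averages, correlations and centres of mass. Event rates
count upward crossings of mean + 3 SD within the masked epoch.
`match_rois()` implements the cross-epoch stability filter (greedy
one-to-one centroid pairing within 4 pixels of the 512-pixel, 800-µm
field).

## Place fields and zones

Candidate fields are maximal contiguous runs of bins above baseline + 25%
of (peak − baseline); a field is accepted if it is 9–120 cm wide, its
in-field mean is ≥ 3× the out-of-field mean, it shows significant
in-field activity (above the trial's out-of-field mean + 2 SD) on ≥ 25%
of trials, and its peak reaches 0.20 dF/F. No bootstrap is used. The
concrete contiguity/width/ratio/reliability values instantiate a
criteria lineage that is cited rather than printed in full in the
methods this package operationalises; they are configurable
(`field_criteria()`), while the 0.20 peak floor and the absence of a
bootstrap are fixed as stated. A cell is a Start-PC or Reward-PC when a
field covers strictly more than half of the respective zone (21.4–48.8 cm
or 160–178.6 cm), a stimulation-zone cell for the configured 105–126.21 cm
window, with start/reward taking precedence; ties between start and
reward resolve to the larger coverage. The centre of mass weights the
trial-averaged map above its floor plus 25% of its range — the same
relative threshold that delimits candidate fields. The raw map is not
used because the sliding-percentile baseline leaves a positive pedestal
(about 1.4 noise SDs of dF/F) along the whole track, and sparse
out-of-field transients add further mass; both drag a raw COM toward the
track midpoint and would systematically shrink measured field shifts.

## Photostimulation responses

Peri-stimulus traces are raw fluorescence, 30 frames before to 120 after
the bout onset, normalised by each trial's mean over frames 5–29 of the
extract (all pre-onset). Ten response windows of 3 frames (~100 ms) open
when each cluster illumination completes; a cell's preferred window is
the trial-averaged argmax (ties to the earliest), and it is responsive iff
dF/F exceeds 0.40 on strictly more than 30% of trials there (window mean;
whether the original analysis used window mean or peak is not stated, and
the mean is the more conservative choice). Window statistics can exclude
artifact-flagged frames; by default they do not, because the response
windows lie inside the bout and the upstream pipeline this mirrors
measures responses on artifact-corrected frames — the mask exists for
analyses that must drop bout frames outright. Off-target responders are
non-targets that are responsive during stimulation, *not* responsive when
the identical analysis is run at trigger-point crossings of the baseline
epoch (guarding against endogenous tuning), and within 30 µm of a beamlet
(800 µm / 512 px calibration). Response stability is the OLS slope of the
responding targets' population-mean amplitude over trials. The efficacy
score is (responding Reward-PCs − responding Start-PCs) × mean response
amplitude, i.e. specificity × count × amplitude.

## Behavioural statistics

Lick rate, speed, occupancy and deceleration events are binned at 3.03 cm
(66 bins) per trial; stimulation-epoch analyses use good trials only.
Deceleration events are 0.1-s acceleration intervals below the session
mean − 2 SD (in-world samples; consecutive subthreshold intervals merge).
Epoch contrasts subtract the baseline-epoch spatial distribution from the
stimulation-epoch one; summaries average bins whose centres fall in the
21.21-cm post-trigger window, the reward zone, or the 15.15-cm
pre-trigger deceleration window. Outcome changes subtract the matched
control-day drift. The deceleration-peak progression computes, for every
sliding block of 3 good trials, the bin of maximal increase over baseline
and regresses peak location on block index (R² and slope). Its null
permutes the *order of the trials* and rebuilds the sliding blocks each
time: overlapping blocks share trials, so the trial — not the block-peak
sequence — is the exchangeable unit; permuting the peak sequence directly
is measurably anti-conservative. The headline analysis uses 100,000
shuffles; the test suite uses 1,000 with identical machinery.

## Latent population analysis

After removing bout frames, dF/F of the analysed cells (place cells,
including targets except in non-place-cell sessions) is z-scored per cell
within each epoch over its in-trial frames, then averaged per (trial,
2.27-cm bin); bins that receive any bout frame on any trial form the
latent-analysis stimulation zone and are excluded in every epoch. The
matrix is decomposed by maximum-likelihood factor analysis (10 factors,
unrotated, regression scores, uniquenesses floored at 0.005); rotation is
irrelevant downstream because only full-space Euclidean distances are
used.

Divergence between stimulation and pre epochs is the Euclidean distance
between trial-averaged 10-D trajectories per bin, with the mean over the
ten bins preceding the zone as the reference level. The per-bin
*significance* machinery departs from a literal per-trial sign-rank
against the pre-zone average, for reasons the package's null simulations
make quantitative: distances at reward-dwell bins are intrinsically
larger and more variable than pre-zone bins (the trial-to-trial mix of
stop positions), within-epoch z-scoring puts a cross-epoch floor under
any distance to another epoch's average, and adjacent bins are strongly
dependent. A literal reading false-alarms on the majority of
zero-amplitude control sessions. Instead, each post-zone bin's statistic
is the trial-averaged divergence of the stimulation epoch minus that of
the *baseline* epoch (the session's own unstimulated control arm) from
the same pre average at the same bin; trial labels are permuted between
the two arms, one permutation applying across all bins so spatial
correlation is carried into the null; bins above their permutation 95th
percentile form contiguous clusters whose mass is referred to the
maximum-cluster-mass distribution. A session is "divergent" when a
cluster is significant at the 0.05 cluster level. On simulated
zero-amplitude sessions this procedure detects nothing; at the default
planted amplitudes it detects the perturbation in the large majority of
sessions.

Cells eligible for perturbation scoring must load at least 0.2 on some
factor and change by at most 0.2 SD over the ten pre-zone bins; each
eligible cell's score is its stimulation-minus-pre activity difference
averaged over three bins centred at 136 cm, and the session's bottom and
top deciles are called suppressed and enhanced. The same procedure on
no-stimulation sessions (epochs by experimental time) builds nulls.
Stimulus-triggered averages use standardised dF/F smoothed with a
Gaussian of SD 5 frames.

## Remapping

Cells whose baseline and pre-epoch maps correlate below 0.3 are excluded
as unstable. Pre/post similarity is the Pearson correlation of
trial-averaged maps over mutually occupied bins; field position is the
COM, and the peak of a COM distribution is the mode of a normal-kernel
density (rule-of-thumb bandwidth) on a 0.5-cm grid. The reward-zone
peak-count null translates every cell's trial-averaged map circularly by
an independent uniform offset (mass-preserving; a bounded non-circular
variant is available) and recounts peaks, 10,000 shuffles by default.
With 88 bins of which 9 have centres inside the reward zone, the uniform
expectation is 9/88 ≈ 10.2% of cells, bracketing the continuum value
18.6/200 = 9.3%.

## Numerical choices and degenerate inputs

Half-open spatial bins `[k·w, (k+1)·w)`, 0-based trial ids, 1-based frame
indices; the dF/F window is centred and truncated at the edges; smoothing
renormalises the truncated kernel; strict inequalities at every stated
threshold (speed > 5, coverage > 50%, dF/F > 0.40 on > 30% of trials)
with a 1e-9 tolerance where binary-float arithmetic could flip an exact
boundary; preferred-window ties resolve to the earliest window; zero
variance traces yield rate 0 with a warning; all-zero maps yield missing
COMs; fewer than 3 mutually occupied bins yield missing correlations;
fewer than 10 eligible cells make deciles an error rather than a guess.
Every stochastic routine takes an explicit seed, and identical
(config, seed) reproduce sessions and pipeline outputs byte for byte.

## What the tests show — and what they cannot

The test suite runs the generator at reduced but structurally complete
sizes chosen to keep a full run in minutes: an 80-neuron four-epoch
session for module-level checks, a 600-neuron full-length session for
recovery of planted place cells and responders, twenty 120-neuron
full-length sessions per arm for divergence power and suppression
calling, and 200 repetitions at 1,000 shuffles for permutation-null
calibration. Passing them certifies that the estimators recover what the
generative model plants under its assumptions — Gaussian fields, Poisson
transients, exponential kernel, stationary behaviour. Real sessions add
slow representational drift, neuropil and motion residuals, non-Poisson
burst statistics, and behaviour-correlated noise that the generator does
not emulate; conclusions about real data inherit those caveats, and the
thresholds above (all configurable) were chosen for the emulated regime.
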