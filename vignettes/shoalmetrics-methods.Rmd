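---
title: "Methods: trajectory-based social affinity, locomotion, sleep and metabolic scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trajectory-based social affinity, locomotion, sleep and metabolic scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalmetrics)
```

`shoalmetrics` quantifies the behavioral phenotypes that distinguish the
social, riverine surface form of *Astyanax mexicanus* from its asocial,
cave-dwelling form, and that shift when the fish's metabolism is pushed
toward ketosis: social-like nearby interactions, repetitive lateral turning,
swimming distance, sleep, and vibration-attraction foraging.  It also covers
the metabolic bookkeeping around such experiments — the glucose–ketone index
(GKI), diet-mixture nutrient arithmetic, and supplement dosing.  This
vignette explains each method, its assumptions, the tunable parameters, and
the design choices made where the procedure was genuinely open.

## Conventions

All trajectories live in a `trajectory_set`: per-frame planar positions in
cm for every fish of one group, origin at the arena's lower-left corner,
frame indices 0-based, analysis windows half-open `[start, end)`.  Group
assays are four fish at 20 frames/s in a 49.5 × 24.2 cm arena, recorded for
6 min with the trailing 5 min analysed (`assay_window`); 24-h activity
assays run at 15 frames/s.  Tracking dropouts are kept as explicit `NA`
gaps.  The default gap policy is *no interpolation*: every downstream metric
treats a missing frame as a run-breaker.  Published descriptions of such
pipelines rarely state how dropouts were handled; leaving gaps unfilled is
the conservative choice because it can only shorten, never fabricate, a
proximity run.  `fill_gaps(max_gap_frames = k)` linearly interpolates gaps
up to `k` frames for users whose trackers drop isolated frames.

## Nearby interactions

A *nearby interaction* is a sustained-proximity bout between two fish:
inter-fish distance at most 5 cm maintained for at least 4 s.
`detect_events` finds, per unordered pair (six pairs among four fish), the
maximal runs of qualifying frames; a run of exactly the minimum duration is
included (the tie at 4.0 s is unit-tested, and both thresholds are
configurable through `interaction_criteria`).  Group scores
(`interaction_scores`) are the total event duration and the event count
summed over pairs — a fish may contribute through several pairs at once,
matching the row-additivity of the event raster (`event_raster`).

Peri-event speed profiles (`speed_profile`) report, per fish, the mean
swimming speed in four exclusive categories: the 4 s before an event, during
it, the 4 s after, and the out-of-event remainder.  Speeds are 1-frame
displacements times the frame rate, unsmoothed.  Where the after-window of
one event overlaps the before-window of the next, each sample is assigned to
the nearer event boundary, keeping the category means independent; during
always takes precedence.  Sample counts (`n_during`, `n_out`) are returned
so ratios can be pooled across fish and groups by weighting — per-fish
ratios are noisy whenever a fish's only events are chance encounters.

## The permutation chance criterion

Whether an observed affinity score exceeds what co-housing four independent
fish would produce is decided against a permutation null (`permute_null`,
1000 replicates by default).  The published account of the criterion does
not pin down the permutation scheme, so two constructions are provided and
every output is labelled with the one used:

* **cross_group** (default when enough groups exist): each replicate
  assembles a virtual group whose members come from *distinct* real groups,
  one randomly chosen fish per sampled group — the standard chance-encounter
  null for shoaling assays.  It therefore requires at least as many groups
  as fish per group.
* **time_shift**: each replicate circularly shifts every fish's series of a
  single group by an independent uniform offset of at least
  `min_duration × fps` frames (a floor that avoids near-identity
  permutations).  The shift preserves each fish's marginal path statistics
  except for the one displacement sample spanning the wrap seam.

`exceeds_chance` returns the add-one empirical tail probability
$p = (1 + \#\{\text{replicates} \ge \text{observed}\})/(n+1)$, which can
never be exactly zero.  One property of the cross-group design deserves
emphasis: when the pool of real groups is small, the virtual groups of one
null share many member fish, which under-disperses the conditional null and
inflates the type-I rate.  With pools of four groups the measured rejection
rate at $\alpha = 0.05$ ran around 0.06–0.09; with pools of twenty groups it
sits inside the binomial band around 0.05.  The calibration studies in the
test suite therefore use 25 experiments of 20 groups each (500 p-values);
users testing a handful of real groups should prefer larger pools or read
small-pool p-values as approximate.

Two further facts shape the calibration tests.  First, under the working
4-s criterion roughly a quarter of chance-level simulated groups score
exactly zero, which places an atom of p-values at 1; the rejection rate at
the 0.05 tail is unaffected (the upper tail of the null is continuous), but
distribution-level uniformity is checked with a 1-s scoring criterion where
the statistic is continuous.  Second, event *counts* are not monotone in the
distance threshold — widening the radius can merge two events into one — so
only the total duration is asserted monotone in `max_distance`.

`calibrate_min_duration` reconstructs the criterion-justification step: from
the null it computes, for each candidate duration τ, the expected per-group
number of chance proximity runs of length ≥ τ, and returns the smallest τ
whose expected chance-event count is at most α (default 0.05).  The distance
criterion is held fixed; only the duration is calibrated.

## Turning bias

Travelling direction is evaluated every five frames (0.25 s at 20 frames/s):
headings are net displacements over successive non-overlapping five-frame
blocks, and the signed wrapped angle between consecutive headings classifies
each change as left (anticlockwise, positive radians) or right (clockwise,
negative).  The turning bias is $N_l/N_s$, the larger over the smaller
count, from 1 (balanced) to infinity (fully one-sided).  Design choices the
source procedure leaves open: blocks tile rather than slide (a `sliding`
flag provides the alternative); blocks whose net displacement falls below a
0.1 cm noise floor, or that touch a missing sample, are skipped and break
the heading sequence rather than bridging it.  Infinite ratios are preserved
in reports, and a regularised alternative $(N_{larger}+1)/(N_{smaller}+1)$
is emitted alongside for the Gamma-GLM statistics layer, which cannot accept
infinities; wherever the regularised value is used that substitution is
visible in the output columns.

## Sleep and vibration attraction

Sleep is scored on 24-h, 15 frames/s tracks as maximal runs of immobility —
speed below 0.5 cm/s — lasting at least 60 s.  The assay tradition this
package follows delegates those numbers to the established *A. mexicanus*
sleep protocol rather than printing them, so both are explicit, prominent
parameters (`sleep_params`) rather than buried constants.  Bouts are
detected on the full series and then split at the lights-on/lights-off
transitions (ZT0 and ZT12 under the 12:12 cycle anchored by `zt0_frame`), so
each fragment is attributed to its photoperiod.  Summaries per phase are
sleep min/h, bout count/h and mean bout duration, plus a 10-min binned
series.

Vibration attraction (`vab_count`) counts approaches of the tracked point
into a circle around the vibrating rod during a 3-min assay.  Only
outside-to-inside transitions count; starting the assay inside the circle is
not an approach.  The printed radius of 1.3 mm is smaller than a fish's
snout, so the unit is configurable (`"mm"` as printed — the default — or
`"cm"` as plausible) and is recorded in every result.

## Glucose–ketone index, diets and doses

GKI = glucose (mM) / ketone (mM); values below 9 are called ketosis, the
human criterion, with the threshold configurable.  Meter glucose readings in
mg/dL divide by 18.016 (glucose molar mass / 10); 18.0, the other convention
in the GKI literature, is available because published reports rarely state
which was used, and the divisor is recorded in the result.

`mix_diets` is ratio-weighted averaging of nutrient percentages and caloric
densities — exactly linear, permutation-invariant, identity on self-mixes.
Values are kept at full precision and rounded only at presentation, half
away from zero, because printed nutrition tables round 47.55 up to 47.6
where banker's rounding would not.  `study_diets` ships the three base
feeds of the ketogenic-diet experiments (brine shrimp, the Zeigler zebrafish
diet, KetoCal 3:1) so the KD (5:1 KetoCal:Zeigler) and CD (1:5) columns can
be reproduced.

`dose_convert` implements the supplement feeding model: a fish eats 3% of
its body weight per meal, and 1 mg of agar-suspended feed occupies about
1 µL (the density the 30 mg ≈ 30 µL equivalence implies).  Molar mass is
always an explicit input — published µmol-per-gram figures embed a specific
molar mass, and hard-coding one would silently impose it on other compounds.

## Group-comparison statistics

`compare_groups` follows the reporting convention of this assay family:
linear models for untransformed measures, Poisson GLMs for counts — with an
optional pre-multiplier (`scale_hack`, e.g. ×10 for ketone readings on a
0.1-mM step) applied before rounding to counts — Gamma GLMs (log link) for
positive ratio indices, and a linear mixed-effect model with a random
intercept per group for repeated measures.  Model fitting is delegated to
`stats::lm`/`stats::glm`/`lme4::lmer` with `emmeans` pairwise contrasts
between all factor-level combinations; the Holm step-down correction
(`holm_adjust`) is implemented natively and checked against an independent
reference in the tests.  Stars follow the 0.05/0.01/0.001 convention on the
adjusted values.

## The synthetic trajectory generator

The generator stands in for archived tracking videos: every pipeline stage
is testable against known ground truth, at the assay's frame rates and arena
geometry.  Movement is a correlated random walk — per-frame speed draws
(truncated normal, default 6 ± 1.5 cm/s), heading diffusion (0.3 rad/frame),
specular wall reflection with inward re-randomisation of the heading to
avoid corner trapping — plus three injected structures:

* **Social bouts.** A group-level Markov state (on 0.05/s, off 0.02/s by
  default, i.e. ~50-s bouts) picks a leader–follower dyad at onset.  The
  follower's heading is blended toward the leader each frame; while the dyad
  is within 5 cm both members swim at `social_speed_factor` (default 0.5) of
  their drawn speed — fish slow down to interact — and beyond it the
  follower gets a 1.5× chase boost.  At bout end the dyad parts ways with
  re-randomised headings.  With `attraction = 0` the machinery is inert and
  the fish are mutually independent, the chance-level reference condition.
* **Turning bias.** A turn kick of 0.4 rad every 5 frames goes left with
  probability `left_bias` (0.5, balanced, by default).
  `simulate_turning_walk` provides the noise-free, wall-free version of this
  mechanism for estimator validation.
* **Sleep.** `simulate_sleep_track` alternates exponential active/quiescent
  dwells (or a fixed injected schedule), with quiescent jitter well below
  the immobility threshold, over a folded random walk that keeps positions
  in the arena without distorting speeds upward.

Two generator design choices matter for interpretation.  First, the
follower's per-frame blend weight is `attraction × steer_gain` (gain 0.1):
with the raw blend weight the stationary heading error scales as
$1/\sqrt{1-(1-a)^2}$, which barely changes between $a = 0.6$ and $0.9$, so
detected interaction time would saturate over most of the attraction axis;
the gain maps the axis onto a graded tracking fidelity instead.  Second, the
slowdown is *dyad-only*, not proximity-triggered for all fish: four fish in
this arena are within 5 cm of some neighbour ~18% of the time by geometry
alone, so a global proximity slowdown would contaminate the out-of-event
speed mean and make the during/out ratio unable to recover the slowdown
factor.  The default cruising speed of 6 cm/s keeps full-speed chance passes
mostly under the 4-s criterion (chance-level groups average ~14 s of events
per 5-min assay), and its slowed value, 3 cm/s, is consistent with the
observation that affinity-related slowing lands at or below about 3 cm/s.

What the generator does *not* emulate: vision or lateral-line sensing,
hydrodynamics, wall-following (thigmotaxis), higher-order (3+ fish)
coordination, circadian modulation of activity, and tracker identity swaps.
Passing tests therefore show that the estimators recover the structure this
model injects at the study's recording geometry — not that real fish behave
like the model, nor that the in-vivo effect sizes are reproduced.

## Problem sizes and determinism

All randomness flows from explicit integer seeds; simulations, permutation
nulls and the pipeline (`run_pipeline`) are bit-for-bit reproducible given a
seed, and rerunning a manifest reproduces its outputs byte for byte.  The
test suite exercises the full 5-min, 20 frames/s group assay for the
calibration studies (25 experiments × 20 groups; 99 permutations per null),
the attraction grid {0, 0.3, 0.6, 0.9} at 20 replicates per level, 1000
randomized detector-versus-oracle trajectories of up to 500 frames, and 1-h
sleep tracks for boundary recovery, with 24-h tracks used where dwell-time
asymptotics are the target.  These sizes were chosen so that each stochastic
check has comfortable statistical margin while the whole suite remains quick
to run on a laptop.

## Known limitations

* The two permutation schemes bracket, but do not reproduce, the original
  criterion-calibration procedure, whose exact scheme is not restated in the
  assay's published description; outputs are always labelled by scheme.
* Group scores sum per-pair quantities; if a per-fish averaging convention
  is preferred, the statistics layer operates on whichever aggregation is
  supplied.
* The immobility threshold and the VAB radius unit are declared defaults,
  not attributed values; both are surfaced in results.
* Empirical p-values inherit the granularity of the permutation count, and
  group scores the 1/fps granularity of frame counting.
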