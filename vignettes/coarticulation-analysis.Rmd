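---
title: "Measuring coarticulation in sequential planar hand movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring coarticulation in sequential planar hand movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coartkin)
```

## The problem

In a sequence task — pass a stylus through four dots A → B → C → D and back
to A, as quickly and accurately as possible — novices produce four separate
point-to-point strokes: straight paths, each with a bell-shaped speed
profile, and a full stop at every dot. With practice (or after observing an
expert), successive strokes begin to overlap in time. The trajectory rounds
the corners, the stops disappear, and the velocity troughs at the
intermediate targets rise. This temporal fusion of motor primitives is
called *coarticulation*, the kinematic face of motor chunking.

`coartkin` quantifies coarticulation per trial, validates the measure
against simulated movements with known overlap, generates synthetic
experimental cohorts with programmable learning dynamics, and runs the
group-level statistics. This vignette records the model, the parameter
choices, and the design decisions.

## The coarticulation score

For a windowed tangential-velocity profile we locate up to four velocity
peaks (local maxima with topographic prominence of at least 5% of the
profile maximum; if more qualify, the four largest are kept, ties broken by
earlier time) and the troughs between them (the lowest point between
consecutive kept peaks). The score is

$$\mathrm{score} \;=\; 100\,\cdot\,
  \frac{\tfrac12 (t_1 + t_3)}{\tfrac14 (p_1 + p_2 + p_3 + p_4)}$$

The second trough is excluded by construction: the reversal at C forces the
speed to (near) zero there whatever the skill level, so it carries no
information about blending. Because every trough is bounded by its
neighbouring peaks, the score lies in [0, 100]; it is invariant to uniform
velocity rescaling and to time dilation, so faster execution alone cannot
change it.

**Inflection-point substitution.** With sufficient overlap a peak–trough
pair vanishes: two bells fuse into one peak that retains only an inflection
(a shoulder). The shoulder's height then substitutes for *both* the missing
peak and the missing trough. Our detector distinguishes two regimes. Near
the transition, the prominence rule has already retired the pair while a
faint sub-threshold local max/min pair still exists; the inflection lies
between the faint extrema and its height is taken as their midpoint, which
keeps the score continuous across the 4 → 3 transition (the faint heights
enter as their mean rather than vanishing abruptly). Once the pair has
truly annihilated, the shoulder is the interior local minimum of |v′(t)|
that is not itself an extremum of v, with the passage time of the merged
target breaking ties between shallow candidates. Trough
ordinals are mapped to the segment boundaries B, C, D by the trajectory's
closest-approach times to those targets when the trajectory is available;
otherwise the smallest observed trough is taken to be the reversal at C and
the ordinals are assigned around it.

**Peak heights in the denominator** are all effective peaks (observed plus
substituted), not only those flanking troughs 1 and 3 — the score contrasts
specific troughs with the overall peak level.

## Preprocessing

* **Smoothing**: least-squares cubic B-spline regression with a fixed knot
  at every 6th sample. We read "smoothing splines with knots every 6
  samples" as fixed-knot regression rather than penalized smoothing because
  a knot grid, not a penalty, is what is specified; it also gives analytic
  derivatives, which is the point of the spline step. Velocity is the
  analytic derivative of the fit — never finite differences of samples.
* **Onset/offset**: movement onset is the last time, before the first
  velocity peak exceeding 35% of the peak velocity, that the velocity is
  below 5% of the peak; offset is the last time velocity exceeds the 5%
  threshold. Both thresholds are relative, so the window is invariant to
  velocity rescaling. Two robustness rules are layered on top: peaks
  qualify only with ≥5% relative prominence (noise ripples must not count
  as "the first peak"), and the offset's supra-threshold excursion must be
  *sustained* for at least 50 ms. The latter matters because spline-smoothed
  sensor noise is correlated over about one knot interval (37.5 ms at
  160 Hz): without the run-length rule, a single ripple during the terminal
  dwell on A drags the offset to the end of the recording and inflates
  every duration by the dwell length.
* **Exclusion**: trials whose largest inter-sample gap exceeds 3 nominal
  sample periods are flagged as discontinuous recordings and excluded. The
  threshold is our choice; only the outcome (a few percent of trials) is
  externally anchored.
* The 500 ms terminal dwell on A is not trimmed explicitly; the threshold
  rule handles it.

## Outcome measures

* **Movement duration**: offset minus onset.
* **Path offset**: mean distance of the windowed trajectory samples to the
  *nearest* of the four straight segments A–B, B–C, C–D, D–A. Nearest-segment
  assignment (rather than segmenting the trajectory in time) is robust to
  coarticulated corner-cutting, where samples near B belong cleanly to
  neither adjacent segment.
* **Spatial error**: per target, the distance from the disc edge (diameter
  5.4 mm) to the trajectory's closest approach, zero if the disc is entered;
  summed over the four targets, in mm. Target A is counted once although the
  movement starts and ends there.
* **Normalization**: duration normalizes to percent improvement over the
  subject's own pre-test baseline, 100·(base − x)/base. Coarticulation
  scores normalize by *subtraction* — baseline scores sit near zero, so a
  ratio would explode.

## The validation simulation

Each stroke is a straight-path minimum-jerk movement with displacement
profile 10τ³ − 15τ⁴ + 6τ⁵ and peak speed (15/8)·D/T. A trial is the vector
sum of four strokes A → B′ → C → D′ → A. *Overlap* o means the next
stroke's onset precedes the previous stroke's end by o·T (so o = 0 is strict
concatenation and the sweep tops out at 55%); it is applied to the stroke
pairs (1,2) and (3,4), while pair (2,3) is pinned to zero overlap because
the reversal at C forces a stop. All strokes share one duration (default
T = 0.5 s, giving a 2 s noviceline trial) and dt = 1/160 s matches the
recording rate.

With overlap, strokes aimed at the physical targets cut the corners, so
virtual via-points B′ and D′ are found by derivative-free optimization
(Nelder–Mead, warm-started along the sweep) such that the superposed path
passes within 10⁻³ cm of B and D. Two numerical details matter:

* The constraint "path grazes the target" leaves a one-parameter family of
  via-points. A small anchor penalty (10⁻⁴·|via − target|², with a BFGS
  polish after the Nelder–Mead solve) selects the member nearest the
  physical target; without it, a warm-started sweep drifts along the
  solution family into degenerate geometry, and with a much weaker anchor
  the optimizer's positional noise in the soft direction is visible as
  ripple in the predicted curvature curve. The penalty's contribution to
  the miss distance (< 3·10⁻⁴ cm at the highest overlap) stays below the
  10⁻³ cm tolerance.
* Closest approach is computed in continuous time (vectorized grid
  refinement plus a parabolic step), since the discrete 160 Hz samples
  straddle the target by far more than the tolerance.

Sweeping 551 equally spaced overlaps from 0 to 55% yields the predicted
score and curvature curves: score(0) = 0, both curves increase
monotonically, and the peak count drops 4 → 3 exactly once. Extremum
heights are refined by local parabolic interpolation; at the 160 Hz grid the
sampling phase shifts with overlap, and without refinement that
discretization ripple is comparable to one grid step of the score curve.
`estimate_overlap()` inverts the score curve by monotone interpolation,
which the recovery tests use to map measured scores back to overlap.

**Layout geometry.** Target coordinates are configuration, with a packaged
default: A = (0,0), B = (5.5, 3), C = (12, 0), D = (6.5, −5.5) cm. The two
corners are deliberately unequal. Whether the velocity dip at a corner can
vanish at high overlap depends on the heading change there, not only on
temporal overlap: with two ~90° corners no peaks ever merge within the
0–55% sweep, and with mirror-symmetric corners both pairs merge at the same
overlap (peak count 4 → 2). A shallow ~53° turn at B and a sharp ~80° turn
at D give the observed progression — one pair merges (4 → 3), the other
stays distinct — matching the attribution of three-peak profiles to
A→B→C blending. The mirror transfer reflects x about the midline between
the leftmost and rightmost targets (the layout midline; whether the
original reflection axis was screen or layout midline is not documented, so
this is configurable). The scaled transfer shrinks center distances by 30%
about the centroid and keeps the 5.4 mm discs.

## The synthetic cohort

The generator emulates the study conditions: 4 groups × 15 subjects; day 1
pre-test (60 trials), six training blocks (30 physical trials for the
observation and random-motion groups, 60 for the double-physical-practice
group), post-test; day 2 trained, mirror and scaled tests (60 trials each).
Group profiles encode the assumed dynamics:

* **OG** (observation): overlap steps from 0 to a plateau within the first
  5 trials of block 1, then drifts up linearly block by block; duration
  drops from 2.00 s to 1.38 s at the same step.
* **SOG** (slowed observation): same overlap dynamics with a slightly
  steeper drift; duration unchanged.
* **RMCG/DPTCG** (controls): overlap stays at zero; duration unchanged.
* All groups speed up ~12% in the scaled transfer (shorter distances, same
  disc size — the usual speed–distance trade).

The plateau and drift values (OG 0.175 + 0.0042/block, SOG 0.20 +
0.0055/block) are calibrated through the simulated score-vs-overlap map so
that measured score gains land near +20/+25 points with training slopes
near +0.7/+1.0 points per block — the outcome magnitudes the generator is
meant to emulate. The paper-style reports give outcomes, not generative
parameters, so jitters are our choices: between-subject overlap SD 0.03,
trial-to-trial SD 0.02, multiplicative duration jitters of 5% (subject) and
4% (trial), positional sensor noise SD 0.03 cm at 160 Hz.

Trials are built from the superposition engine with via-points interpolated
from a per-layout lookup table (solved once on a 23-point overlap grid —
via-points vary smoothly with overlap, and a per-trial solve would dominate
the runtime). Target misses are injected with a per-session probability by
shifting the via-point away from the target; the trajectory stays a smooth
superposition, and the spatial error becomes nonzero. The accuracy cost of
observation training is transient: miss probability 0.55 at post-test for
the observation groups, back to the 0.10 baseline at day 2, elevated again
in the mirror transfer. The post-test rate must exceed 0.5 for the bump to
be recoverable at all: subject-level summaries use the *median*, and the
median of a mostly-zero measure is identically zero below that rate.
Recording gaps (dropped sample runs) are injected in 3.3% of trials and are
what the continuity screen is expected to catch. Observation trials (video
playback) produce no trajectory rows — only physical trials are emitted.

One identifiability note: positional sensor noise lifts the measured score
by a couple of points even at zero true overlap, and the inverse of the
score–overlap map sends that floor to an apparent overlap of roughly 0.06.
Overlap recovery is therefore meaningful for subjects with programmed
coarticulation; for non-coarticulating subjects the estimate is bounded by
the noise floor rather than converging to zero.

What the generator does *not* emulate: biomechanics (no arm model, no
speed–accuracy trade within a trial), trajectory-shape idiosyncrasies,
correlated sensor noise, or any mechanism of observation-to-execution
transfer — it produces the assumed statistical structure only. Passing
recovery tests therefore shows that the pipeline measures what the
generator programmed, not that humans behave like the generator.

## Statistics

Summaries collapse trials to one row per subject × session × block (or
5-trial bin): median for duration and spatial error, mean for score, path
offset and peak count; excluded trials are dropped first, and normalized
columns use each subject's own pre-test baseline. The battery:

* **Mixed-design (split-plot) ANOVA** — between-subjects group,
  within-subjects session or block — via a multivariate linear model with
  type-III sums of squares. With three or more within levels the
  Greenhouse–Geisser correction is applied (and reported alongside the
  uncorrected p); sphericity handling is toggleable. Subjects with missing
  cells are dropped listwise, mirroring reduced error dfs.
* **Slopes**: per-subject OLS slope of the block means over training
  blocks, then a group-level one-sample t-test — one-tailed (slope > 0) for
  coarticulation-type measures, two-tailed for duration.
* **Non-parametrics for spatial error**: Friedman over matched sessions
  with pairwise Wilcoxon signed-rank follow-ups; Kruskal–Wallis across
  groups with pairwise Mann–Whitney follow-ups; Bonferroni correction
  (raw p × number of comparisons, capped at 1). Fully tied data (e.g. all
  spatial errors zero) reports χ² = 0, p = 1 rather than NaN.
* **Transfer battery**: group × transfer-type ANOVAs on normalized
  duration, normalized score, path offset and peak count, plus the Friedman
  route for spatial error, over the day-2 trained/mirror/scaled sessions.

A 500-replicate null simulation (iid normal responses in the 4 × 15 × 3
design) checks that the interaction test holds its nominal 5% level; with
sphericity true, the Greenhouse–Geisser-corrected test is expected to sit
at or slightly below 0.05.

## Problem sizes and numerical choices

The packaged analyses use: the full 551-point sweep (a few minutes,
dominated by via-point solves); a complete default cohort of 60 subjects /
~31,500 trials through generation, measurement and statistics (under ten
minutes); 500 null replications for the type-I check; and 200 randomized
profiles for the oracle-equivalence checks. Optimizer tolerance is 10⁻⁶ cm²
on the squared miss with up to 5 deterministically jittered restarts; spline
order is cubic (the knot rule fixes spacing, not order, so cubic is the
conventional choice); all tie-breaks prefer earlier times. Degenerate
inputs (flat profiles, all-tied ranks, single-level factors, too-few
samples) raise informative errors or fixed conventions rather than NaNs.

## Known limitations

* The score presumes the four-target task structure (troughs indexed to
  B, C, D); other sequences need a re-mapping of trough ordinals.
* Inflection substitution relies on a detectable shoulder; at extreme
  overlap (beyond the simulated 55%) two pairs can merge and the remaining
  structure is extrapolation.
* The mirror reflection axis and the original layout coordinates are
  conventions, not reproductions.
* Group profiles reproduce outcome *patterns*; their variance components
  are calibrated, not estimated from human data.
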