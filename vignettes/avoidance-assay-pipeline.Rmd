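---
title: "Quantifying two-chamber avoidance from video: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying two-chamber avoidance from video: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chamberchoice)
```

## The measurement

In a dual-chamber forced-choice assay a mouse moves freely between two
connected chambers while one chamber is nebulized with an irritant solution
and the other with saline. The behavioral readout is simple: how much of the
session does the animal spend on the irritant side? chamberchoice turns a
top-down video of such a session into that number, and provides the
aggregation and statistics used to compare genotypes, doses and repeated
exposures — plus a fully seeded simulator so the whole chain can be validated
without animal recordings.

The per-round **behavior score** is

$$ s = \frac{n_\text{irritant}}{n_\text{irritant} + n_\text{saline}} - 0.5, $$

the fraction of assigned track points on the irritant side, re-centered so 0
is indifference, negative values avoidance and positive values preference.
Bounds are $[-0.5, +0.5]$ by construction. Points that fall outside the
traced arena or could not be detected carry no side information and are
excluded from numerator and denominator alike; a round with zero assigned
points is an explicit error rather than a silent zero.

## Tracking by frame differencing

The tracker assumes a dark animal on a lightly illuminated background and a
fixed camera. Every 30th frame is a *reference* frame, paired with a
*comparison* frame 15 frames later; at 30 fps this samples one pair per
second with a 0.5-s lag. For each pair:

1. grayscale conversion (luma weights) and normalization to $[0, 1]$;
2. pixelwise absolute difference $|c - r|$, which is bright wherever the
   animal was in *either* frame (the "old + new" ghost);
3. binarization at Otsu's between-class-variance threshold (a fixed level
   can be configured instead);
4. a morphological opening with a 2-px-radius disc to delete speckle;
5. the sub-pixel centroid of the largest 8-connected component, classified
   into the left or right chamber of the user-traced arena.

A pair with no detectable change — a freezing animal — yields a *missing*
point. Missing points are recorded, logged, and excluded from scoring; no
last-position carry-forward is applied, because imputing a position for an
undetected animal would invent data. The per-video log (schedule length,
threshold actually used, per-side and missing counts) exists precisely so
that the sensitivity of results to this choice can be audited.

Two geometric conventions worth stating: the divider drawn by the user is
extended to its infinite supporting line, so a hand-drawn segment need not
span the polygon; and with the divider oriented from its first to its second
endpoint, the half-plane on the negative-x side (image coordinates, y down)
is "left", with exact ties assigned to left. Both rules make classification
a deterministic total function.

## Why the difference image localizes the animal

The difference of two frames containing a congruent dark blob at positions
$A$ and $B$ is supported on the symmetric difference of the two blobs, which
is centrally symmetric about the midpoint $(A+B)/2$. When the animal moves
less than its body length between the paired frames the two "ghosts" overlap
and the largest connected piece is a crescent whose centroid sits near the
blob rim; when it moves farther, the ghosts separate and the largest
component is one full blob, localizing the animal to sub-pixel accuracy. The
centroid therefore always lies on or near the chord between the two true
positions — the property the test suite asserts — and side classification is
robust either way, since both positions share a chamber for all but the
transit pairs.

## The synthetic assay

The simulator generates ground-truthed sessions at three levels.

**Occupancy.** Chamber choice is a two-state continuous-time Markov chain
with stationary irritant-chamber probability $p$ (the preference parameter)
and mean dwell time $d$ (default 20 s, the scale of visits seen in freely
exploring mice): sojourn means are $2pd$ and $2(1-p)d$, so the stationary
fraction is exactly $p$. This is the minimal model producing the assay's
observable with one interpretable parameter; it makes no claim of behavioral
realism beyond that. The time-averaged occupancy of a $T$-second round has
variance $2p(1-p)/(\theta T)$ with $\theta = 1/(2pd) + 1/(2(1-p)d)$ — at
$p = 0.5$, $d = 20$ s, $T = 300$ s the per-round standard deviation is
$\approx 0.13$, which is why per-mouse baseline scores scatter visibly
around zero while cohort means concentrate.

**Path.** Within a chamber the animal follows a persistent (correlated)
random walk: speed 150 px/s with heading diffusion 2 rad/\(\sqrt{s}\),
reflecting off walls. Persistence matters: real locomotion is directional,
and a Brownian path at realistic speeds would keep the paired-frame ghosts
permanently overlapped, denying the tracker the separated-blob regime it was
designed around. On a chamber switch the path is routed deterministically
through the passage at ≥220 px/s, so the geometric side re-matches the
chain state within 2 s; these transit windows are flagged in the ground
truth and excluded from oracle comparisons.

**Render.** Frames are a light background (0.8) with a dark filled ellipse
(0.15, semi-axes 18 × 10 px) at the true position plus optional per-pixel
Gaussian noise (default σ = 0.02), over the default geometry of two
300 × 300-px chambers joined by a 60 × 60-px passage. Every frame is a pure
function of (positions, parameters, seed), so videos can be rendered lazily
frame-by-frame and are bit-reproducible. A single global seed fans out to
per-round sub-seeds through a fixed counter scheme, making an entire cohort
a pure function of its specification and seed.

What the simulator does *not* emulate — shadows, reflections, bedding
disturbance, partial occlusion at the passage, posture change, camera
jitter — bounds what passing tests prove: they validate the algorithmic
chain (segmentation arithmetic, geometry, scoring, statistics), not
robustness to real-world imaging artifacts.

## Sessions, aggregation and statistics

A session (one mouse, one time point) is three 5-min rounds: saline/saline
baseline, irritant presentation, and a side-swapped presentation with the
irritant moved to the opposite chamber to cancel chamber bias. The irritant
side also alternates across consecutive time points (0, 1, 6 h). The
per-mouse time-point score is the mean of the presentation and swap rounds,
each scored against its own irritant side — the swap design makes this mean
cancel chamber-specific bias by construction. Baseline rounds are scored
against the following round's side as a nominal label and reported
separately, never pooled with irritant scores.

Group comparisons use one-way ANOVA on `group`, or two-way ANOVA on
`group × time` with type-II sums of squares (the standard choice for
unbalanced factorial behavior data), each followed by Tukey's HSD with
α = 0.05. No repeated-measures correction is applied across time points;
this mirrors common practice for this assay and is a known limitation —
scores from the same animal at 0, 1 and 6 h are treated as independent.

Heat maps show the mice × rounds matrix of centered scores with a diverging
palette: gray at exactly 0, blue toward −0.5 (avoidance), red toward +0.5
(preference).

## Numerical choices

- **Otsu threshold**: 256-bin histogram on $[0,1]$; ties broken toward the
  lowest level; a flat difference image yields an empty mask rather than a
  spurious one. The implementation is checked against an exhaustive
  between-class-variance search in the tests.
- **Components**: 8-connectivity (a 4-connected labelling plus diagonal
  merge); area ties broken by the smallest top-left bounding-box corner.
  Exact area ties are not hypothetical: a noiseless ghost that splits into
  two crescents produces them systematically (central symmetry), which is
  why mirrored-video centroids coincide only for untied pairs, while side
  counts and scores still mirror exactly.
- **Score arithmetic**: the centered score is computed as
  $(2a - n)/(2n)$ with integer $a$, $n$, so relabelling the irritant side
  negates it bit-exactly.
- **Point-in-polygon**: even-odd crossing rule with half-open edges;
  boundary points count as inside, so classification is total.
- **Schedule boundary**: pairs whose comparison frame would fall past the
  end of the video are dropped; a partial pair has no difference image.
- **Indexing**: frames are 0-based; timestamps are `index / fps`; pixel
  coordinates are 0-based with origin at the top-left.

## Problem sizes used in validation

The test suite exercises scaled-down sessions (10–60 s at 10 fps,
ground-truth-only where rendering is not the point) for unit-level checks,
and reserves full-scale 300-s, 30-fps rendered sessions for the end-to-end
recovery check, which sweeps preference p over {0.2, 0.35, 0.5, 0.65, 0.8}
with ten seeded replicates each and requires the tracked centered score to
sit within 0.05 of the ground-truth pair-level fraction. Statistical
calibration uses 1000 null replicates (type-I error) and 500 shifted
replicates (power at a 0.2 shift, SD 0.1, n = 10 per group), sizes at which
the binomial error of the estimated rates is well inside the asserted
bands.
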