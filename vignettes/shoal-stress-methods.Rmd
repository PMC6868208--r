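---
title: "Group-level stress metrics: models, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-level stress metrics: models, design decisions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shoalmetrics)
```

This vignette is the package's own account of its science: the measurement
model, the statistical model, the synthetic-data generator, and the choices
made where the design was genuinely open.

## The measurement model

The observational unit is a *frame*: a time-stamped snapshot of the 2D
positions of all fish in one shoal, taken from an overhead camera at a fixed
interval (default one frame per 10 s over a 30 min session, 180 frames).
Coordinates are centimetres with the origin at a tank corner and axes along
the walls; the default arena is a 45 x 25 cm footprint filled to 20 cm.
Lens-distortion correction is assumed to have been applied upstream.

Per frame the package computes three families of metrics.

*Proximity* metrics summarise cohesion: the nearest-neighbour distance
vector and its mean; its coefficient of variation (CV), a scale-free measure
of spacing irregularity; mean inter-individual distance; expanse (mean
distance to the centre of mass); and convex hull area. The CV uses the
sample standard deviation (divisor $n-1$): conventional for small
behavioural samples ($n = 7$ fish), and configurable in the sense that the
raw NND vector is exported for any other summary. A frame in which all fish
occupy an identical point has no defined CV; such frames raise an error
rather than propagating NaN into the mixed models.

*Spatial* position is summarised by thigmotaxis: the distance of the shoal
centroid to the nearest wall, $\min(c_x, L - c_x, c_y, W - c_y)$, bounded by
half the tank width. Wall proximity is a standard anxiety indicator in open
arenas.

*Social* metrics come from a per-frame binary association network: two fish
associate when their distance is within two mean body lengths of the fish in
their group (body lengths are measured in mm and the threshold converted to
cm). Network density is the number of associating pairs over the number of
possible pairs $\binom{n}{2}$; subgroups are the connected components.
Two readings of "number of individuals associating ... divided by the total
number of possible associations" are possible; the pairs/pairs reading is
the default because it is the standard graph density and is the only reading
bounded in $[0, 1]$, but an individuals/pairs mode is retained
(`network_density(mode = "individuals")`). The boundary is inclusive: a
pair exactly at the threshold associates. This is a coin-flip decision made
once and exposed as `include_boundary`.

*Behaviour* is coded on 10 s clips as presence/absence, present when at
least one fish shows the behaviour at any point in the clip. The canonical
pair is erratic movement (sharp darting/dashing) and swimming height
(any fish in the top half of the water column). Behaviours present in fewer
than 10% of all clips (both conditions pooled) are removed; a behaviour at
exactly 10% is retained, reading "less than 10% ... removed" literally.
Intra-observer reliability uses percent agreement and Cohen's kappa on a
seeded random 10% rescoring subsample. Two kappa degeneracies arise with
constant coders: identical constant coders agree perfectly (kappa defined as
1); different constant coders have no chance-corrected agreement (kappa
defined as 0, with a warning).

## Metric selection

All candidate metrics — per-frame continuous metrics and per-clip binary
behaviours, aligned by their shared 10 s interval — enter a mixed-method
correlation matrix: Spearman for continuous pairs where either member fails
a Shapiro–Wilk normality check (alpha = 0.05, subsampled to at most 5000
values — the test is undefined above that and pointlessly powerful long
before it), Pearson otherwise; binary metrics always use Pearson, which for
0/1 data is the point-biserial / phi coefficient. Zero-variance metrics get
correlation 0 with a warning rather than NA.

Selection is a greedy pass in an explicit priority order: a metric is kept
only if $|r| < 0.2$ against everything already kept ($|r|$ exactly 0.2
counts as correlated). Afterwards any empty category (behavioural, social,
proximity, spatial) is backfilled with its least-correlated member, logged
as constraint-forced. The default priority puts the five canonical stress
metrics first (density, CV of NND, wall distance, erratic movement,
swimming height), then the rest alphabetically; the criterion for choosing
among correlated metrics is genuinely open, so it is configuration, not
inference. An exhaustive-search mode (feasible to 15 metrics) exists as a
testing oracle: the greedy result provably equals the
priority-lexicographic-first maximal valid subset, and the test suite
verifies that equality on randomly constructed matrices.

## Inference

Each selected response is tested with a likelihood-ratio test between
nested mixed models fitted by maximum likelihood (not REML, so the
likelihoods are comparable):

$$y \sim \text{condition} + (1 \mid \text{group})$$

against the null without the condition term. Continuous per-frame metrics
use a Gaussian LMM; clip-level behaviours use a binomial GLMM with the
Laplace approximation. The group random intercept absorbs the repeated
observation of each group in both conditions. The statistic is
$\chi^2 = 2(\ell_{\text{full}} - \ell_{\text{null}})$ on 1 df, clipped at 0
if numerically negative. Bonferroni correction multiplies p-values by the
family size, by default the number of responses tested in the run; the
cortisol model is its own a-priori test (family of 1) unless
`cortisol_in_family = TRUE`. Singular random-effect fits are returned with a
warning and flag; degenerate binary responses (all 0 or all 1) are flagged
without crashing.

Whole-body cortisol (ng per g body weight, one sampled fish per group per
condition) is log-transformed before modelling. A measured value at or
below zero — possible when a sample falls under the assay detection limit —
would break the log; such values are floored at half the detection limit
(default limit 0.0567 ng/ml) with a warning. Half the detection limit is
the standard imputation for non-detects; the offset is configurable.

The design's sample size is recoverable from `paired_t_sample_size()`: the
smallest $n$ whose two-sided paired t-test power reaches the target, found
by inverting `stats::power.t.test`. A minimum effect of 4 ng/g against an
upper-range SD of 5.6 ng/g at 90% power gives 23 groups.

## The synthetic-data generator

No public accession exists for the original observations, so the package
ships a generator whose output has the statistical structure the analysis
assumes, making every pipeline stage testable end to end. It is a
discrete-time (default dt = 0.1 s) agent-based model; its parameters are
configuration describing a plausible shoal, not claims about zebrafish
kinematics.

Each fish's velocity sums:

* attraction toward the shoal centroid at rate
  $w_{\text{att}}(1 + \kappa\theta)$, where $\theta \in [0, 1]$ is the
  stress level of the condition (defaults: 1 immediately after transfer,
  0.2 at 24 h) — stressed shoals cohere more tightly;
* short-range pairwise repulsion inside a collision radius;
* a pull toward the nearest wall, $w_{\text{wall,base}} + w_{\text{wall}}\theta$ —
  thigmotaxis with a stress-dependent component on top of a baseline;
* Gaussian velocity noise;
* rare erratic bursts: large impulses in a random direction with
  per-subframe probability $p_0(1 + \beta\theta)$.

Depth follows a downward drift $d_0 + d_1\theta$ with reflection at bottom
and surface, so stressed fish sit low and relaxed fish range higher.
Each fish also switches between a *cohesive* and an *independent*
behavioural state: cohesive fish detach at rate
$\lambda_{\text{out}}(1 - \theta)$ and return at $\lambda_{\text{in}}$
(mean excursion ~5 s), feeling only a small fraction of the attraction
while independent. Relaxed shoals therefore contain transient stragglers —
raising their spread and the variability of nearest-neighbour spacing —
while acutely stressed shoals cohere homogeneously. This state-switching
term earned its place empirically: with attraction scaling alone the NND CV
is scale-invariant (shrinking the cloud does not change a ratio), and a
repulsion shell strong enough to regularise spacing is numerically unstable
at the default time step, so no parameterisation of the plain
attraction/repulsion scheme can express the lower-CV-under-stress effect.

Two further choices are driven by the statistics rather than the biology.
First, every metric's correlation time must stay below the 10 s frame
interval, because the mixed models treat frames as independent within
group-condition: the state-switching rates, the attraction rates and the
baseline wall pull are set so that configurations decorrelate within a few
seconds. Without the baseline wall pull the shoal centroid is an
unrestored random walk whose wall distance mixes over hundreds of seconds,
and an equal-stress null study then produces spurious LRT significance in
most replicates — a property of the per-frame observational unit, not of
the test. Second, group-level heterogeneity (lognormal multipliers on
attraction, burst rate and wall pull, an additive depth-drift trait, and a
shared cortisol effect) is drawn once per group and shared by both of a
group's sessions, which is exactly the structure the group random intercept
absorbs.

Behaviours are derived from the subframe-resolution trajectory: a clip is
erratic when any fish exceeds a speed threshold (default 50 cm/s, between
the noise-driven speed distribution and the burst impulses) in any
subframe; a turning-angle threshold is also available but disabled by
default, because without velocity persistence the instantaneous heading is
noise-dominated and the turning angle carries no signal at the default
parameters. Top-half presence is any fish above half the water depth at any
subframe.

Cortisol is lognormal per condition, calibrated so the sample mean and
standard error at 23 fish per condition approximate 40.2 ± 6.0 (immediate)
and 19.9 ± 4.3 ng/g (24 h); a shared group effect (log-scale SD 0.3) makes
the repeated-measures structure real. Setting the target SE to zero
collapses the draws onto the exact condition means.

Seeding: one master seed drawn once per study spawns per-session child
seeds, so any single session can be regenerated in isolation and the same
seed reproduces a study bit for bit.

What the generator does *not* emulate: visual-field interactions, velocity
persistence and polarised schooling, hydrodynamics, individual identities
across frames, or any species-specific kinematics. Passing tests on
synthetic data therefore demonstrate that the pipeline recovers the effects
its models are built for under the assumed structure — not that real shoal
data satisfy that structure (see Limitations).

## Numerical choices

* Convex hull area: `grDevices::chull` plus the shoelace formula; fewer
  than three distinct points, or collinear points, give area 0.
* Degenerate frames (all fish coincident) raise errors; silent NaN would
  corrupt the model fits downstream.
* $\chi^2$ numerically negative within optimiser tolerance is clipped to 0.
* Connected components: `igraph` behind the exported `subgroups()`; the
  per-frame hot path uses an equivalent breadth-first search (verified
  against igraph and a union-find oracle in the tests) to avoid building
  thousands of graph objects.
* Intervals are closed: positions may lie exactly on a wall; a distance
  exactly at the association threshold associates; presence exactly at the
  10% cutoff is retained; $|r|$ exactly at the selection threshold is
  excluded.

## Problem sizes in the test suite

The suite exercises the full study geometry (23 groups x 7 fish x 180
frames x 2 conditions) where the property under test concerns study-scale
behaviour: parameter recovery uses 50 replicate studies and the equal-stress
null 20; type-I calibration of each LRT family uses 1000 null simulations
with 23 groups and small per-cell counts (2 continuous observations, 6
binary clips per group-condition), sizes at which the refitting cost stays
proportionate while the group-level asymptotics match the design. Oracle
equivalence for the frame metrics uses 1000 random frames at relative
tolerance 1e-9.

## Known limitations

* Per-frame (and per-clip) observational units inherit the original
  design's assumption that frames are exchangeable within a session given
  the group effect. Real trajectories are autocorrelated on scales that
  camera intervals may not erase, which makes the LRTs anti-conservative on
  real data; the very large $\chi^2$ values this produces should be read as
  strength of evidence under that assumption, not as calibrated statistics.
  A conservative alternative is to aggregate to session means before
  testing.
* Metrics are 2D; the depth coordinate exists only in the simulator and the
  behaviour derivation.
* The selection step's choice among correlated metrics is a stated priority
  order, not an optimality claim.
* Kappa for more than two coders, weighted association networks, and
  temporal network statistics are out of scope.
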