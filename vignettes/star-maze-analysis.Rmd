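---
title: "Analysing star-maze navigation: metrics, strategies and learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing star-maze navigation: metrics, strategies and learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starmaze)
```

## The task and the model of it

A star maze is a regular pentagon with five alleys radiating outward from its
vertices. A participant starts at the end of one alley and must find a reward
hidden at the end of another; the reward is invisible until reached. Because
the same route can be solved either by replaying a learned sequence of body
turns (an egocentric strategy, ES) or by steering toward landmarks placed
around the maze (an allocentric strategy, AS), the maze dissociates the two
navigation systems: moving the start alley breaks the motor sequence but not
the landmarks (compelling AS), while stripping the landmarks breaks allocentric
guidance but not the motor sequence (compelling ES).

`starmaze` models the whole analysis chain for such experiments: maze
geometry, the canonical two-task trial schedule, per-trial trajectory metrics,
strategy classification, learning-curve stabilization detection, the group
statistics that accompany such studies, and an agent-based simulator that
generates complete synthetic cohorts for testing every stage.

### Geometry and conventions

Coordinates are planar metres, origin at the pentagon centroid, alley 1
pointing along +y, and alley *i* centred at heading $(i-1)\cdot 72^\circ$
counter-clockwise. All dimensions are configurable through `maze_config()`.
The defaults — circumradius $R = 8$ m, alley length $L = 115$ m, alley width
4 m, capture radius 2 m — are a *calibration*, not a reconstruction: published
star-maze work rarely prints physical dimensions, but the canonical
alley-1-to-alley-3 route is known to measure 246 m. We therefore define the
ideal path as alley end → own vertex → centroid → goal vertex → goal alley
end, whose length $2(L + R) = 246$ m meets that constraint exactly. A
turn-around path (start alley = goal alley, which a test trial can require)
is out-and-back to the vertex with a 180° rotation. Because the alley axes
pass through the centroid, the ideal path has a single turn there; for the
1 → 3 route the minimum rotation is 36°.

`locate_points()` labels any point as `center`, `alley_i`, `alley_end_i`
(the distal stretch of a corridor within twice the capture radius of its
end) or `outside`; the most specific label wins where regions touch.

### Trial protocol

`default_protocol()` returns the 28-trial schedule: Task 1 holds 16 training
trials (start alley 1, reward alley 3) interleaved with 5 test trials (start
alley 4, rewards in *both* alleys 1 and 3) at positions 6, 10, 14, 17 and 21;
Task 2 holds four compelled-AS trials (cued maze, starts 2, 5, 2, 5) and
three compelled-ES trials (bare maze, start 1) in an order counterbalanced by
a seed. Trial indices are 1-based. The preliminary "walk along the pathway"
familiarisation is outside the protocol: it is a pass/fail inclusion gate,
not a navigation trial.

## Per-trial metrics

For one trajectory (a strictly increasing time series of planar positions,
nominally 120 Hz) `compute_trial_metrics()` reports:

* **success** and **time to reward** — the first sample within the capture
  radius of a reward point, within the 120 s limit;
* **visited alleys** — an alley counts once a sample lies deeper than
  `depth_fraction` (default 0.10) of the alley length past the vertex; the
  start alley always counts; order of first entry is kept;
* **TPL**, total path length — summed Euclidean distances between samples;
* **duration** and **mean speed** (TPL/duration; an instantaneous-mean
  variant is available via `metric_options(speed_method =
  "instantaneous")` because a median of per-trial TPL/duration ratios is not
  the ratio of medians);
* **distance error**,
  $\mathrm{DE}\% = 100\,(d_{\text{traveled}} - d_{\text{ideal}})/d_{\text{ideal}}$;
* **rotation angle**,
  $\mathrm{RA} = \text{participant's rotations} - \text{minimum rotations}$
  (degrees), where the participant's rotations are the summed absolute
  heading changes over successive displacements of at least `min_step`
  (default 0.05 m, suppressing jitter-induced heading noise), and the
  minimum is the ideal path's total heading change.

Three numerical choices deserve note. First, on successful trials all
path-dependent quantities are truncated at reward capture, and the traveled
distance *closes the residual gap* from the capture sample to the reward
point: capture fires up to one capture radius early, and closing the gap
keeps the comparison with the ideal path (which ends at the reward) like for
like — it also guarantees $\mathrm{DE} \ge 0$ exactly, by minimality. Second,
heading is estimated from successive positions, not from body orientation:
pelvis markers drive such recordings, but orientation traces are not part of
the analysed data model. Third, on failed trials DE and RA are computed
against the nearer reward's ideal path over the full recorded trajectory — a
conservative, deterministic choice.

`ideal_trajectory()` samples the ideal polyline at the nominal rate *and*
inserts the polyline breakpoints as extra samples, so the sampled ideal
trajectory preserves the exact ideal length and rotation; a pure time grid
would cut the centroid corner by a few millimetres.

## Strategy classification

On a test trial the reached alley reveals the strategy: alley 3 entered via
only two alleys is AS, alley 1 via only two alleys is ES, anything else
(failure or more than two alleys) is inefficient. Over the five test trials a
participant is **Allocentric** (or **Egocentric**) when at least four
consecutive trials carry the same efficient label and the other trial is
inefficient; **Shifter** when both AS and ES appear; **Lacking** when at
least four trials are inefficient. We read the protocol's "more than three"
as $\ge 4$ of 5; `run_threshold = 3` restores the laxer reading. Residual
patterns that match no rule (e.g. a run of three AS plus two inefficient
trials) fall back to Lacking — they show no stable efficient strategy — and
the precedence is documented: Allocentric/Egocentric, then Shifter, then
Lacking.

A compelled trial succeeds only by a direct route: success with exactly two
visited alleys. Success percentages are computed per participant separately
for compelled AS and compelled ES, over recorded trials.

**Learning onset** is the first training trial from which the participant
succeeded at every remaining training trial. A lone success on the final
trial is not stability — the terminal run must span at least two trials — so
strictly alternating success yields "never stable". The onset bins default to
first trial / trials 2–3 / trials 4–7 / later / never; descriptions of such
binnings are often internally inconsistent, so the edges are an argument.

## Stabilization ("knee") detection

Group learning curves (median and IQR per training trial) of visited alleys,
TPL, DE and RA all flatten once a group has learned the route. Where the
original procedure finds the bend visually and then verifies it, the package
makes the search explicit and reproducible: `detect_knee()` returns the
smallest candidate trial $k \in 2..15$ such that, for **all four** metrics,

* a Friedman test over trials $k..16$ is non-significant
  ($p > \alpha_{\text{stable}}$, default 0.05) — performance after the knee
  is stable; and
* a paired Wilcoxon signed-rank test between trials $k-1$ and $k$ is
  significant ($p < \alpha_{\text{change}}$, default 0.05) — performance is
  still changing into the knee.

Full diagnostics for every candidate are returned. Conventions are pinned by
tests: participants with any missing involved trial are dropped per test
(complete cases); a Wilcoxon with all-zero differences, or a Friedman on
constant data, reads as "no detectable change" ($p = 1$); `wilcox.test()`
supplies the zero-drop, exact-versus-approximate behaviour. Because both
tests are rank-based in the relevant sense, the detected knee is invariant to
participant order and to monotone rescalings of a metric.

The knee search needs paired replicates, hence at least 5 participants. Note
that a knee is a *group-level* construct: cohorts whose members learn at very
different trials may genuinely have none, and the function then says so
rather than guessing.

## Group statistics

All comparisons follow standard nonparametric practice for small cohorts,
with conventions pinned explicitly because tie and continuity handling
differs across software:

* 2 × 2 counts (e.g. gender by group): Pearson chi-square **without**
  continuity correction (`chisq_uniformity()`);
* continuous demographics and z-scores: unpaired t-test when both groups
  pass a Lilliefors normality test at 0.05, Mann-Whitney U otherwise;
* Mann-Whitney U (`mann_whitney()`): exact null distribution when there are
  no ties and $\min(n_1, n_2) \le 8$, otherwise the tie-corrected normal
  approximation with continuity correction; fully tied samples give $p = 1$;
* learning-phase correlations: per-participant medians of each metric over
  the pre-knee training trials of that participant's group, pooled across
  groups, Spearman-correlated with the Corsi, Labyrinth and Raven z-scores
  (12 pairs), pairwise deletion, $\ge 3$ complete pairs required;
* post-hoc power (`posthoc_power()`): closed-form noncentral-*t* power of the
  two-sample t-test, $\text{ncp} = d\sqrt{n_1 n_2/(n_1+n_2)}$ on
  $n_1+n_2-2$ df. The default is one-tailed; that tail convention is what
  reproduces the conventional reference value for $n = 13$ vs $15$ at
  $d = 1$ (0.82), and `tails = 2` is available.

No multiple-testing correction is applied anywhere; p-values are reported
raw, as is usual for pilot-scale cohorts of this kind.

## The simulator

`simulate_cohort()` makes every stage testable without any recorded data. An
agent walks waypoint paths (alley end → vertex → centroid → vertex → target
depth) at a per-trial lognormal speed (default mean 8 m/s, SD 1.5 — a round
246 m in roughly 30 s), with smooth cross-track jitter: a sum of three
random-phase sinusoids in arc length with RMS amplitude `path_jitter_sd`
(default 0.5 m). Smoothness matters — adding white noise per sample at 120 Hz
would inflate path length by hundreds of metres, whereas a lateral wobble of
bounded amplitude adds little length and a realistic amount of heading
variability.

Strategies follow the behavioural contracts the task implies. The egocentric
agent replays the trained start-relative sequence (alley offset +2 mod 5), so
from the test start in alley 4 it lands in alley 1, and from compelled-AS
starts it walks to an unrewarded alley and then searches in vain. The
allocentric agent steers to the landmark-defined goal from any cued start and
degrades to searching (partial "peeks" into alleys, never committing to an
end) in the bare maze, where its guidance is gone. The shifter alternates
sides across test trials (`switch_prob = 1` by default: deterministic
alternation from a random starting side, the simplest behaviour that always
uses both strategies; lower values make switching stochastic). The lost agent
wanders: at least two partial peeks before it ever commits to walking an
unexplored alley to its end — so its trials always show inefficient
multi-alley exploration, which is what "lacking an efficient strategy" means
operationally.

Learning is an error process: on training trial $t$ the agent errs with
probability $p_0 (1 - \lambda)^{t-1}$ (`initial_error_prob`,
`learning_rate`); an error either derails the trial into wandering until the
time limit (`error_fail_prob`, default 0.5) or inserts one or two wrong-alley
excursions before the reward. Group defaults (TD $p_0 = 0.3, \lambda = 0.6$;
CP $p_0 = 0.6, \lambda = 0.35$) encode the qualitative finding that one group
learns faster; per-agent heterogeneity comes from a truncated normal on
$p_0$ (`error_sd = 0.15`). Strategy mixtures default to the shares observed
in the motivating cohort (TD 54/31/15/0 and CP 27/53/7/13 percent
allocentric/egocentric/shifter/lost). Test z-scores are planted with a stated
monotone link, $z = a + b\,p_0 + \varepsilon$ with $b < 0$, so
visuospatial scores correlate negatively with learning-phase path metrics by
construction — giving the correlation analysis a testable synthetic analogue.

What the simulator does *not* emulate: biomechanical gait, body-orientation
traces (heading is positional here too), visual rendering, momentary pauses,
and the possibility that a real child's errors are systematic rather than
exchangeable across trials. Tests passing on simulated cohorts therefore
validate the *pipeline* — geometry, metrics, classification rules, test
conventions — not claims about real populations.

## Problem sizes and determinism

Everything is seeded: cohorts are pure functions of `cohort_config(seed=)`,
the protocol of its counterbalance seed, and written cohorts round-trip
byte-identically. The test suite exercises parameter recovery on 200
default-noise agents (the classifier must recover at least 95 % of true
strategy labels and the learning onset within one trial for at least 90 %),
knee recovery on constructed 10-participant step curves, Mann-Whitney
equivalence against exhaustive enumeration up to $n_1 + n_2 = 10$, and a
1000-replicate metric-level null calibration of the between-group comparison
at $n = 13$ vs $15$. These sizes were chosen as the smallest that make the
stochastic checks stable.

One caveat surfaced by simulation is worth knowing: with a *gradual*
per-trial error decay, the strict all-four-metrics Friedman/Wilcoxon
conjunction often finds no knee, because no single trial pair carries a
synchronized jump. Sharp group-level knees require learning that is fast
relative to its between-participant spread — which is exactly what the knee
construct presumes. `detect_knee()` reports `NA` with diagnostics in the
gradual case rather than forcing a bend.

## Limitations

* The geometry is calibrated to one published path length; absolute
  coordinates of landmarks and walls are conventions, so region labels near
  boundaries depend on the configured widths.
* The knee is defined per group; it is not an individual change-point
  estimator, and curvature-based estimators are deliberately out of scope.
* Tie-handling matches the pinned conventions above; other statistical
  software may print slightly different p-values on tied data.
* The pipeline consumes positions only; analyses of body orientation,
  platform sway or gait quality need different inputs.

## Interfaces

The package is function-first: `read_cohort()` / `simulate_cohort()` →
`cohort_metrics()` → `classify_cohort()` / `detect_knee_by_group()` →
`compare_navigation()` / `learning_phase_correlations()` →
`run_pipeline()` / `make_report()`. A thin command-line wrapper over
`run_pipeline()` ships in `inst/scripts/run_pipeline.R` for users who prefer
a shell entry point; it adds no behaviour of its own.
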