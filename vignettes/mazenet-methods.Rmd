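---
title: "Scoring Barnes-maze trajectories: conventional features, strategy calls and exploration networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring Barnes-maze trajectories: conventional features, strategy calls and exploration networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mazenet)
```

## The problem

The Barnes maze is a brightly lit circular arena with holes along its
perimeter, one of which leads to an escape box. A mouse released at the
center learns, over days of training, to navigate to the goal hole
using distal visual cues. `mazenet` scores this task from 2-D tracking
trajectories (20 Hz position samples in arena coordinates), for arenas
of different scales — the built-in geometries are a 1-m maze (`BM1`:
49-cm arena radius, 12 holes 40 cm from the center, 80-mm scoring
circles, 8-cm start area) and a 3-m maze (`BM3`: 150-cm radius, 270-mm
scoring circles, 27-cm start area). Three families of features are
computed per trial, then aggregated per day and per animal.

All lengths are millimeters internally; configs may specify `unit: cm`.
Trajectories are first rotated about the arena center so every animal's
goal lies at the same canonical angle (90°, "north"); rotation is an
isometry, so distances and region dwell are unaffected.

## Conventional features

For each training trial:

* **Errors** — the number of visit events to nontarget hole scoring
  circles, a visit being a maximal run of consecutive in-area samples.
  Re-entries recount; counting stops at the first entry into the target
  circle. No minimum visit duration is imposed by default
  (`min_visit_duration = 1` sample), configurable for noisy tracking.
* **Latency** — time from trial start to the first sample inside the
  target circle, capped at 600 s (the 10-min trial limit) when the goal
  is not reached. The clock starts at the first trajectory sample; if a
  rig logs lift motion separately, trim the file accordingly.
* **Travel distance** — summed sample-to-sample Euclidean steps up to
  the goal entry.

Per-day values average the (up to) three trials of a day. Series can be
normalized to unit sum within an animal (`normalize_series()`) so
curves are comparable across maze scales in unitless form.

**Learning-curve fit.** A per-animal feature series over the trials of
days 1–6 is fitted to

$$y_t = \alpha e^{-\beta t},$$

with $t$ the global trial number (1–18; the base is configurable since
a within-day index convention is equally defensible). Smaller $\beta$
means slower convergence of performance. The fit is nonlinear least
squares via Levenberg–Marquardt (`minpack.lm::nlsLM`) with a
deterministic initialization: $\alpha_0$ is the first observed value
and $\beta_0$ is multistarted over $\{0.01, 0.05, 0.1, 0.3, 1\}$, the
lowest residual sum of squares winning. Flat or degenerate series fall
back to $\beta = 0$, $\alpha = \bar y$, flagged via `converged = FALSE`.
Noiseless model data are recovered to $10^{-6}$; under additive
Gaussian noise the estimator is unbiased (median bias below 10% of
$\beta$ across $\alpha \in \{2,5,10\} \times \beta \in
\{0.05,0.2,0.5\}$). Its absolute error is information-limited: at
$\beta = 0.5$, 18 trials and noise sd $= 0.1\alpha$, the Cramér–Rao
bound already puts the median absolute error near $0.09$, so we state
and test the bias guarantee rather than an absolute-error one.

**Probe test.** The probe (escape removed, 300 s) is scored over its
first 150 s — long enough to be informative, short enough that
extinction-driven exploration of other holes does not dominate; the
window is a parameter, so adjusted-duration comparisons (e.g. 90 s vs
150 s across scales) need no separate code path. The dwell profile
keys each hole's in-area time by its angular offset from the target
(−150° … +180° in 30° steps). Because dwell is counted per sample over
disjoint regions, the summed dwell can never exceed the window. Probe
latency is the start of the first continuous stay in the target circle
exceeding 10 s; probe errors count nontarget visits over the window.

## Strategy classification

Each training trial is labeled **spatial**, **serial** or **random**.
The initial stay in the start area (8/27 cm radius) is discarded first,
so lift-related wobble cannot influence the call; later passages
through the center are retained. The rules, tested in this order:

1. *spatial* — fewer than 3 nontarget-hole visits **and** path
   efficiency ≥ `theta_direct` (default 0.75). Path efficiency is the
   straight-line distance from the first post-strip point to the target
   center divided by the traveled path length to the first target entry
   (plus the residual straight distance from the entry point to the
   center, so a perfectly straight approach scores exactly 1; a
   semicircular ring-following approach scores $2/\pi \approx 0.64$).
2. *serial* — target reached, fewer than 3 quadrant crossings, and
   serial consistency ≥ `theta_serial` (default 0.8). Serial
   consistency is the fraction of consecutive visit pairs stepping to
   the circularly adjacent hole in one dominant rotational direction;
   adjacent steps in both directions contradict a single scan and score
   0. Quadrants are the four 90° sectors with the target ray bisecting
   sector 0 — anchoring them to the target (rather than the camera
   frame) makes the count rotation-invariant across animals.
3. *random* — everything else, including trials that never leave the
   start area (flagged).

The two thresholds are operationalizations of "moved directly toward
the target" and "sequentially approached neighboring holes"; they are
exposed in `run_config()` and echoed into every output, and every call
reports its full evidence vector. Spatial is tested before serial
because a direct run trivially satisfies the crossing bound.

## Exploration networks

Stopping behavior is turned into an undirected graph in three stages:

1. **Stop detection** (`detect_stops()`): whenever the traveling
   distance over ≥ 20 successive frames (1 s at 20 Hz) stays below
   40 mm — about half a mouse body length — one stopping coordinate is
   generated at the centroid of the frames involved. Overlapping
   qualifying windows merge into one maximal run (sliding semantics); a
   net-displacement mode is available as an alternative criterion.
2. **City Clustering Algorithm** (`cca_cluster()`): stops are taken in
   temporal order (a deterministic, data-natural order) and each is
   integrated into the nearest node closer than 40 mm, else it spawns a
   new node; node centroids are then recomputed as member-stop
   centroids, and the passes repeat until the stop-to-node assignment
   is unchanged (cap 100 iterations, warning on non-convergence). At a
   fixed point no spawns occur, every stop lies within the merge radius
   of its node, and centroids are exact member means.
3. **Links** (`build_network()`): consecutive stops mapped to distinct
   nodes add an undirected link; self-links are excluded and repeats
   collapse (the measures below are defined on unweighted graphs).

Seven measures summarize each network, per-node quantities averaged
over nodes: order (node count), mean degree, density
$2L/(n(n-1))$, mean local clustering (fraction of a node's neighbor
pairs that are themselves linked; 0 for degree < 2), mean shortest
path, mean betweenness (for node $i$, the fraction of shortest $s$–$t$
paths through $i$, averaged over the $\binom{n-1}{2}$ pairs excluding
$i$, hence in $[0,1]$), and mean closeness (inverse summed distance to
other nodes). Empty-link trials can produce disconnected graphs, which
the original formulation leaves unaddressed; we average shortest-path
and closeness over reachable pairs only, count only reachable pairs in
betweenness, and report `n_isolated`. All five per-node measures are
verified against an exhaustive path-enumeration oracle on random
graphs, and cross-checked against igraph.

## The synthetic generator

No public trajectory data accompany this task, so `generate_trial()` /
`generate_cohort()` emulate the study conditions: 20-Hz sampling,
center release, 600-s cap, three trials per day, randomized goal hole
per animal, and day-over-day learning. Strategy-dependent paths:

* *spatial* — noisy straight pursuit of the target (heading sd
  0.15 rad);
* *serial* — run to a start hole several positions away, then
  hole-to-hole steps in one direction until the goal; the start offset
  shrinks with training so serial errors follow the same learning
  schedule as random-strategy visits;
* *random* — meandering pursuit through random interior waypoints and
  $K \sim \mathrm{Poisson}(\alpha e^{-\beta t})$ nontarget holes before
  the goal, so the expected error count follows the programmed
  exponential decay.

Locomotion speed is 150 ± 40 mm/s (typical open-field mouse travel);
pauses arrive at 4/min with log-normal durations (median 2 s, above the
1-s stop window so stop detection is exercised); a home-base mode
generates roundtrips anchored at one site, reproducing the
maximal-betweenness signature of home-base behavior. Probe-mode trials
concentrate dwell at the former goal with brief excursions. The
BM1-like and BM3-like cohort templates program fast
($\alpha = 10, \beta = 0.30$, quickly fading random mix) versus slow
($\alpha = 12, \beta = 0.08$, heavier random mix) learning.

What the generator does *not* emulate: thigmotaxis and wall-following,
body-scale kinematics (acceleration limits, grooming bouts), tracking
noise and dropouts, visual-cue use, or any pharmacological effect.
Passing tests therefore certify the *analysis* pipeline — detection,
clustering, classification, fitting, statistics — under controlled
conditions, not behavioral realism of the simulated paths.

## Statistics harness

Group contrasts follow a nonparametric per-day schedule: two groups per
day by Wilcoxon rank-sum, three or more by Kruskal–Wallis with pairwise
rank-sum post hocs gated on significance. p values are
Bonferroni-corrected with the family taken as the days within one
measure, matching per-day reporting (the family definition is a
choice; it is recorded in the output's `m` column). Rank effect size is
$r = |z|/\sqrt{N}$ with $z$ from the normal approximation with tie and
continuity corrections (exact p values are used when both groups have
≤ 10 observations without ties). Mixed-design two-way ANOVA (between:
group; within: day or hole) delegates to `stats::aov` with the
classical error strata and reports
$\eta_p^2 = SS_\mathrm{effect}/(SS_\mathrm{effect} + SS_\mathrm{error})$
per effect, with Tukey's HSD over subject means when a group effect is
significant. Under a simulated global null the per-day schedule's
familywise error stays at or below the nominal 5%.

## Numerical choices and degenerate inputs

* Gaps ≤ 0.5 s in tracking are linearly interpolated; longer gaps or
  more than 5% missing samples fail validation loudly (the original
  acquisition format is rig-internal, so the CSV dialect and gap policy
  here are this package's own).
* Points at the exact arena center have no defined quadrant; crossing
  counts carry the previous quadrant forward.
* Ties in nearest-hole assignment break to the lowest index; the start
  area takes precedence over hole circles (they cannot overlap under
  the spec invariants, but precedence is enforced for malformed
  configs).
* The BM3 hole-ring radius is not a published quantity (its holes are
  slots along the rim segments); the default 1350 mm triples the BM1
  layout approximately and is configurable, as is the exact BM1
  scoring radius (published as approximately 80 mm).
* Empty networks yield `NA` measures; order-1 networks have `NA`
  density and 0 betweenness.
* Problem sizes used by the test-suite and the acceptance script —
  100 random graphs for the measure oracle, 50 stop sets for the CCA
  fixed point, 200 trials per strategy class, 20 simulated mice per
  arm, 1000 null replicates for the error-rate check — were chosen as
  the smallest sizes at which the Monte-Carlo margins are comfortable.

## Known limitations

* The strategy thresholds (0.75, 0.8) are defensible but not uniquely
  determined by the verbal rules they operationalize; sensitivity to
  them should be reported alongside any substantive claim.
* Serial consistency treats any bidirectional adjacent stepping as
  non-serial; a scan with a single backtrack is deliberately penalized
  hard.
* The CCA result depends on processing order; temporal order is fixed
  here, so identical stop sets in different temporal order can cluster
  differently (as in any order-dependent greedy scheme).
* Learning-curve $\beta$ from 18 noisy trials is information-limited;
  compare groups with rank statistics on per-animal $\hat\beta$, not on
  individual fits.
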