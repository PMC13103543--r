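---
title: "Dynamic connectivity states of a brain network: models, choices and limits"
author: "dfcstates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic connectivity states of a brain network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Static functional connectivity summarizes the coupling between brain regions
as one scan-average correlation per edge. That average hides temporally
structured variability: a network can alternate between weakly and strongly
coupled configurations whose balance — not whose mean — differs between
clinical groups. `dfcstates` implements the standard sliding-window pipeline
for quantifying that balance in a single network (here, a 21-node
frontoparietal set): windowed correlation features, multisite harmonization,
k-means state identification, per-subject temporal metrics, and a
case-control statistical battery, together with a generative simulator so
that every stage is testable without access to consortium imaging data.

## Windowed connectivity features

Each subject's $T \times N$ ROI time-series matrix (defaults $T = 230$
retained volumes at TR = 2 s, $N = 21$ nodes) is segmented into windows of
22 TR (44 s) advanced 1 TR at a time, giving
$\lfloor (T - 22)/1 \rfloor + 1 = 209$ windows. Within each window we compute
all pairwise Pearson correlations, clamp them to $[-1+\epsilon, 1-\epsilon]$
($\epsilon = 10^{-7}$) so the boundary maps to a large finite value, apply
the Fisher transform $z = \operatorname{artanh}(r)$, and vectorize the
upper triangle row-major over $i<j$ into $E = N(N-1)/2 = 210$ edges. Windows
containing an undefined correlation (a node with zero variance in the
window) are flagged invalid and excluded from clustering and metrics rather
than imputed; the window slot itself is retained so window indices stay
interpretable.

Numerical choices: the window is rectangular (no taper) — the minimal,
assumption-free reading of a "22 TR / step 1" design; $\epsilon$ is
config-exposed because only symmetric clamping at some small value is
needed, and any $\epsilon \le 10^{-3}$ changes nothing downstream except the
magnitude assigned to numerically perfect correlations.

## Multisite harmonization

Multisite features carry additive and multiplicative site effects.
`combat_adjust()` removes them with the parametric empirical-Bayes
location/scale model (ComBat), delegating the EB core to `sva::ComBat` and
preserving age (standardized) and sex (0/1) covariate effects. The default
treats **each windowed edge vector as one observation** carrying its
subject's site label — the literal reading of harmonizing "windowed
features". Because all 209 windows of a subject share that subject's site,
an alternative reading harmonizes subject-mean vectors and applies each
subject's adjustment to its windows; both are implemented
(`harmonize = "window"` / `"subject"`) and the choice is recorded in the run
manifest. Degenerate cases follow explicit contracts: a single site returns
the input unchanged with a warning; a feature with zero variance inside some
batch is adjusted location-only (scale has no information there).

The efficacy diagnostic is the per-feature one-way site F statistic before
and after adjustment; harmonization should reduce it in essentially all
features while leaving planted covariate slopes intact, and the test suite
asserts exactly that on simulated cohorts.

## State identification

Recurring connectivity configurations are found by two-stage k-means with
squared Euclidean distance on the Fisher-z edge vectors:

1. **Exemplars.** Per subject, windows at strict local maxima of the
   across-edge variance signal (endpoints excluded; if no interior strict
   maximum exists the global argmax is used, first index on plateaus). The
   variance signal has a second config-selectable reading (summed squared
   deviation from the subject's mean edge vector) because "temporal variance
   of connectivity across ROI pairs" is genuinely ambiguous; the default is
   the within-window across-edge variance.
2. **Stage 1.** Best-of-500-replicates Lloyd's k-means on the pooled
   exemplars (lowest within-cluster sum of squares wins). Each replicate
   draws distinct uniform starting points from a per-replicate substream of
   the master seed, so results are bit-reproducible and the best-of-$r$ WCSS
   is non-increasing in $r$.
3. **Stage 2.** A single Lloyd run over all valid windows initialized at the
   stage-1 centroids.

Ties in nearest-centroid assignment break to the lowest state id; a cluster
that empties during iteration is re-seeded at the point farthest from its
assigned centroid. Both policies exist purely to make the procedure
deterministic. The number of states is chosen by the elbow of the WCSS
curve; the curve is computed with warm starts (previous solution plus a
split of its widest cluster) so it is monotone at modest replicate counts,
and the knee is suggested as the largest second difference of
**log** WCSS. The log scale is a deliberate deviation from the common
raw-WCSS second difference: windowed correlation features share one dominant
sampling-covariance direction, which inflates the $k=1\to2$ drop and makes
the raw rule suggest $k=2$ even when three well-separated regimes are
planted; relative curvature recovers the planted three.

For reporting, states are relabeled by ascending centroid mean z and mapped
to the conventional numbering of three-state solutions: state 2 =
hypoconnected (lowest mean), state 1 = moderate, state 3 = hyperconnected.

## Temporal metrics

From each subject's state sequence over valid windows: fractional occupancy
(share of windows per state), mean dwell time (mean maximal-run length, in
window units; multiply by step × TR for seconds), total transitions
(adjacent label changes), and directed pairwise transition counts
(self-transitions excluded, zero diagonal). Unvisited states yield `NA`
("undefined"), never zero, and are excluded listwise per test downstream —
this is what produces per-state sample sizes slightly below the cohort
size. The final, censored run counts toward dwell time; no censoring
correction is applied. When invalid windows create gaps, a transition is
counted across the gap only if the labels differ. Per-subject identities
(occupancies sum to 1; pairwise counts sum to total transitions; runs ×
dwell = windows) are asserted on every subject in every run.

State-conditioned mean connectivity (`state_mean_fc()`) averages the edge z
values over any node subset — the full network (FC strength), a sub-network,
or a disjoint pair of sets for between-network means — per state, supporting
control analyses over arbitrary node sets.

## Statistical battery

Group comparisons use Welch's unequal-variance t with Welch–Satterthwaite
degrees of freedom and p-values from the t distribution at that non-integer
df (no normal approximation), computed from group summaries so that
published tables can be re-analyzed directly. Families are explicit: the 7
temporal metrics form one BH-FDR family, the 6 directed transitions another,
the 3 post-hoc state pairs a third, and each clinical stratum its own.
Effect sizes are Hedges g with $J = 1 - 3/(4N-9)$, reported as magnitudes
(direction lives in the t sign; the alternative small-sample correction
differs below reporting precision). Sex tables use Pearson chi-square with
Yates correction — required to reproduce a published 0.00 / 1.000 sex
comparison. Within-subject state differentiation uses a one-way
repeated-measures ANOVA with Greenhouse–Geisser $\epsilon$ estimated from
the condition covariance (not Huynh–Feldt), listwise deletion of subjects
with unvisited states, and FDR-corrected paired post-hocs on
pairwise-complete subjects. Covariate-adjusted group effects are OLS on
group + age + sex + mean framewise displacement + site dummies (reference =
largest site) with normal-theory 95% CIs; rank deficiency is an error that
names the collinear columns rather than a silent drop.

## The simulator: what it emulates and what it does not

The generator plants $k=3$ connectivity regimes as multivariate-normal
observation models whose **windowed** mean edge z matches published
three-state anchors (moderate 0.198, hypoconnected 0.106, hyperconnected
0.288). Each regime is a compound-symmetric correlation core plus fixed
symmetric edge texture (jitter), projected to a positive-definite
correlation matrix. Because a 22-sample correlation is a biased, noisy
estimator, the core correlation is calibrated by internal Monte-Carlo
(10,000 windows per evaluation, two correction sweeps) until the expected
windowed mean z is within ±0.02 of target.

Two generator parameters deserve justification:

* **Regime texture (`jitter_sd = 0.2`).** Real connectivity states differ
  in edge *pattern*, not only in mean level — published state centroids are
  visibly distinct matrices. With near-zero texture the planted regimes
  degenerate to mean-shifted copies of one exchangeable matrix separated by
  ~0.09 in mean z, which is below the sampling noise of a 22-TR windowed
  estimate: no estimator could recover window labels reliably, and k-means
  agreement on even pure windows drops to ~0.66. At 0.2 the regimes have
  distinct topographies of realistic magnitude and pure-window recovery is
  essentially perfect.
* **Markov dynamics.** Patients and controls share the moderate and
  hyperconnected rows; the case-control contrast is planted as an elevated
  hypoconnected-regime self-transition (0.97 vs 0.93) plus slightly reduced
  entry into the extremes, which yields the qualitative published pattern:
  greater patient occupancy of and dwell in the hypoconnected state and
  fewer transitions. A minimum segment length of 10 TR keeps segments long
  relative to the window so windows are regime-dominated; the published
  dwell times (≥ ~5 windows) imply comparably slow dynamics.

Site effects are planted exactly as the site model states them — additive
offsets and multiplicative scales **on the Fisher-z edge features** — by
transforming each regime's correlation matrix elementwise
($r \mapsto \tanh(\text{scale}\cdot(\operatorname{artanh} r +
\text{offset}))$) per site. A naive additive/multiplicative transform of the
raw signal would be invisible to correlations.

What the simulator does **not** emulate: hemodynamic convolution and
autocorrelation, motion artifacts and scanner drift, spatially structured
(non-exchangeable) anatomy, heavy-tailed BOLD noise, and real demographic
structure. Passing tests therefore demonstrate that the pipeline's
machinery is correct and sensitive under a faithful stochastic cartoon of
the data-generating process — not that the published group differences are
reproduced from real data, which are not redistributable here.

**Ground truth at window resolution.** A window overlapping a regime switch
mixes two covariance structures; below some dominance fraction its "true"
label is undefined. `planted_window_labels()` therefore takes a
`min_purity` argument: the default 0.5 keeps the plain majority label for
every window, while recovery tests score agreement over regime-dominated
windows (purity ≥ 2/3), where agreement is ~0.96 at cohort scale; over all
windows, majority-label agreement is ~0.89 because boundary windows are
genuinely intermediate. The clean clustering benchmark
(`simulate_regime_windows()`) removes this ambiguity entirely by drawing
each window from exactly one regime, and there two-stage k-means attains an
adjusted Rand index above 0.99.

## Problem sizes used in the shipped checks

The packaged test suite and the acceptance script run the full pipeline at
100 + 100 subjects (41,800 windows of 210 edges, ComBat at window level, 500
stage-1 replicates), the clean clustering benchmark at 100 × 209 windows
with a 6-point elbow at 50 replicates, null specificity over 50 fresh
cohorts of 30 + 30 labeled with the fitted model, and harmonization efficacy
at 30 subjects × 3 sites. These sizes were chosen so the effects of
interest are decisively powered while a complete run stays comfortable on a
single CPU; the analysis drivers under `analysis/` use 50 + 50 subjects for
the same reason.

## Known limitations

* Sliding-window + k-means is one operationalization of brain-state
  dynamics; hidden Markov models, time-varying graphical models, consensus
  clustering and silhouette/gap model selection are out of scope.
* Dwell times are right-censored by scan end and the simple run-length
  definition (deliberately) ignores it; very sticky states are therefore
  underestimated in short scans.
* Window-level ComBat treats windows of one subject as exchangeable
  observations of their site; a subject-level random-effects formulation is
  approximated by the `"subject"` mode, not modeled explicitly.
* The elbow knee is a suggestion; `k` is a configuration choice
  (`k = "auto"` adopts the suggestion).
* The simulator's null model (identical dynamics) shares covariances across
  groups; specificity under group-dependent covariance heterogeneity with
  identical dynamics is untested.
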