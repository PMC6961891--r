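---
title: "Detecting dynamic shifts in density-dependent population time series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting dynamic shifts in density-dependent population time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shiftdetector)
```

## The problem and the model

A population's *dynamic rule* is the set of parameter values governing
its fluctuations. Abrupt environmental change — an invading prey
species, a new management regime, habitat loss — can move those
parameters to new values without leaving an obvious signature in the
raw counts, because density dependence keeps the series fluctuating
either way. `shiftdetector` asks, for a single annual abundance series
$N_1, \dots, N_T$: did the rule change, when, and how strong is the
evidence?

Within one regime we assume Ricker dynamics with additive Gaussian
error,
$$N_{t+1} = N_t \exp\!\big(r\,(1 - N_t/K)\big) + \varepsilon_t,
  \qquad \varepsilon_t \sim \mathcal N(0, \sigma^2),$$
chosen for its minimal parameterisation (three estimated quantities,
all ecologically interpretable), its lack of exogenous inputs, and its
range of behaviours from compensatory to over-compensatory to chaotic
as $r$ grows. The fitting interface is deliberately segment-local, so
other discrete maps could be slotted in later; only Ricker ships.

## The detection algorithm

1. **Enumerate.** Every admissible *break-point combination* is a
   composition of the $T$ data points into contiguous segments of at
   least `min_segment` points (default 4 — the guard against fitting a
   three-parameter model to almost nothing). Enumeration is
   constructive and exhaustive; `max_breaks` exists only as an escape
   hatch for very long series.
2. **Fit.** Each segment is fitted independently by
   Levenberg–Marquardt least squares (`minpack.lm::nls.lm`),
   minimising $\sum (N_{t+1} - N_t e^{r(1-N_t/K)})^2$ over the
   segment's transition pairs.
3. **Score.** Each segment gets the Gaussian least-squares criterion
   $\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 2k$ with $k = 3$ ($r$, $K$,
   residual variance) and, by default, the small-sample correction
   $\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$. A combination's
   score is the sum over its segments, which is valid because the
   segments partition the transition pairs (next paragraph).
4. **Weigh.** Combinations within `equivalence_delta = 2` units of the
   best are reported as equivalently supported. Akaike weights over
   all scored combinations are pruned below `prune_threshold = 0.001`
   and renormalized; a year's *break weight* is the summed weight of
   retained combinations containing that break. Weights above 0.8 are
   labelled "supported", below 0.2 "erroneous", in between the weight
   itself quantifies the evidence.

### Transition-pair convention

A break "after year $y$" ends one segment at $y$ and starts the next
*at* $y$: consecutive segments share the boundary data point, and the
transition $y \to y+1$ belongs to the later regime — which is also how
the simulator applies shifts, so detection and generation agree about
what a break means. Under this convention a combination's segments
partition the $T-1$ transition pairs exactly once (the per-segment
`n_obs` always sum to $T-1$), the summed criterion never counts a
residual twice, and the first segment of a $p$-point part carries
$p-1$ pairs while later parts carry $p$. Reported phase tables use the
conventional labels (first phase from the series start, later phases
from break year $+1$).

### AICc at the minimum segment size

With $k = 3$ the correction denominator $n - k - 1$ is only positive
for segments with at least 5 transition pairs, so a minimal 4-point
segment (3 pairs) has no defined AICc. We keep the 4-point minimum as
the user-facing default and treat criterion finiteness as part of
admissibility: under AICc, combinations containing a segment with
fewer than 5 pairs are outside the scored model space (`segment_ic`
raises an instructive error if asked directly; `detect_shifts` simply
never scores them, and reports the effective constraint). Under AIC
the 4-point minimum binds as stated. Users wanting more sensitivity at
short segment lengths should switch to `criterion = "AIC"` rather than
lower `min_segment`.

The benchmark harness draws ground-truth break sets uniformly from the
sets the configured criterion can score, for the same reason: a truth
that is structurally outside the model space measures the
admissibility rule, not the detector, and would make "accuracy"
uninterpretable. This is the one place where the harness is
deliberately stricter than the simulator's own default (which only
enforces the 4-point rule).

### Numerical choices

* **Starting values** (unstated by any convention): $r_0 = 1$, mid
  range of plausible per-step growth rates, and $K_0$ = the segment's
  mean abundance — a robust guess for series fluctuating around
  carrying capacity. $K$ is bounded below by $10^{-9} \times$ mean
  abundance to forbid sign flips; $r$ is unbounded.
* **Standard errors** come from the Jacobian-based covariance at the
  solution scaled by $\mathrm{RSS}/(n-2)$, standard nonlinear
  least-squares practice. A series sitting exactly at equilibrium fits
  every $r$ equally well; that non-identifiability surfaces as huge or
  `NA` standard errors, never as a crash.
* **Residual floor.** Inside the criterion the RSS is floored at
  $n_\mathrm{obs} \cdot (10^{-6}\,\bar N)^2$ (`rss_floor_rel`). On
  noiseless data every segmentation that respects the true breaks fits
  to rounding error, and comparing logarithms of rounding error is
  meaningless; the floor equalises those log-likelihood terms so the
  ranking degrades gracefully to the parsimony penalty. At every noise
  level in the simulation design ($\tau \ge 1\%$) the floor is
  inactive by about four orders of magnitude.
* **Ties and determinism.** Equal total scores rank the combination
  with fewer breaks first, then lexicographically by break years;
  identical input and configuration give identical output.
* **Non-convergent segments** render their combination unscorable; it
  is dropped with a warning and counted in the result
  (`n_unscorable`). Equivalence-set members are never pruned by the
  0.001 weight cut, so the reported top set is always complete.

## The simulator and what it emulates

`simulate_ricker` iterates the deterministic map and applies
*multiplicative* Gaussian noise: the expected next abundance is
multiplied by $(1 + \eta_t)$, $\eta_t \sim \mathcal N(0, \tau)$, so
noise scales with population size — a reasonable stand-in for combined
environmental and sampling variation across series of very different
magnitudes. Note the asymmetry with the additive error assumed when
fitting; both are implemented exactly as specified and no attempt is
made to reconcile them, which is itself part of what the benchmark
measures (model misspecification is the realistic case). At each break
the current $r$ and $K$ are multiplied by $(1 \pm \delta)$ with signs
drawn independently per parameter per break; successive shifts
compound on the current values. A noise draw that would push abundance
to zero or below is redrawn rather than truncated, to avoid biasing
the noise mean (at the design's noise levels this is a >6-sigma
event).

The scenario grid reproduces the full benchmark design: base values
$N_1 = 3000$, $K = 2000$, $r_0 = 2$, $\delta_r = \pm 25\%$,
$\delta_K = \pm 75\%$, $\tau = 2\%$, 20-year series; 40 scenarios
crossing $r_0 \in \{0.5, 1, 1.5, 2\}$ with five shift sizes in $r$ and
five in $K$; 50 crossing $\tau \in \{1, 2, 5, 10, 15\}\%$ with the
same shift grids; 4 varying length over $\{15, 20, 25, 30\}$ — 94 in
all, with $K$'s starting value held fixed throughout since the
dynamics depend on other parameters relative to $K$ rather than on its
absolute value. The design's full scale is 250 replicates per scenario
per break count (0–3).

What the simulator does **not** emulate: demographic stochasticity,
age or stage structure, observation models separate from process
noise, autocorrelated environments, gradual (press) parameter change.
Passing benchmarks therefore show the detector recovers clean step
changes in an otherwise well-specified world; on real data, where
drivers superimpose and shifts can be gradual, break weights should be
read as evidence summaries, not verdicts.

## Evaluation metrics

A replicate counts as *detected* only when the exact true break set —
set equality, not containment — appears among the equivalence-set
combinations; a candidate containing the true breaks plus a spurious
one does not count, and a true break matched one year off counts as
erroneous. This is the strict reading of "the true break scenario is
in the top set", and it makes the headline accuracy conservative; a
looser per-break view is available from the per-break weight table
that the harness also returns. Break weights pool across replicates
and partition by exact year match into true and erroneous; an empty
partition is reported absent, not zero. Replicates where detection
fails outright are counted separately and excluded from the accuracy
denominator.

## Problem sizes in the shipped checks

The packaged tests and the acceptance script run the base scenario at
100 replicates per break count (0–2), the noiseless separability check
at 100 replicates, enumeration cross-checks up to 16-point series, and
parameter-recovery grids over $r \in \{0.5, 1, 1.5, 2\}$ — sizes
chosen so the whole suite completes in well under a minute while
keeping Monte-Carlo standard errors on accuracy near one percentage
point. The full-scale study is one `benchmark_grid()` call away.

## Known limitations

* Exhaustive enumeration is factorial-ish in series length; beyond
  ~40 points use `max_breaks` or analyse the window of interest.
* Shifts closer together than the minimum segment size are invisible
  by construction.
* AICc's penalty shrinks as series lengthen, so long series accumulate
  more small-weight spurious candidates; the break-weight decision
  rules (0.8/0.2) are the intended antidote.
* The per-segment error model is additive Gaussian on abundance;
  strongly skewed observation error (e.g. log-normal counts spanning
  orders of magnitude) may warrant transforming the series first, at
  the cost of changing the parameters' interpretation.
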