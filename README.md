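# shiftdetector

Break-point detection for density-dependent population time series.

Ecological populations are governed by internal rules — density
dependence, a carrying capacity, an intrinsic growth rate — and
external perturbations can abruptly move those parameters to new
values. Pinpointing *when* such a dynamic shift happened in a noisy
annual abundance series is hard: segmented linear regressions ignore
the nonlinearity, and ad-hoc break placement invites bias.
`shiftdetector` is for population ecologists and quantitative
conservation analysts who have one abundance value per year (trap
counts, census areas, survey indices) and want an exhaustive,
information-theoretic answer with honest uncertainty.

## The method

Within each regime the population is assumed to follow a Ricker map
with additive Gaussian error:

    N[t+1] = N[t] * exp(r * (1 - N[t] / K)) + e[t],   e[t] ~ N(0, s^2)

The series is partitioned into every admissible *break-point
combination* — every composition of the series into contiguous
segments of at least 4 data points (a break "after year y" ends one
segment at y; the transition y → y+1 already belongs to the next
regime, so no transition pair is used twice). Each segment is fitted
independently by Levenberg–Marquardt nonlinear least squares, scored
with the small-sample-corrected Akaike information criterion

    AICc = n * ln(RSS / n) + 2k + 2k(k+1) / (n - k - 1),   k = 3,

with n the segment's transition pairs, and a combination's score is
the sum over its segments. Combinations within 2 units of the best
form the *equivalence set* of top candidates; Akaike weights
`w_i = exp(-d_i/2) / sum_j exp(-d_j/2)` over all scored combinations
(pruned below 0.001 and renormalized) are summed per break year into a
**break weight** in [0, 1] — above 0.8 a break can be treated as real,
below 0.2 as erroneous, in between the weight itself is the strength
of evidence.

The package also ships the full simulation design used to benchmark
the detector (94 scenarios varying initial growth rate, shift sizes in
r and K, multiplicative noise 1–15%, and series length 15–30) and an
evaluation harness measuring exact-set detection accuracy and
true-vs-erroneous break-weight separation.

## Worked example

A bundled synthetic series (20 years, one simulated −75% shift in K
after year 12, 2% noise):

```r
library(shiftdetector)
series <- read_series_csv(system.file("extdata", "synthetic_one_break.csv",
                                      package = "shiftdetector"))
ranking <- detect_shifts(series, criterion = "AICc")
ranking
summary(ranking)
```

```
Dynamic-shift ranking (criterion: AICc )
  26 combination(s) scored, 25 pruned (< 0.001 weight), 0 unscorable
  best combination: break(s) after 12
  equivalence set (delta < 2): 1 combination(s)
    { 12 }                   IC =   132.530  delta =  0.00  w = 1.000
  break weights:
    after 12: 1.000 (supported)
Segment parameter estimates (best combination):
 start_year end_year    r   se_r    k se_k sigma n_obs   rss converged
          1       12 2.02 0.0165 2005 6.23 33.09    11 12044      TRUE
         13       20 2.00 0.0186  501 2.30  8.43     8   569      TRUE
```

Reading it: of the 26 scoreable segmentations, the single break after
year 12 wins outright — no rival lands within 2 AICc units, so the
break carries the full weight 1.000 ("supported" under the 0.8/0.2
decision rules). The per-phase table recovers the generating
parameters (r ≈ 2 throughout; K ≈ 2000 dropping to ≈ 500 after the
break).

The same pipeline is available from a shell via the installed script:

```sh
<library>/shiftdetector/exec/shiftdetect detect --input series.csv --json report.json
<library>/shiftdetector/exec/shiftdetect simulate --output sim.csv --n-breaks 2 --seed 7
<library>/shiftdetector/exec/shiftdetect benchmark --scenarios 20 --reps 100 --seed 1
```

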