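---
title: "Methods: acoustic coordination of collective movements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic coordination of collective movements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(troopcall)
```

## The problem

Group-living primates must coordinate departures: a movement succeeds only if
enough individuals follow the initiator. `troopcall` implements the analysis
chain used to study how acoustic signals participate in that coordination in
a matrilineal macaque troop: characterising the calls given during
departures, measuring each individual's social position, quantifying joining
order in collective movements, and modelling which social factors predict how
often an individual vocalizes. Because raw field observations of this kind
are rarely deposited, the package pairs every analysis stage with a synthetic
generator whose ground truth is known, so the whole chain is testable end to
end.

## Movement analytics

A *collective movement* is a run of joins with no gap exceeding five minutes;
it is *successful* with at least three participants, initiator included
(`segment_events()`). Distance thresholds are read strictly ("over 10 m"
means `> 10`) and temporal/angular windows inclusively ("within 30 s" means
`<= 30`); the initiator is the first individual to walk over 10 m within
30 s, a follower moves over 5 m within 45 degrees of the initiator's bearing
(circular difference). Simultaneous join times keep record order, so join
positions are always distinct — the field protocol never produces exact ties,
and a deterministic tie-break keeps the pipeline reproducible.

The joining-order index of the individual at 1-based position $I$ among $N$
participants is

$$\mathrm{OI} = 1 - \frac{I - 1}{N - 1},$$

which is 1 for the initiator and 0 for the last joiner; it is undefined for
$N < 2$ and the package refuses to compute it there.

Vocal tallies are reported as complementary percentage pairs rounded to one
decimal with largest-remainder reconciliation, so each pair sums to exactly
100.0. On the packaged 132-movement fixture this yields 39.4% vocal / 60.6%
non-vocal, and an initiator-vocal share of 65.4% (= 34/52; note that 65.4 is
the only value consistent with the counts under any standard rounding rule).
Per-individual *vocal frequency* is total calls divided by the number of
movements the individual participated in; the exposure (participation count)
is carried separately so a per-time convention is a one-line change.

## Social metrics

**Dyadic association.** For individuals $a, b$ the dyadic association index
is the simple-ratio measure

$$\mathrm{DAI}_{ab} = \frac{D_{ab}}{D_a + D_b - D_{ab}},$$

with $D_{ab}$ the total time the pair spent within 1 m (summed over all
focal sessions of either individual) and $D_a$, $D_b$ each individual's total
focal observation time. The diagonal is fixed at 0. When the denominator is
non-positive — possible only when a pair is in proximity for essentially all
observed time — the index takes its limiting value (1 if any proximity was
seen, 0 otherwise), and all values are clamped to $[0, 1]$.

**Eigenvector centrality** is the leading eigenvector of the (weighted,
symmetric) DAI matrix, computed by power iteration from the uniform vector on
the largest connected component; off-component individuals score 0 and the
vector is normalized to unit Euclidean norm. Two numerical choices matter:
a positive diagonal shift (half the maximum row sum) is added during
iteration — this leaves the leading eigenvector unchanged but prevents the
permanent oscillation that plain power iteration exhibits on bipartite
graphs, where the spectrum is symmetric; and convergence is declared when
successive normalized iterates differ by less than `tol` (default 1e-12) in
max-norm, with non-convergence an error, never a silent return. Raw weights
are used by default (no binarization); because the downstream regression is
scale-equivariant, the normalization convention only rescales the centrality
coefficient.

**Dominance.** David's Score for individual $i$ is
$DS_i = w_i + w_2 - l_i - l_2$ with $w_i = \sum_j P_{ij}$,
$w_{2,i} = \sum_j w_j P_{ij}$, and mirror-image loss terms, where $P_{ij}$ is
$i$'s win proportion against $j$. Dyads that never interacted contribute
$P = 0$ in both directions rather than an invented 0.5. The chance-corrected
$D_{ij}$ variant is available (`correction = "dij"`). Under the $P_{ij}$
convention the scores sum to zero, which the tests assert as a conservation
identity. Ranks are descending in DS with lexicographic id tie-break.

**Kinship** is matrilineal: an individual's relative count is its matriline
size minus one; immigrants (no matriline) count 0.

## Acoustics

Calls are analysed frame-by-frame with a 0.03 s Gaussian window and 0.01 s
hop. The fundamental is tracked by normalized autocorrelation within a
75–600 Hz search band (the repertoire spans roughly 244–490 Hz):

- the frame autocorrelation is divided by the window's own autocorrelation to
  undo the taper-induced bias toward short lags, and clamped at 1 because
  that correction can overshoot on strongly non-stationary frames;
- candidate peaks are the local maxima in the lag band; a small per-octave
  cost (0.05 per doubling of lag) prefers the shortest of near-equal peaks —
  a periodic signal peaks identically at every multiple of its period, so
  without this cost the tracker halves the true f0;
- the chosen peak is refined by a least-squares parabola whose half-width
  grows with the lag (broad low-f0 peaks average more points), giving
  sub-sample precision that stays below 1% error on noisy tones at 20 dB SNR;
- frames whose peak value falls below the voicing threshold 0.45 (a standard
  default, exposed as an argument) are unvoiced.

Call-level features are the seven used for call typing: duration of the
voiced span (first to last voiced frame, endpoint-inclusive, i.e. plus one
window length), mean/min/max f0 over voiced frames, and mean/min/max
per-frame intensity. Intensity uses the 16-bit convention that a full-scale
sine reads 96 dB; absolute sound-pressure comparability with field recordings
is explicitly not claimed. f0 statistics are taken over voiced frames only —
the alternative (whole-file statistics) is not meaningful for an
autocorrelation tracker that marks silence unvoiced.

Classification assigns a feature vector to the nearest type centroid in
per-feature-standardized Euclidean distance; ties break in fixed type order
(coo, leap coo, bark). The bark type has a single exemplar and hence no
dispersion of its own; it borrows the pooled coo/leap-coo standard deviation
per feature, the only available variance estimate.

**Synthesis.** `synthesize_call()` renders a 5-harmonic stack with 1/k
rolloff (harmonics of the repertoire's f0 range stay below 5 kHz, the band in
which these calls carry structure; the exact timbre is irrelevant to the
seven features). The f0 contour and dB envelope each rise monotonically from
the type minimum to its maximum following $u^p$ in normalized time, with $p$
solved so the frame-sampled mean equals the type mean. Targets are placed at
the analysis frame centers, and a short fixed-point calibration loop
(render, measure on the same grid, feed back the error, three passes)
compensates the smoothing that short-time analysis applies near call edges —
without it the 0.06 s bark, which spans only four frames, misses its minimum
intensity by more than a decibel. Jitter perturbs every target
multiplicatively on the log scale (trios re-sorted to stay ordered).

## The statistical battery

**Mann–Whitney U.** Midrank-based; `U` counts pairs with $x > y$ (ties half).
When $n_1 n_2 \le 400$ and the data are tie-free the two-sided p-value comes
from the exact permutation distribution, computed by a subset-sum dynamic
program over ranks and memoised per $(n_1, n_2)$; otherwise a normal
approximation with midrank tie correction and 0.5 continuity correction is
used (matching the conventions of standard rank-sum software, so the W form
is directly comparable). The empirical size at nominal 0.05 over 10,000 null
replicates with $n = 20$ per group is 0.051.

**Spearman correlation** is the Pearson correlation of midranks with the
t-approximation on $n - 2$ degrees of freedom.

**Count model.** Vocal frequency is zero-heavy, so the social-factor model is
a zero-inflated Poisson: a structural-zero probability $\pi$ (intercept-only
on the logit scale) mixed with a Poisson whose log rate is linear in the
predictors with a log-exposure offset. The original analysis used a
mixed-model package with an unstated random-effect structure; since the
analysis unit here is the individual-by-event count with all predictors
individual-level, the identifiable default is the fixed-effects ZIP, and the
gap is documented rather than papered over. Inference is Wald (estimate/SE
with two-sided normal p), matching the shape of a Z-column coefficient
table. Optimization is BFGS with an analytic gradient from a zero start for
the count part and the observed zero fraction for the inflation part,
followed by safeguarded Newton polishing until the gradient max-norm falls
below 1e-8; the log-likelihood trace is recorded and never decreases, and
standard errors come from the observed information at the optimum.
Rank-deficient designs and non-positive exposures are errors naming the
offending columns, and non-convergence is flagged in the result, never
silently returned. On zero-inflation-free data the Poisson family reproduces
a standard GLM fit to 1e-6; on ZIP data the fit matches an independent
mixed-model implementation to 1e-4.

## The synthetic generator

The generator is latent-variable based, because the study reports the
analysis, not the data-generating process:

- **Roster**: 12 males and 15 females (the adult + sub-adult focal makeup);
  females are assigned to matrilines multinomially so matriline sizes vary;
  each male is an immigrant with probability 3/4 (at least one always is, so
  relative counts of 0 occur; at least one male belongs to a matriline, so
  the relative count is never a deterministic function of sex — that would
  make the regression design singular). Each individual carries a latent
  gregariousness (lognormal, log-SD 0.6) and a latent strength rank.
- **Proximity**: per focal session, dyadic 1 m durations scale with the
  product of the two gregariousness values with Beta-shaped noise, so
  expected DAI rises in that product; the log-SD 0.6 produces the strong
  between-individual association heterogeneity typical of provisioned
  macaque troops and makes the centrality effect identifiable at the study's
  effect sizes.
- **Agonism**: every dyad interacts (6 bouts by default); the stronger
  individual wins with logistic probability in the strength difference,
  scaled by `dominance_steepness` — 0 gives coin flips (David's Scores near
  zero), large values a strict linear hierarchy.
- **Movements**: at least 3 participants per event, sampled with
  gregariousness weights; call counts are zero-inflated Poisson with log
  rate `vocal_intercept + 0.771*female + 3.361*centrality +
  order_effect*order_index`. The sex and centrality coefficients are the
  fitted values of the study's social-factor table, taken as ground truth;
  `vocal_intercept = -2.8` and `zero_inflation = 0.6` make roughly 88% of
  per-participant counts zero, the strongly zero-heavy regime the model is
  meant for, while keeping both effects recoverable at 500 events. The
  generating parameters are returned with the events for recovery tests.
- **paper_tally preset**: a deterministic 132-event fixture on the bundled
  study roster with 52 vocal events, 34 of them initiator-vocal —
  the printed movement tallies as exact counts.

Every generator is a pure function of (config, seed); each draws from its own
named sub-stream of the master seed, so adding a generator never perturbs the
others' output.

What the generator does **not** emulate: spatial trajectories (displacement
and bearing checks operate on already-measured observations), temporal
autocorrelation across sessions, individual random effects beyond the
modelled covariates, observation error in caller identity, and seasonal
effects. Passing tests therefore demonstrate the correctness of the
computational chain under a known process, not the field validity of the
original measurements.

## Problem sizes and runtime choices

The test suite runs the acoustic round trip on full-rate (44.1 kHz) audio;
network and dominance oracles use the study's 27-individual scale; recovery
checks use 500-event simulations over 20 seeds and a 100-simulation sign
pattern; the rank-test size check uses 10,000 null replicates. These sizes
keep the whole suite under a couple of minutes while leaving Monte-Carlo
margins well away from the asserted thresholds.

## Known limitations

- The exact David's Score variant and data subset behind the bundled printed
  scores are not recoverable; the bundled roster is a structural template
  (its printed DS values do not sum to zero), and the package's own DS is
  always recomputed from bouts.
- The f0 tracker is designed for one call per file; it does not segment long
  recordings or handle overlapping callers.
- The ZIP model has no random effects and no negative-binomial family; with
  individual-level predictors and event-level counts the fixed-effects model
  is the identifiable core, but clustered overdispersion in real data would
  make its Wald SEs optimistic.
- Amplitude features are relative to digital full scale, not calibrated SPL.
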