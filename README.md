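# troopcall

Tools for studying how acoustic signals coordinate collective movements in
primate troops. The package grew out of the analysis problem posed by a
matrilineal macaque group in which some departures are accompanied by calls
(coos, leap coos, an occasional bark) and some are silent: do calls recruit
participants, do early joiners call more, and which social factors — sex,
dominance rank, kin count, network centrality — predict how often an
individual vocalizes?

It is aimed at behavioural ecologists who have focal-observation proximity
records, agonistic bout logs, movement join logs and call recordings (or who
want to prototype such an analysis on simulated data before fieldwork).

## What it computes

- **Movement analytics** — five-minute-rule event segmentation,
  initiator/follower classification, and the joining-order index
  `OI = 1 − (I − 1)/(N − 1)` (1 = first joiner, 0 = last), plus vocal
  tallies with reconciled percentages.
- **Social metrics** — the dyadic association index
  `DAI = D_ab / (D_a + D_b − D_ab)` from 1 m proximity durations,
  eigenvector centrality of the DAI network by power iteration, David's
  Score dominance ranking (`DS = w + w2 − l − l2`, Pij or Dij convention),
  and matrilineal relative counts.
- **Bioacoustics** — autocorrelation f0 tracking (Gaussian window 0.03 s,
  hop 0.01 s, band 75–600 Hz), seven-feature call summaries (duration,
  mean/min/max f0, mean/min/max intensity), nearest-centroid call typing,
  and a harmonic-stack call synthesizer that round-trips those features.
- **Statistics** — Mann–Whitney U (exact permutation distribution when
  feasible, tie/continuity-corrected normal approximation otherwise),
  Spearman rank correlation, and a zero-inflated Poisson regression with
  Wald tests (the identifiable core of a zero-heavy count GLMM).
- **Synthetic data** — a troop generator with known ground truth for every
  stage (roster, proximity, bouts, movements, audio), plus a deterministic
  `paper_tally` fixture reproducing the reference tallies
  (132 movements, 52 vocal, 34 initiator-vocal).

## Worked example

```r
library(troopcall)
rep <- run_pipeline(troop_config(seed = 1), out_dir = "run1")
print(rep)
```

prints (abridged):

```
## Movement tallies
- 132 successful movements; 84 vocal (63.6%), 48 non-vocal (36.4%)
- initiator vocal in 27 of the vocal movements (32.1%)

## Social-factor count model
ZIP count model (n = 1077, logLik = -488.11)
        term estimate      se      z         p
 (Intercept) -2.25973 0.37263 -6.064 1.325e-09
      female  0.44547 0.25243  1.765 7.761e-02
        rank  0.01217 0.01197  1.017 3.092e-01
   relatives  0.08357 0.05607  1.491 1.361e-01
  centrality  2.30585 0.90185  2.557 1.056e-02
zero inflation: pi = 0.612 (logit 0.455 +/- 0.239)
```

Reading it: of 132 simulated departures, 84 had at least one call. The count
model estimates each factor's effect on the per-movement call rate (log
scale): at 132 movements the positive female and centrality effects used by
the generator (0.771 and 3.361) are estimated with wide intervals — a single
season of movements identifies the centrality effect (p = 0.011) but leaves
sex marginal (p = 0.078); at 500 movements both are recovered decisively
(see `tests/testthat/test-acceptance.R`). Rank and relatives, which the
generator leaves at zero, stay near zero. The `run1/` directory holds every
intermediate table as CSV (`dai_matrix.csv`, `dominance.csv`,
`order_index.csv`, `model_table.csv`, ...).

The exact reference tallies come from the deterministic fixture:

```r
rep <- run_pipeline(troop_config(), out_dir = "tally", preset = "paper_tally",
                    stages = c("simulate", "movements"))
rep$tallies[c("n_events", "n_vocal", "pct_vocal", "pct_nonvocal")]
#> 132, 52, 39.4, 60.6
```

A command-line front end is included at `inst/scripts/troopcall.R`
(`Rscript troopcall.R run --seed 1 --out DIR`).

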