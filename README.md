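# allochrony

Quantifying **daily temporal reproductive isolation** between the E and Z
pheromone strains of the European corn borer, and the gene-expression
time-course analysis that goes with it.

Two moth strains that mate at different times of night (and different times
of summer) are partially reproductively isolated simply because potential
mates rarely meet. This package is for evolutionary biologists measuring
that isolation from timed mating trials, and for anyone analysing the
accompanying head-transcriptome time course sampled around each strain's
peak mating time.

## The statistic at its core

Mating times observed at 20-minute checks over a 7-h scotophase are binned
into one-hour windows. In window *i* with *n<sub>i</sub>* matings, strain
fractions *p<sub>i</sub>* (Z) and *q<sub>i</sub>* (E), random within-window
mating would produce 2*p<sub>i</sub>q<sub>i</sub>n<sub>i</sub>* hybrid and
(*p<sub>i</sub>*² + *q<sub>i</sub>*²)*n<sub>i</sub>* pure-strain offspring
(Hardy–Weinberg proportions). Summing over windows,

> RI = 1 − Σ 2 p<sub>i</sub> q<sub>i</sub> n<sub>i</sub> / Σ (p<sub>i</sub>² + q<sub>i</sub>²) n<sub>i</sub>

ranges from 0 (random mating) to 1 (complete temporal separation).
Sequential barriers combine as `1 − Π(1 − s_k)`: seasonal isolation of 0.66
plus daily isolation of 0.393 blocks 1 − 0.34 × 0.607 ≈ **79%** of
inter-strain mating.

The expression stage runs CPM normalisation, a weak-expression filter
(≥ 1 CPM in ≥ 7 libraries), nine contrasts (between strains at each of three
timepoints; within each strain between timepoint pairs) with per-contrast
Benjamini–Hochberg correction, strain × timepoint mean profiles, and
pairwise profile correlations with t(4) p-values. Contrast p-values use a
Welch test on log2(CPM + 0.5) — a documented lightweight surrogate for a
negative-binomial GLM (see the methods vignette).

## Worked example

```r
library(allochrony)

cfg    <- trial_sim_config()              # study-scale defaults: 76/79 trials,
trials <- simulate_trials(cfg, seed = 11) # propensity ~0.3, medians 1.33/4.0 h
trial_summary_table(trials)
#>   strain n_trials n_mated prop_mated median_h   mean_h
#> 1      E       76      28  0.3684211 1.333333 1.547619
#> 2      Z       79      31  0.3924051 4.333333 4.333333

rep <- run_trial_analysis(trials, n_boot = 1000, seed = 11,
                          seasonal_strength = 0.66)
```

which prints (via the report fields):

```
Fisher p = 0.869                       # strains mate at similar rates...
rank-sum W = 418.5, p = 1.386e-10      # ...but at very different times
RI = 0.886, 95% CI [0.789, 0.970]      # daily isolation in this simulation
combined with seasonal 0.66: 0.961     # joint sequential barrier
```

Here the simulated strains' nightly distributions (medians 1.33 h vs 4 h,
spread 1.2 h) barely overlap, so daily RI is high; the Fisher test correctly
finds no propensity difference, while the rank-sum test flags the timing
difference. On the published trial counts themselves the package reproduces
27.6% / 31.6% mated, Fisher p = 0.602, and the 79% joint barrier.

The expression side, on a null simulated matrix:

```r
sim <- simulate_counts(counts_sim_config(n_transcripts = 500), seed = 11)
er  <- run_expression_analysis(sim$counts, sim$meta)
er$manifest$n_kept                      # 500 of 500 pass the filter
unlist(er$manifest$significant_per_contrast)
#> all nine contrasts: 0                 # no false positives at q < 0.05
```

## Command line

```sh
Rscript inst/cli/allochrony.R simulate-trials --out trials.csv --seed 1
Rscript inst/cli/allochrony.R analyze-trials  --trials trials.csv \
    --out-prefix report --seasonal 0.66
Rscript inst/cli/allochrony.R simulate-counts --out-counts counts.tsv \
    --out-meta meta.csv --seed 1
Rscript inst/cli/allochrony.R analyze-expression --counts counts.tsv \
    --meta meta.csv --out-dir expr_out
```

Exit codes: 0 success, 2 validation error, 3 computation error. Results go
to files/stdout, logs to stderr; every report embeds the tool version and a
config fingerprint.

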