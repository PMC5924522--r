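---
title: "Methods: quantifying daily temporal isolation and its expression correlates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying daily temporal isolation and its expression correlates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allochrony)
```

## The problem

Two pheromone strains of the European corn borer (E and Z) differ both in
*seasonal* mating time (early- vs late-summer flights) and in *daily* mating
time within the night. Both are forms of allochrony: reproductive isolation
that arises purely because potential mates are active at different times.
`allochrony` quantifies the daily component from timed mating trials, attaches
uncertainty, combines it with the seasonal barrier, and provides a companion
RNA-seq time-course stage for asking which transcripts (circadian clock genes
in particular) track the strain difference in nightly mating time.

## The isolation index

Trials record, for each single-strain mating group observed over a 7-h dark
period (scotophase) at 20-minute checks, whether the group mated and the first
check at which mating was seen. Mated times are binned into one-hour windows
`((k-1), k]`, right-closed so that a mating recorded exactly on the hour
belongs to the elapsed hour — the recorded time is "first check at which
mating was observed", so the event happened at or before the check.

Within window $i$, let $n_i$ be the matings observed, $p_i$ the Z-strain and
$q_i = 1 - p_i$ the E-strain fraction. If moths re-paired at random *within*
their activity window, Hardy–Weinberg proportions give $2 p_i q_i n_i$
expected hybrid and $(p_i^2 + q_i^2)\, n_i$ expected pure-strain offspring.
Summed over windows,

$$\mathrm{RI} \;=\; 1 - \frac{\sum_i 2 p_i q_i n_i}{\sum_i (p_i^2 + q_i^2) n_i},$$

which is 0 when every occupied window is 50:50 and 1 when no window mixes
strains. Because $2pq \le p^2 + q^2$, RI always lies in $[0, 1]$, and it is
invariant to multiplying all counts by a constant — so counting mating
*pairs* versus individual *moths* only rescales the expected-offspring totals
(`unit = "moths"` is available but cancels in RI). Empty windows contribute
nothing to either sum; the statistic is undefined (an error) when no matings
were observed at all.

Two properties worth knowing:

* **RI = 0 requires 50:50 windows, not merely identical timing.** If one
  strain simply mates more (higher propensity or more trials), every window
  departs from 50:50 and RI is slightly positive even with identical time
  distributions. The index deliberately measures departure from random
  mating in the assembled pool, and the pool reflects abundance as well as
  timing.
* **Small-sample bias.** With few matings per window, estimated $p_i$ are
  noisy and RI is biased upward; the bootstrap below reflects sampling
  variability but not this bias, which is why the simulator-recovery test is
  run at large trial counts.

### Bootstrap uncertainty

The study design fixes who was offered a mate, and RI is conditional on who
actually mated; the bootstrap therefore resamples the *mated* observations
with replacement, stratified by strain so each strain's mated count stays
fixed, and reports a percentile interval (default 95%, `n_boot` resamples,
deterministic given a seed). Coverage is validated by simulation at 500
trials per strain; at the original study's scale (~20 matings per strain)
percentile intervals are wide and can undercover, which the interval's width
makes visible.

### Combining sequential barriers

Barriers act in sequence: a later barrier can only remove gene flow that
earlier barriers let pass, so strengths combine as
$T = 1 - \prod_k (1 - s_k)$. The published seasonal strength 0.66 and daily
strength 0.393 give $1 - 0.34 \times 0.607 = 0.794$, i.e. about 79% of
inter-strain mating blocked. The combination is order-invariant,
nondecreasing in each argument, and dominated by any complete barrier.

## Trial-level tests

Strain differences in mating *propensity* use a two-sided Fisher's exact
test on the mated/unmated 2×2 table, with the minimum-likelihood two-sided
rule (sum point hypergeometric probabilities no larger than the observed
table's, with a 1e-7 relative tolerance for float ties) — the convention of
the common statistical packages, and the one consistent with the published
p = 0.602 for the 21/76 vs 25/79 table. Differences in mating *time* use the
Wilcoxon–Mann–Whitney rank-sum test. Because times are quantized to 20-minute
checks, ties are expected: midranks with a tie-corrected normal approximation
(no continuity correction) are the default, with exact enumeration when both
samples are ≤ 8 and untied. The statistic is reported in both the rank-sum
(W) and Mann–Whitney (U) conventions because published "W" values are
ambiguous between software conventions; inference is on the p-value.

## The expression stage

The design is 2 strains × 3 timepoints (end of photophase, 1.3 h and 4 h
into scotophase — the two strains' median mating times) × 4 replicate
libraries, with one Z 1.3 h library missing (23 libraries). The pipeline:

1. **CPM normalisation** — counts per million library reads.
2. **Weak-expression filter** — keep transcripts with ≥ 1 CPM in ≥ 7
   libraries; 7 is the smallest number of libraries representing both strains
   at one timepoint in this design. The filter is idempotent in practice but
   re-filtering after dropping rows can shift CPM marginally; the filter log
   records thresholds and dropped ids.
3. **Nine contrasts** — between strains at each timepoint (positive log2FC =
   higher in E) and within each strain between each timepoint pair (positive
   = higher at the *earlier* timepoint, ordering photophase < 1.3 h < 4 h).
   log2FC is the ratio of group-mean CPM with a prior count (default 0.5)
   added to both means.
4. **Significance surrogate** — p-values come from a Welch t-test on
   `log2(CPM + 0.5)` replicate values. This deliberately replaces a
   negative-binomial GLM with GC/depth offsets: it preserves the contrast
   structure, sign conventions and FDR procedure while keeping the package
   dependency-light and the null well-calibrated at the simulated
   independence structure. Agreement with differential-expression lists from
   count-model software is *not* claimed, and the per-contrast significant
   counts here should not be compared numerically to published ones.
5. **BH correction** — Benjamini–Hochberg within each contrast separately
   (the published per-contrast DE counts imply per-contrast correction).
6. **Profiles and correlations** — normalised counts averaged within each
   (strain, timepoint) group give a 6-point mean profile per transcript, in
   the fixed order E-photophase, E-1.3h, E-4h, Z-photophase, Z-1.3h, Z-4h;
   missing replicates are averaged over the libraries present. Pairwise
   Pearson correlations over the 6 points get two-sided p-values from
   $t = r\sqrt{4/(1-r^2)}$ with 4 df — this reproduces the published
   (r, p) pairs (−0.82 → 0.046, 0.97 → 0.001) to printed precision, which is
   how the convention was identified. Constant profiles carry no correlation
   information and are skipped with a warning. Note the small-sample caveat:
   with 6 points the p-values assume bivariate normality and are best read
   as a screening device.
7. **Heatmap export** — log2FC clamped to [−2, 2] *for display only*, with
   asterisks at q < 0.05.

## The synthetic world

`simulate_trials()` emulates the trial protocol: per trial, mating is
Bernoulli(`p_mate`); mated trials draw a latent time from a truncated normal
(default) or truncated gamma on `(0, 7]` h and record its ceiling on the
20-minute check grid. Defaults mirror the observed study scale: 76/79
trials, propensities 0.28/0.32, locations 1.33 h (E) and 4.0 h (Z). The
spread is not published; 1.2 h was chosen once as a realistic nightly
activity spread and is not revisited. The truncated normal is a fixture, not
a biological claim; the gamma option exists because observed mating-time
histograms are right-skewed. `expected_ri()` computes the analytic
large-sample RI of a configuration from the binned distribution masses
(upward censoring to the check grid cannot cross an hour boundary, so window
masses are exact), serving as an independent oracle for parameter-recovery
tests.

`simulate_counts()` emulates the 23-library count design: negative-binomial
counts with $\mathrm{var} = \mu + \phi\mu^2$ (default $\phi = 0.05$, a
typical replicate-level RNA-seq dispersion), group means
$2^{\text{baseline} + \text{effect}}$, and per-library depth factors drawn
log-uniformly in [0.5×, 2×] to exercise CPM normalisation. Effects default
to zero (null transcripts); a correlated module option adds a shared 6-point
latent profile so profile correlations have known positives. What the
generator does *not* emulate: GC-content biases, transcript-length effects,
correlated transcripts outside the declared module, and outlier libraries —
so a green recovery test establishes correctness of the estimators under the
stated model, not robustness to those artefacts.

In the FDR validation scenario the non-null effects are few (2% of
transcripts) and balanced in sign. This is the standard global-normalisation
assumption: CPM (like any total-count normalisation) is only valid when DE
transcripts do not move library totals materially; heavily unbalanced DE
shifts all null CPMs and inflates the error rate, which is a property of
total-count normalisation rather than of the testing procedure.

## Numerical choices and degenerate inputs

* Times are snapped to exact multiples of the check interval on load, so
  hour-binning never drifts across a boundary from float error; binning uses
  a 1e-9 guard on window edges.
* Fisher point-probability comparison uses a 1e-7 *relative* tolerance.
* Welch rows with zero variance in both groups get p = 1 when the means are
  equal and p = 0 otherwise.
* |r| = 1 correlations are clamped so p-values stay in (0, 1].
* A bootstrap over single-strain data returns the degenerate interval [1, 1]
  rather than an error; no matings at all is a computation error.
* The rank-sum exact path refuses tied data rather than silently switching
  conventions.

## Open design points resolved here

* **W convention**: published rank statistics do not say which sample was
  "first" nor whether W or U was reported; both are returned and tests
  compare p-values only.
* **Last-check boundary**: the 7-h recording period is taken to end exactly
  at the 21st check; a mating at 7.0 h belongs to window 7.
* **Correlation input**: profile correlations use CPM means; published
  normalised counts used additional GC/depth offsets that cannot be
  reproduced without the raw reads, so numerical agreement of r values is
  not claimed (only the r-to-p transform is).

## Limitations

The RI index conflates timing and abundance asymmetries (see above); the
expression p-values are a documented surrogate, not a count-model fit; the
published RI values (0.393 contemporary, 0.525 historical) and DE counts are
not re-derivable without the underlying per-hour counts and raw reads, so
the test suite validates those code paths against independent oracles and
simulated ground truth instead.
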