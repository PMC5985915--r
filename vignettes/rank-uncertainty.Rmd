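---
title: "Monte Carlo uncertainty for state league tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo uncertainty for state league tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(staterank)
```

## The problem

Public-health surveillance routinely ranks states on estimated behavior
prevalence. A rank, however, is a highly nonlinear function of all states'
estimates at once: small sampling errors in many estimates reshuffle the
middle of the table substantially, so a printed rank without an uncertainty
measure overstates what the data can distinguish. `staterank` treats the
rank vector as a random quantity and reports, per state, a median rank with
a 95% confidence interval obtained by simulation.

## The model

The input is one row per state: an estimated prevalence $\hat p_i$ and its
standard error $SE_i$, both on the percent scale, as published tables print
them (this package stores them at printed precision and never attempts to
reconstruct unrounded values). The engine assumes the estimates are
independent across states — appropriate when each state's estimate comes
from its own survey sample — and simulates

$$x_i^{(s)} \sim N(\hat p_i,\, SE_i^2), \qquad s = 1, \dots, n_{sims},$$

ranking each replicate row so that rank 1 is the **highest** prevalence
(worst performance; the fixed convention of the packaged tables). The
default $n_{sims} = 100{,}000$; summaries warn below 1,000. Each state's
point estimate is the **lower median** of its simulated ranks — the
$\lceil n_{sims}/2 \rceil$-th order statistic — which is always an integer
and always lies inside the reported interval. Raw (deterministic) ranks can
in principle fall outside a simulated CI; median ranks cannot. Median ranks
may tie and need not form a permutation.

### Confidence intervals

Two interval modes:

* **individual** (default): the 2.5th and 97.5th percentiles of each
  state's own rank distribution, taken as order statistics at
  $\lceil q \, n \rceil$ with no interpolation (ranks are integers;
  interpolating would fabricate non-integer bounds).
* **simultaneous**: per-state tail probability $\gamma$ is decreased from
  the nominal $1 - \text{ci\_level}$ along a fixed grid until the product
  set of per-state intervals $[Q_i(\gamma/2), Q_i(1-\gamma/2)]$ contains
  *every* state's rank jointly in at least 95% of simulation rows. Joint
  coverage is counted directly on the realized rows, so the guarantee is
  exact for the simulation, and the simultaneous interval is a superset of
  the individual one by construction. If the grid is exhausted (degenerate
  inputs), full-range intervals are returned with a warning.

The published rankings this package reproduces describe their intervals as
simultaneous but cite an external method without parameters. We default to
individual percentile intervals and surface the choice as `mode=`: the two
modes agree for extreme-rank states (which is where reproduction is
checked), while middle-rank interval endpoints can shift by a few positions
between modes. Middle ranks are therefore deliberately not reproduction
targets.

### Distributional alternatives

Three alternative sampling laws probe sensitivity to the normal assumption,
each matched to $(\hat p_i, SE_i)$:

* *truncated normal*: the same law truncated to $[0, 100]$, drawn by
  inverse CDF;
* *binomial*: $100\,X/\tilde n_i$ with
  $X \sim \mathrm{Bin}(\tilde n_i, \hat p_i / 100)$ and effective size
  $\tilde n_i = p(1-p)/SE^2$ (proportion scale) rounded to the nearest
  integer, floor 1 — the binomial size whose sampling SE matches the
  reported one;
* *lognormal*: parameters solved so the mean is $\hat p_i$ and the SD
  $SE_i$ (moment matching; the parameterization is a package choice, as is
  moment matching itself).

On the packaged cigarette table, median ranks under each alternative stay
within 2 positions of the normal ones for over 90% of states (asserted in
the test suite), supporting the default.

### Numerical conventions

Ties within a simulated row (possible under the binomial law, measure-zero
under continuous laws) are broken by input column order. A single seed
drives the whole replicate matrix through one generator stream, so any
published output is exactly reproducible from `(table, sim_config)`. States
with $SE = 0$ produce constant columns under every law, and the $SE \to 0$
limit recovers the deterministic ranking with degenerate intervals exactly.

## Design-based estimation

When respondent-level microdata are available (state, stratum, PSU, weight,
binary outcome), `weighted_prevalence()` computes the ratio estimator
$100 \sum w_i y_i / \sum w_i$ and `taylor_se()` its Taylor-series
linearization SE: residuals $z_i = w_i (y_i - p) / W$ are totaled within
PSU and the variance is the stratified between-PSU sum
$\sum_h \frac{n_h}{n_h - 1} \sum_k (z_{hk} - \bar z_h)^2$, treating the
first stage as sampled with replacement (no finite-population correction,
the standard public-use convention). Singleton strata are a hard error —
silently centering them at the overall mean would mask generator bugs.
States are estimated independently; there is no pooling or small-area
smoothing, because the ranking method ranks direct estimates. In the
single-stage, equal-weight limit the SE reduces algebraically to
$100\sqrt{p(1-p)/(n-1)}$, and on clustered designs it agrees with an
independent delete-one-PSU jackknife within 10% (both asserted in tests).

## Consistency analysis

Rank agreement between two tables uses Spearman correlation computed as the
Pearson correlation of **midranks**: published median-rank columns contain
many ties (three states share rank 6 in the packaged cigarette table), and
the classical $1 - 6\sum d^2 / (n(n^2-1))$ formula is invalid under ties.
On tie-free data the two coincide (verified exhaustively for all
permutations up to $n = 6$). P-values use the t approximation on $n - 2$
degrees of freedom; with 46–51 states an exact permutation p adds nothing
at the precision reported. Systematic prevalence differences between
surveys use a paired t test with Bonferroni adjustment, defaulting to
$m = 3$ (one comparison per behavior). Within-survey cross-behavior
correlations are computed both on the states shared by the two surveys and
on all states the survey covers — the appropriate state set is genuinely
ambiguous, so `run_paper()` emits both.

## What the synthetic generators emulate

`generate_estimate_table()` draws true prevalences **uniformly** on a
requested range (default 4–27%, the marginal spread of the packaged
tables) with SEs uniform on 0.4–2.4%, then adds truncated-normal
observation noise. Uniform truth is deliberate: coverage of a method that
assumes normal sampling noise should not be certified only under a normal
truth model. `generate_microdata()` builds stratified two-stage cluster
samples with PSU random effects on the logit scale, variance calibrated to
a latent-scale intra-cluster correlation
($\sigma_u^2 = \mathrm{icc}\,\pi^2/3\,(1-\mathrm{icc})^{-1}$) and the
intercept solved by Gauss–Hermite quadrature so the marginal prevalence
equals the requested truth exactly; weights are lognormal with a requested
CV, normalized within state. `make_paper_like_world()` couples two
surveys' truths through a Gaussian copula (default correlation 0.8) with a
51-state survey A and a 47-state survey B whose prevalences are shifted
upward, mimicking the school-based survey's systematically higher
estimates.

What these generators do **not** emulate: real sampling frames,
nonresponse and post-stratification weighting, cross-year design changes,
reporting bias that varies by state, or correlated estimation error across
behaviors measured on the same respondents. Passing coverage tests on
synthetic worlds therefore certifies the *rank-CI machinery* — not that
any real survey's published SEs capture all error sources.

## Problem sizes used in the test suite

Reproduction checks run the full 100,000-simulation configuration on the
packaged tables across five seeds. Property checks use scaled sizes chosen
for stable verdicts at interactive cost: 200 synthetic 51-state worlds at
2,000 simulations each for individual-interval coverage (≥ 92% observed
against a 95% nominal level, the margin allowing for simulation noise);
5,000 rows for joint-coverage counting; 20–50 seeds for recovery and null
calibration of cross-survey correlations at 1,000 simulations per table.

## Documented discrepancies and limitations

* Recomputing the in-text median prevalence from the printed one-decimal
  columns gives 9.2% where the source text reports 9.3% for
  household-survey cigarette smoking: the published medians evidently used
  unrounded estimates. In-text medians are therefore documented, not
  reproduced.
* The source's abstract and results sections disagree slightly on the
  cross-survey correlations (0.66/0.64, 0.38/0.36, 0.70/0.69), plausibly
  raw-rank versus median-rank inputs; this package's checks target the
  results-section values and the printed rank columns.
* One printed table contains apparent transcription quirks (two states
  sharing rank 47 at identical prevalence); fixtures transcribe the table
  verbatim and ties are tolerated everywhere.
* Estimates are treated as independent across states and as exactly
  normal at the printed SE; neither assumption is testable from the
  printed tables alone.
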