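# staterank

Ranking geographic units on survey-estimated prevalence — "league tables" of
states by adolescent smoking, binge drinking, or marijuana use — is easy to
do and easy to over-interpret: a raw rank carries no measure of its own
uncertainty, and states in the middle of a distribution are usually
statistically indistinguishable. `staterank` implements the statistical
machinery for honest state rankings:

- **Monte Carlo rank distributions.** Given one prevalence estimate
  `p_i` (%) and standard error `SE_i` (%) per state, draw
  `x_i^(s) ~ N(p_i, SE_i^2)` independently across states for
  `s = 1, ..., 100000` replicates (truncated-normal, binomial at the
  effective sample size `p(1-p)/SE^2`, and moment-matched lognormal laws are
  available as robustness checks), rank every replicate jointly
  (rank 1 = highest prevalence), and summarize each state by its **median
  rank** with a **95% rank confidence interval** — either per-state
  percentile intervals or simultaneous intervals widened until they jointly
  cover all states' ranks in ≥ 95% of replicates.
- **Design-based estimation.** Weighted prevalence and Taylor-series
  linearization standard errors from stratified, clustered, weighted
  microdata (with-replacement first stage; linearized ratio residuals
  totaled by PSU, variance from between-PSU variation within strata).
- **Rank consistency.** Tie-corrected (midrank) Spearman correlations
  between rank tables, and paired t tests with Bonferroni adjustment for
  systematic prevalence differences between surveys.
- **Synthetic data with known truth.** Generators for estimate tables with
  known true ranks and for stratified-cluster microdata with known
  prevalence and intra-cluster correlation, so rank-CI coverage and
  estimator calibration are testable without restricted survey microdata.

Six packaged tables ship with the package: state-level past-month cigarette,
binge-alcohol, and marijuana prevalence among adolescents aged 14–17
(2011–2015) from two national surveillance systems — NSDUH (51
jurisdictions, household-based) and YRBSS (47 states, school-based; 46 for
marijuana).

## Worked example

```r
library(staterank)

tab <- load_packaged_table("NSDUH", "cigarette")   # 51 states, % and SE
rt  <- rank_states(tab, sim_config(n_sims = 100000, seed = 1))
rt
#> <rank_table> 51 states (normal draws, n_sims=100000, individual CIs)
#>            state prevalence_pct se_pct median_rank ci_low ci_high
#> 51       Wyoming           14.3    1.3           1      1       7
#> 27       Montana           13.0    1.3           3      1      14
#> 49 West Virginia           12.6    1.3           4      1      17
#> 18      Kentucky           12.2    1.2           6      1      19
#> 26      Missouri           12.2    1.2           6      1      19
#> ...
```

Wyoming has the highest estimated adolescent smoking prevalence and is
median-ranked 1, but its 95% rank CI (1–7) shows the top rank is not
statistically exclusive; Kentucky and Missouri print the same median rank 6
(ties are expected — median ranks need not form a permutation). Utah sits at
rank 51 with CI 47–51.

Cross-survey consistency of the published ranks, and the systematic
difference in prevalence between the school-based and household surveys:

```r
m <- align_states(load_packaged_table("NSDUH", "cigarette"),
                  load_packaged_table("YRBSS", "cigarette"))  # 47 shared states
spearman_ranks(m$printed_rank.a, m$printed_rank.b)
#> Spearman rho = 0.633 (n = 47 states, P = 1.79e-06)
paired_t(m$prevalence_pct.a, m$prevalence_pct.b, m_comparisons = 3)
#> Paired t: mean diff = 3.45, t(46) = 10.99, p = 1.86e-14 (Bonferroni x3: 5.59e-14)
```

So state ranks agree only moderately across the two surveillance systems
(rho ≈ 0.63), while the school-based survey reports systematically higher
smoking prevalence (+3.5 percentage points on average across the 47 shared
states).

The whole analysis — six rank tables, figure data, all consistency
correlations and paired tests — runs in one call (or via the thin CLI at
`inst/cli/staterank.R`):

```r
run_paper("out/", seed = 1, n_sims = 100000)
```

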