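# mrgrid

Two-sample Mendelian randomization (MR) from GWAS summary statistics,
for epidemiologists screening many exposure–outcome pairs at once.
Given per-variant association estimates for an exposure and an outcome
from non-overlapping cohorts, `mrgrid` selects genetic instruments,
harmonizes alleles, estimates the causal effect by the three standard
methods, runs heterogeneity and pleiotropy diagnostics, and applies
grid-level decision rules with Bonferroni control. A synthetic
summary-statistics generator with known causal truth makes every stage
testable without external downloads.

## The statistics

For instrument *j* with exposure effect β<sub>Xj</sub> (SE
σ<sub>Xj</sub>) and outcome effect β<sub>Yj</sub> (SE σ<sub>Yj</sub>):

* **Wald ratio** θ̂<sub>j</sub> = β<sub>Yj</sub>/β<sub>Xj</sub>, SE
  σ<sub>Yj</sub>/|β<sub>Xj</sub>|.
* **IVW** θ̂ = Σ w<sub>j</sub> β<sub>Xj</sub>β<sub>Yj</sub> / Σ
  w<sub>j</sub> β<sub>Xj</sub>², w<sub>j</sub> = σ<sub>Yj</sub>⁻² —
  the zero-intercept weighted regression of β<sub>Y</sub> on
  β<sub>X</sub>; fixed-effect SE (Σ w<sub>j</sub>β<sub>Xj</sub>²)^−1/2,
  multiplicative random-effects SE inflated by max(1, √(Q/(J−1))).
* **MR-Egger** — the same regression with a free intercept (pairs
  oriented so β<sub>Xj</sub> ≥ 0); the intercept measures directional
  pleiotropy, the slope is the adjusted effect; t inference on J−2 df.
* **Weighted median** — the weighted 50% point of the ordered Wald
  ratios; SE by seeded parametric bootstrap.
* **Diagnostics** — Cochran's Q (weights β<sub>Xj</sub>²/σ<sub>Yj</sub>²,
  χ²<sub>J−1</sub>), the Egger intercept t-test, and the MR-PRESSO
  global test (leave-one-out weighted RSS against a parametric null;
  Monte-Carlo p with floor 1/(n_sim+1)).

Instrument selection applies, in order: exposure p < 1e-5 (strict),
greedy LD clumping (r² ≥ 0.001 removed within ±10 Mb), proxy
substitution (r² > 0.8) for instruments missing from the outcome,
per-variant F = (β/σ)² ≥ 10, and confounder pruning against an
annotation table. Decision rules: a pair is *nominally significant*
when the IVW p < 0.05 **and** IVW, weighted median and Egger slope
agree in sign; *family-wise significant* when p is also below
α/n (Bonferroni over the grid, family size overridable).

## Worked example

```r
library(mrgrid)

truth <- synthetic_truth(theta = 0.25, J = 40, n_null_snps = 160,
                         pleiotropy = pleiotropy_law("balanced", sigma = 0.01),
                         seed = 2024)
sim  <- simulate_pair(truth)
inst <- select_instruments(sim$exposure, sim$outcome, config = mr_config(seed = 7))
inst
#> <instrument_set> simulated_exposure: 40 instruments
#>   audit: input=200 post_p_filter=40 post_clump=40 post_proxy=40 post_f=40 post_confounder=40

h <- harmonize(inst, sim$outcome)
h
#> <harmonized_set> simulated_exposure -> simulated_outcome: 39 pairs (1 dropped)

est <- run_all_methods(h, mr_config(seed = 7))
est[, c("method", "theta", "se", "ci_low", "ci_high", "pval", "n_snps")]
#>            method   theta      se  ci_low ci_high     pval n_snps
#> 1       ivw_fixed 0.22386 0.01270  0.1990  0.2488 1.69e-69     39
#> 2          ivw_re 0.22386 0.01817  0.1883  0.2595 6.80e-35     39
#> 3 weighted_median 0.22922 0.02090  0.1883  0.2702 5.34e-28     39
#> 4     egger_slope 0.21919 0.03558  0.1471  0.2913 3.81e-07     39
#> 5 egger_intercept 0.00101 0.00658 -0.0123  0.0143 8.79e-01     39

sensitivity_report(h, mr_config(seed = 7))
#> <sensitivity_report> Q=77.7 (p=0.0001532); Egger intercept=0.001009 (p=0.8789);
#>   MR-PRESSO global p=0.0004998 (n_sim=2000)
```

Reading the output: 200 simulated variants enter; 40 pass the p-value
filter (the 40 true instruments), none are lost to clumping, proxies,
the F screen or confounder pruning; one palindromic variant with an
ambiguous allele frequency is dropped at harmonization, leaving 39
pairs. All three estimators agree in direction and magnitude
(θ̂ ≈ 0.22–0.23 against a true effect of 0.25, within their standard
errors). The balanced per-variant pleiotropy injected by the generator
is real extra-sampling heterogeneity: Cochran's Q and the MR-PRESSO
global test both detect it (small p), the random-effects IVW widens its
SE accordingly (0.018 vs 0.013), and the Egger intercept — which tests
*directional* pleiotropy — is correctly null (p = 0.88).

For a grid screen over several exposures and outcomes, see
`run_grid()`; `write_results()` serializes the grid to a 13-column TSV
mirroring published main-result + sensitivity tables.

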