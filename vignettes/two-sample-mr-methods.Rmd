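---
title: "Methods: two-sample Mendelian randomization with mrgrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization with mrgrid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgrid)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect
$\theta$ of an exposure on an outcome from GWAS summary statistics of two
non-overlapping cohorts. For each genetic variant $j$ used as an
instrument, let $\hat\beta_{Xj}$ (SE $\sigma_{Xj}$) be its association
with the exposure and $\hat\beta_{Yj}$ (SE $\sigma_{Yj}$) its association
with the outcome. Under the instrumental-variable assumptions (the
variant is associated with the exposure, independent of confounders, and
affects the outcome only through the exposure), each variant gives a Wald
ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order
standard error $\sigma_{Yj}/|\hat\beta_{Xj}|$.

`mrgrid` implements the three standard combiners:

* **IVW** — inverse-variance weighted meta-analysis of the Wald ratios,
  algebraically the zero-intercept weighted regression of
  $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with weights $\sigma_{Yj}^{-2}$.
  It is efficient when every instrument is valid. The fixed-effect
  standard error is $(\sum_j w_j \hat\beta_{Xj}^2)^{-1/2}$; the
  multiplicative random-effects variant inflates it by
  $\max(1, \sqrt{Q/(J-1)})$, where $Q$ is Cochran's statistic. Both are
  always reported; inference is normal-based.
* **MR-Egger** — the same weighted regression with a free intercept,
  after orienting every pair so $\hat\beta_{Xj} \ge 0$. The intercept
  estimates the average directional pleiotropic effect; the slope remains
  consistent for $\theta$ under the InSIDE assumption (direct effects
  independent of instrument strength). Coefficient standard errors are
  rescaled by $\max(1, \hat\sigma)$ and tested on $t_{J-2}$, reflecting
  the extra estimated intercept at small $J$.
* **Weighted median** — the 50% point of the Wald ratios under
  inverse-variance weights, interpolated across the centred cumulative
  weights; consistent while variants carrying less than half the weight
  are invalid. Its only stochastic component is the parametric bootstrap
  for the standard error (both effect sides redrawn from normals with
  their reported SEs), which is why a seed is mandatory there.

Diagnostics: Cochran's $Q$ with weights
$\hat\beta_{Xj}^2/\sigma_{Yj}^2$ (first-order, matching the Wald-ratio
SE convention) against $\chi^2_{J-1}$; the Egger intercept $t$-test; and
the MR-PRESSO global test, which compares the observed leave-one-out
weighted residual sum of squares to a parametric simulation of the
no-pleiotropy model and returns the Monte-Carlo p-value
$(1 + \#\{RSS^* \ge RSS_{obs}\})/(n_{sim}+1)$, with attainable floor
$1/(n_{sim}+1)$.

## Instrument selection

`select_instruments()` composes four screens in a fixed order, recording
attrition counts after each:

1. **p-value filter** — keep variants with exposure $p <$ `p_threshold`
   (strict). The default `1e-5` is the relaxed threshold used when few
   variants reach $5\times10^{-8}$.
2. **LD clumping** — greedy: repeatedly take the remaining variant with
   the smallest p (variant id as tie-break, making the result
   independent of input order) and remove neighbours on the same
   chromosome within `clump_window_bp` (default $\pm$10 Mb) with
   $r^2 \ge$ `clump_r2` (default 0.001; retained pairs therefore satisfy
   $r^2 < 0.001$, removal being the complement of the stated retention
   rule). Variants absent from the LD reference are kept as independent
   and flagged — this mirrors reference-panel dropout and keeps the
   operation total.
3. **Proxy substitution** — a selected instrument missing from the
   outcome dataset is replaced by the outcome variant in highest LD with
   it, provided $r^2 >$ `proxy_r2` (default 0.8, strict). The proxy's own
   records from both datasets are used; nothing is imputed. Ties go to
   the smaller exposure p, then lexicographic id.
4. **Instrument strength** — per-variant
   $F = (\hat\beta_X/\sigma_X)^2$, the squared Wald z-score (the
   single-variant approximation consistent with reporting a per-SNP
   range); keep $F \ge 10$.
5. **Confounder pruning** — a variant is removed iff it carries an
   annotation (an offline stand-in for a PhenoScanner lookup) in a
   configured category with $p <$ `confounder_p_threshold`. No
   conventional threshold is universal here; the default is genome-wide
   $5\times10^{-8}$ and both stricter and laxer policies are expressible
   through configuration, including removing no categories at all.

Boundary semantics throughout are deliberate and tested: strict `<` for
p-values and proxy LD, `>=` for the F screen and clump removal.

## Harmonization

`harmonize()` aligns outcome records to the exposure's effect allele.
Matching labels pass through; swapped labels negate $\hat\beta_Y$ and
complement the allele frequency; if neither comparison succeeds the
outcome alleles are strand-flipped (complemented) and compared again —
attempting the complement only after direct comparisons fail minimizes
spurious matches. Palindromic variants (A/T, C/G) cannot be resolved by
labels: they are aligned by allele-frequency agreement when both
frequencies fall outside the ambiguity window, and dropped otherwise.
The window defaults to (0.42, 0.58), the conventional default of the
standard MR tooling, and a drop-all-palindromes policy is available.
Missing frequency on either side drops a palindrome (no way to
disambiguate) while non-palindromes proceed. Every shared variant ends
in exactly one of five statuses, so kept plus dropped always equals the
intersection size; flipping is an involution, and estimates are
invariant to which dataset's labelling is taken as reference.

## Grid screening

`run_grid()` runs selection, harmonization, estimation and diagnostics
for every exposure-by-outcome pair, then applies two decision rules:
*nominal* significance requires the headline IVW $p < 0.05$ **and**
sign-agreement of IVW, weighted median and Egger slope (none exactly
zero); *family-wise* significance replaces 0.05 by the Bonferroni
threshold $\alpha/n$. The family size defaults to the realized number of
pairs and can be overridden (e.g. to mirror a published family of 468
tests whose exact trait composition cannot be reconstructed); the
override changes only the flags, never an estimate. Each pair derives
its seed from the master seed and the pair's names, so results are
independent of execution order, and per-pair failures become structured
null rows that preserve the grid shape.

The headline IVW defaults to the multiplicative random-effects variant —
conservative when heterogeneity is present and identical to fixed
effects otherwise (the inflation factor is floored at 1); the
fixed-effect row is always emitted alongside since published reports
rarely state which was used.

## The synthetic-data generator

`simulate_pair()` draws, per instrument, a true exposure effect
$\gamma_j = |N(0, 0.15^2)|$ truncated below at 0.06 (effect alleles
oriented to increase the exposure, the usual GWAS reporting convention),
a direct effect $\alpha_j$ from the configured pleiotropy law, the true
outcome effect $\Gamma_j = \theta\gamma_j + \alpha_j$, and observed
effects $\hat\beta_X \sim N(\gamma_j, \sigma_{Xj}^2)$,
$\hat\beta_Y \sim N(\Gamma_j, \sigma_{Yj}^2)$ with independent noise on
the two sides (the two-sample design). Default SE ranges —
$\sigma_X \sim U(0.003, 0.012)$, $\sigma_Y \sim U(0.01, 0.02)$ — were
chosen once so that per-variant $F$ spans roughly 25 to 20,000, the
order of magnitude reported for real COVID-19 GWAS instruments, keeping
the $F \ge 10$ screen non-trivial. Background null variants have
$\gamma = \alpha = 0$. Positions are laid out 20 Mb apart so only
declared LD-block mates (5 kb spacing, configurable within-block $r^2$)
fall inside the default clumping window. A configurable fraction
(default 10%) of variants receives palindromic allele pairs to exercise
harmonization. All randomness flows from the single truth seed;
identical truths produce bitwise-identical datasets.

`scenario_suite()` packages the canonical validity conditions — null,
causal, balanced pleiotropy, directional pleiotropy (InSIDE holds),
InSIDE-violated ($\alpha_j$ correlated with $\gamma_j$), and 30%/60%
contamination. Under 60% invalid instruments the weighted-median
consistency condition is void, which is documented rather than asserted.

What the generator does **not** emulate: realistic human LD maps,
winner's-curse selection of instruments, sample overlap between the two
GWAS, allele-frequency-dependent effect sizes, or population
stratification. Passing recovery and calibration tests therefore shows
the estimators implement their defining formulas correctly under the
stated model — not that real-data analyses are free of these upstream
artifacts.

## Numerical choices and degenerate inputs

* CI identity `ci = theta -/+ q * se` holds exactly for every emitted
  estimate (normal $q$, or $t_{J-2}$ for Egger).
* Simulated p-values are floored at $10^{-300}$ so very strong
  instruments still satisfy the record invariant $p \in (0, 1]$; stored
  SEs are floored at $10^{-12}$ so noise-free (SE = 0) study designs
  remain representable while the observed effects equal their true
  values exactly.
* Exact-fit MR-Egger inputs (zero residuals) are legitimate: the
  residual scaling factor is floored at 1, so the intercept test returns
  $p = 1$ rather than a 0/0.
* A single harmonized pair degrades IVW to the Wald ratio; fewer than 3
  pairs mark the median/Egger rows "not computed"; fewer than 4 skip
  the MR-PRESSO test — all as structured results, not errors.
* Ties in clumping and proxy search break by p then variant id;
  determinism everywhere is by construction (derived seeds), not by
  shared global RNG state.

## Problem sizes used in the checks

The packaged statistical checks use 1000 replicates at $J = 30$ for
type-I error (nominal 5% band 3–7%), 500 replicates at $J = 100$ for
recovery of $\theta = 0.1$, 500 replicates for the pleiotropy
robustness orderings, 200 repeated datasets for the uniformity of the
MR-PRESSO null p-value (1000 simulations for single worked examples,
500 within the repeated-dataset study), and a 2×3 grid for end-to-end
determinism. These sizes give Monte-Carlo error comfortably below the
asserted margins while keeping a full run in the low minutes on a single
core.

## Known limitations

The per-variant F statistic is the single-SNP approximation, not the
multi-instrument regression F. The Wald-ratio SE is first-order by
default (`second_order = TRUE` available). MR-PRESSO outlier removal and
distortion testing, Steiger directionality filtering, I²/Rucker model
selection, multivariable MR and mode-based estimators are out of scope.
LD information must be supplied by the user (matrix or long pairwise
format); the package performs no genotype-panel computation.
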