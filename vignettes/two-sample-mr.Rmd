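---
title: "Two-sample Mendelian randomization with mrwald"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrwald}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrwald)
```

## The model

Mendelian randomization (MR) estimates the causal effect of an exposure
on an outcome by using genetic variants as instrumental variables. A
valid instrument must (i) be robustly associated with the exposure,
(ii) be independent of confounders of the exposure-outcome
relationship, and (iii) affect the outcome only through the exposure
(no horizontal pleiotropy). In the two-sample design, the SNP-exposure
associations $\hat\gamma_j \pm \sigma_{X_j}$ and SNP-outcome
associations $\hat\Gamma_j \pm \sigma_{Y_j}$ come from two separate
GWAS, so the whole analysis runs on published summary statistics.

Each variant supplies a Wald ratio
$\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard
error $\sigma_{Y_j}/|\hat\gamma_j|$ (the exposure-side uncertainty is
ignored; see *Numerical choices*). The package combines the ratios
three ways:

* **IVW** — the inverse-variance-weighted mean of the ratios,
  equivalently the slope of a weighted through-origin regression of
  $\hat\Gamma$ on $\hat\gamma$ with weights $1/\sigma_{Y}^2$. The
  fixed-effect SE is $\sqrt{1/\sum w_j}$; the default multiplicative
  random-effects (MRE) SE inflates it by the residual scale
  $\max(1, \hat s)$, so heterogeneity widens but never narrows the
  interval. `cochran_q()` reports the matching heterogeneity statistic
  ($Q/(J-1) = \hat s^2$).
* **Weighted median** — the weighted 50% quantile of the ordered
  ratios, consistent while less than half the total weight comes from
  invalid instruments; its SE is a seeded parametric bootstrap.
* **MR-Egger** — weighted least squares of $\hat\Gamma$ on
  $\hat\gamma$ with a free intercept after orienting every variant so
  $\hat\gamma_j \ge 0$. The intercept estimates average directional
  pleiotropy (valid instruments must pass through the origin); the
  slope estimates the causal effect under the InSIDE assumption that
  direct effects are uncorrelated with instrument strength.

The bundled worked example is the published analysis of serum
25-hydroxyvitamin D (25(OH)D, standardized natural-log scale) on three
dental-caries outcomes; its instrument and outcome tables ship as
verbatim fixtures (`vitd_exposure()`, `caries_outcome()`), frozen by a
checksum test.

```{r example}
dat <- harmonize(vitd_exposure(), caries_outcome("primary"),
                 caries_config("primary"))
mr_fit(dat)
```

## Harmonization and the palindrome problem

Both studies must report effects for the same allele. The exposure
record's printed effect allele is the fixed reference; an outcome
record reported for the other allele has its beta negated and its
frequency complemented, and strand-complement matching (A-T, C-G) is
attempted before an allele pair is declared incompatible. Flipping is
involutive, and every estimator is invariant to the reference choice,
so the convention is arbitrary but harmless.

Palindromic variants (allele pairs A/T or C/G) are the hard case: the
allele letters cannot distinguish a strand flip from a true effect
reversal. Three policies are available per outcome:

* `assume-forward` — align by letter and keep the variant (both
  studies are trusted to report the forward strand);
* `infer-by-frequency` — infer the strand by comparing effect-allele
  frequencies (opposite sides of 0.5 implies opposite strands), then
  exclude the variant as ambiguous when the *exposure-study* frequency
  lies inside the open window `(ambiguity_low, ambiguity_high)`,
  default `(0.39, 0.61)`, where the inference is unreliable;
* `drop-all` — exclude every palindromic variant.

Two design choices here were genuinely open. First, the ambiguity
window is judged on the exposure-study frequency alone: the exposure
GWAS (n = 443,734) estimates allele frequency far more precisely than
the outcome meta-analyses, whose per-variant frequencies drift with
cohort composition (several fixture rows show exposure/outcome
frequency discrepancies of 0.1-0.25 for this reason), and an
either-study rule would let that drift, not strand ambiguity, drive
exclusions — on the fixtures it would discard a third variant
(rs7650253) whose exposure frequency (0.690) is nowhere near ambiguous.
Second, the window default is (0.39, 0.61) rather than the common
(0.42, 0.58): with the wider window the frequency filter reproduces
exactly the two exclusions of the reference analysis (exposure
frequencies 0.605 and 0.410) while the next-nearest palindromic
frequencies (0.647, 0.320) stay safely outside. Both bounds are
ordinary configuration fields.

The reference analysis kept intermediate-frequency palindromes for the
two paediatric outcomes yet removed them for DMFS; no single rule
reproduces both, so `caries_config()` encodes the policy per outcome
(`assume-forward` for paediatric, `infer-by-frequency` for DMFS) rather
than guessing an intent. With these settings the fixtures yield the
published 79/79/78 instrument counts, with an exclusion audit trail
(`exclusion_report()`) accounting for every input row.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `selection` p-value | 5e-8 | genome-wide significance for instrument selection |
| MAF threshold | 0.05 | minimum minor-allele frequency |
| proxy r² | 0.7 | minimum LD for proxy substitution (boundary inclusive) |
| ambiguity window | (0.39, 0.61) | open frequency window for palindrome exclusion |
| `dmfs_scale_factor` | 19.87 | tooth surfaces per 1 SD of the standardized DMFS score, from an external reference population |
| `wm_bootstrap_reps` | 1000 | weighted-median bootstrap replicates |
| IVW variant | `mre` | multiplicative random effects, residual scale floored at 1 |

Binary-outcome estimates are log odds ratios per SD of ln-25(OH)D and
are reported as `OR = exp(beta)` with CI `exp(beta ± 1.96 SE)`
(`to_odds_ratio()`). Some published tables instead print
`exp(beta) ± 1.96 SE`; a `legacy-additive` CI mode reproduces that
layout for comparison but is not the default, because it is not an
interval for the OR on its natural scale. DMFS estimates are multiplied
by `dmfs_scale_factor` (`to_dmfs_surfaces()`). Instrument strength uses
the approximation $R^2_j = 2\hat\gamma_j^2 f_j(1-f_j)$ per variant and
the standard overall F approximation
$\frac{R^2}{1-R^2}\cdot\frac{n-J-1}{J}$; on the fixture panel the 83
variants explain about 4.4% of exposure variance (F well above 10). The
published text is ambiguous about which variant subset the 4.4% sums
over; the package computes it over the full instrument panel, which
matches the printed value.

## Numerical choices

* Wald-ratio SEs use the first-order delta method only; the
  second-order term is omitted deliberately (the conventional default,
  and the simulator quantifies the approximation error, which is
  negligible at fixture-scale instrument strength).
* IVW and weighted-median p-values use a normal reference; Egger uses a
  t reference with $J-2$ df. Egger SEs are scaled by
  $\max(1, \hat s)$ like the MRE IVW.
* A weighted-median breakpoint landing exactly on 0.5 returns that
  ratio without interpolation.
* Variants with `beta_exp == 0` after harmonization are dropped with a
  message, not an error.
* Printed p-values below ~1e-308 underflow double precision and read
  as 0; they are accepted (they trivially pass any selection
  threshold).
* Presentation rounding is half-away-from-zero to 2 decimals, matching
  the published tables; full-precision columns are always emitted
  alongside.
* Reported CIs in result tables use 1.96 exactly (as the published
  formulas do); `confint()` uses `qnorm(0.975)`.

## What the simulator emulates — and what it does not

`simulate_study()` generates summary statistics directly: true
per-variant exposure effects $\gamma_j$ (magnitude log-uniform on
0.012-0.19, the fixture's range; random sign), direct effects
$\alpha_j$ per pleiotropy mode, and observed betas drawn at the
recorded SEs (`se_exp` ~ 0.002-0.004, `se_out` ~ 0.009-0.05, again the
fixture regime; 79 instruments; ~20% palindromic; ~5% missing outcome
rows). Direct effects attach to the exposure-increasing allele, so
directional pleiotropy survives the estimators' reorientation. Outcome
rows are written with randomly swapped allele order so harmonization is
genuinely exercised, and both studies share a strand.

It does **not** simulate individual genotypes, LD between variants,
liability-scale binary traits (outcome effects are drawn directly on
the log-OR scale), or between-cohort frequency drift. A green
calibration test therefore establishes correct behaviour of the
estimators under the stated structural model — not robustness to
correlated instruments or winner's-curse selection, which are out of
scope.

`evaluate_estimators()` summarizes bias, empirical SE, RMSE, coverage
and rejection rates over seeded replicates. Calibration of the nominal
5% IVW test is asserted for the fixed-effect variant: conditional on
the exposure estimates, its z-statistic is exactly standard normal
under the null, while the MRE floor makes the default variant
deliberately conservative (it can only widen the interval), which the
tests check as an inequality.

## Known limitations

* The harmonized paediatric estimates land within 0.01-0.02 (on the
  2-dp OR scale) of the published Table values rather than exactly on
  them; the DMFS column reproduces to all printed digits. The printed
  input tables appear to differ slightly from the data used in the
  original runs (several proxy-substituted rows print discordant
  frequencies), and no tuning is applied to close that gap.
* Proxy discovery, multi-allelic variants, indels, non-linear MR and
  LD-aware (correlated-instrument) IVW are out of scope; a precomputed
  proxy table is consumed as input instead.
* The weighted-median bootstrap draws ratios from
  `Normal(ratio, se_ratio)`; at very weak instruments the true ratio
  distribution is heavier-tailed than normal.
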