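---
title: "Two-sample Mendelian randomization with mrkit: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The design

Mendelian randomization (MR) uses genetic variants as instrumental
variables to ask whether an exposure causally affects an outcome. A
*two-sample* design takes the per-SNP association statistics with the
exposure from one GWAS and with the outcome from another, so the analysis
never touches individual-level data. A variant is a valid instrument when
it is (A) robustly associated with the exposure, (B) independent of
confounders of the exposure–outcome relationship, and (C) associated with
the outcome only through the exposure. `mrkit` operationalizes A as a
strict genome-wide significance filter plus F-statistics, B as
annotation-based confounder exclusion, and C as exclusion of variants
directly associated with the outcome plus the MR-Egger intercept test.

The packaged worked example is an analysis of plasma homocysteine (SD
units, exposure GWAS of N = 44,147) against atrial fibrillation (log-odds,
outcome GWAS of N = 1,030,836 with 60,620 cases), with nine instruments
(`load_fixture_hcy_af()`). The fixture stores the published per-SNP values
verbatim at their printed precision — no extra digits are imputed — because
the package's regression tests reproduce the published results from exactly
those numbers.

## Instrument selection

Selection runs in four audited stages (`select_instruments()`):

1. **Relevance** — keep SNPs with exposure `p < 5e-8`. The inequality is
   strict everywhere a p-value threshold appears.
2. **Independence (LD)** — greedy pruning of pairs with `r² > 0.001`:
   while an offending pair remains, drop the SNP correlated with the most
   other remaining SNPs; break ties by the larger exposure p-value, then by
   the lexicographically larger rsid. The correlation degree is recomputed
   on the shrinking set after each drop. The first two keys are the
   standard practice; the lexicographic final key exists only to make the
   procedure deterministic under exact ties, and which member of a fully
   tied pair survives is scientifically arbitrary.
3. **Confounders** — drop SNPs annotated (PhenoScanner-style table) to a
   user-listed confounder trait at genome-wide significance. Trait matching
   is exact after case-folding; fuzzy matching of free-text trait names is
   deliberately out of scope, so the trait list must use the annotation
   table's own spelling.
4. **Outcome resolution** — pair each surviving SNP with its outcome
   record; substitute the best available proxy with `r² > 0.8` when the SNP
   is absent from the outcome GWAS; exclude SNPs directly associated with
   the outcome at genome-wide significance (an assumption-C violation).

Instrument strength uses the standardized-trait approximation
`r²ⱼ = 2 pⱼ(1−pⱼ) βⱼ²` and `Fⱼ = r²ⱼ (N−2)/(1−r²ⱼ)`, with F ≤ 10 flagged
weak. On the packaged table this reproduces all nine published integer F
values (145 down to 33), which is also the evidence that the published
column was computed with this r² convention.

## Harmonization

Both GWAS must report effects for the same allele.
`harmonize()`/`harmonize_pair()` pass aligned records through, and
sign-flip the outcome beta (complementing its EAF) when the allele pair is
reported in the opposite orientation. Allele pairs that agree in neither
orientation are an error rather than a silent drop. Palindromic SNPs (A/T,
C/G) carry no strand information in their allele labels: inside the
ambiguous frequency window 0.5 ± 0.08 they are dropped under the default
policy; outside it they are oriented by comparing allele frequencies, and
dropped when the outcome EAF is unavailable. The window half-width 0.08 is
the common community default; none of the fixture SNPs is palindromic, so
the worked example is unaffected by this policy.

Each harmonized instrument carries its Wald ratio `βY/βX` with the
first-order delta-method standard error `seY/|βX|` by default. The
second-order form (adding the exposure-uncertainty term) is available via
`harmonize_policy(ratio_se_order = "second")`; first-order is the default
because it is the convention of the standard MR toolchain and is what the
published tables were computed with.

## The estimator suite

All methods operate on the harmonized table and report log-odds per SD,
with normal-quantile CIs and two-sided normal p-values throughout (not t
quantiles — verified to reproduce the published CIs at three decimals).

* **Fixed-effect IVW** — weighted mean of Wald ratios with weights
  `1/se(ratio)²`; `se = 1/√Σw`. Algebraically identical to weighted least
  squares of βY on βX through the origin with weights `1/seY²`, which the
  test suite uses as an independent oracle. Cochran's Q on J−1 df is
  returned as the heterogeneity diagnostic.
* **Random-effects IVW** (multiplicative) — same point estimate; SE scaled
  by `max(1, √(Q/(J−1)))`. Under-dispersed data (as in the worked example,
  Q/df ≈ 0.32) therefore reproduce the fixed-effect row exactly.
* **Maximum likelihood** — maximizes
  `Π N(βXj; γj, seXj²) · N(βYj; θγj, seYj²)` over `(θ, γ₁…γJ)`. The γ
  profile is closed-form, leaving a 1-D optimization in θ initialized at
  the IVW estimate; the SE is the θ-block of the inverse observed
  information (Schur complement), computed analytically. A dense grid
  search is the oracle for small J in the tests.
* **MR-Egger** — weighted regression of βY on βX *with* intercept, weights
  `1/seY²`, after orienting every instrument so βX ≥ 0. The slope is the
  causal estimate under InSiDE; the intercept estimates average directional
  pleiotropy, and `egger_intercept_report()` surfaces it as the pleiotropy
  test. Coefficient SEs carry a multiplicative overdispersion factor
  truncated below at 1, consistent with the random-effects IVW convention.
* **Simple/weighted median** — order the ratios, attach standardized
  weights with the half-step cumulative convention
  `pⱼ = (Σₖ≤ⱼ wₖ − wⱼ/2)/Σw`, and interpolate the 50th percentile
  linearly. Weighted uses `1/se(ratio)²`.
* **Simple/weighted mode** — argmax of a Gaussian-kernel density of the
  ratios with weights as kernel masses; bandwidth
  `h = φ · 0.9 · min(sd, MAD) · J^(−1/5)` with φ = 1 by default, argmax
  located on a 10,000-point grid over `[min − 2h, max + 2h]` (the grid
  discretization error is far below the three-decimal reporting
  precision). If every ratio is identical the bandwidth degenerates and
  that common value is returned.

Median and mode SEs come from a parametric bootstrap: each ratio is
redrawn from `N(ratioⱼ, se(ratioⱼ))` with weights held fixed and the
estimator recomputed; the SE is the SD over `n_boot = 1000` replicates
under a recorded seed (default 42). Same seed, same SE, and the bootstrap
runs on a private RNG stream so it never disturbs the caller's. Published
point estimates for these four methods reproduce exactly or to within one
grid/convention step; their CI and p columns are bootstrap-based and
therefore matched within bootstrap noise, not digit-for-digit.

`estimate_all()` runs all eight methods, sharing one seed, and converts
per-method arity failures (e.g. Egger with two SNPs) into annotated
not-applicable rows instead of aborting the suite.

## Sensitivity diagnostics

`leave_one_out()` re-runs an estimator (fixed-effect IVW by default, the
primary method) on every J−1 subset plus the full set; each row is exactly
reproducible by calling the estimator on that subset directly, which the
tests assert. `single_snp_forest()` emits per-SNP Wald estimates with the
pooled IVW row for forest plots; `funnel_data()` emits (ratio, precision)
pairs with the IVW reference. The funnel symmetry score — a Spearman
correlation between ratio deviations and precisions, defined as 0 in
degenerate cases — is a descriptive statistic only; the corresponding
published assessment is visual, and no asymmetry test is claimed.

## Statistical power

For a binary outcome, `mr_power_binary()` uses the noncentrality
approximation: with `b = log(OR)` under the alternative, total outcome
sample size N, case fraction K and total instrument r²,

power = Φ(√(N·r²·K(1−K))·|b| − z₁₋α/₂) + Φ(−√(N·r²·K(1−K))·|b| − z₁₋α/₂).

Both rejection tails are counted, so the null alternative OR = 1 returns
exactly α and the formula agrees with a Wald-test simulation oracle within
Monte-Carlo error (asserted over a 3×3 grid of OR × r² at 10,000
replicates). Power is monotone in N, r², |log OR|, and in K up to 0.5.
The source analysis names a power-calculator requirement of at least 80%
but prints no achieved value, so the package validates this module against
its own simulation oracle rather than a published number.

## The synthetic-data generator

`simulate_summary_stats()` generates summary statistics directly under the
normal measurement model the estimators assume — summary-level, not
individual-level, generation, which is exact under that model and fast
enough for replicated calibration studies. Per SNP: EAF ~ U(0.05, 0.95);
true exposure effect γⱼ with SD 0.06 (the scale of instruments a
well-powered biomarker GWAS yields; resampled until the implied per-SNP F
at the exposure sample size exceeds 10 unless weak instruments are
requested); exposure SE `1/√(2p(1−p)N)`; pleiotropic effect
αⱼ ~ N(μα, σα²), optionally correlated with γⱼ to break InSiDE; outcome SE
`1/√(2p(1−p)N·K(1−K))` with case fraction K = 0.1 (the order of magnitude
of large binary-outcome GWAS, e.g. ≈ 0.059 in the worked example's outcome
study). Every SNP is reported for its exposure-increasing allele
(γⱼ ≥ 0), the convention of published instrument tables; the pleiotropy
law applies to that oriented allele, which is what makes "mean Egger
intercept recovers μα" a well-posed recovery target under Egger's own
βX ≥ 0 orientation.

Defaults for the calibration studies are J = 50 SNPs, exposure N = 44,147,
outcome N = 100,000, with 500 replicates for type-I-error and
pleiotropy-recovery checks and 100-replicate spot checks elsewhere — sizes
chosen so a full replication study remains a desk-scale computation while
keeping Monte-Carlo error well below the effects being checked.

What the generator does *not* emulate: realistic LD (block LD is available
synthetically via `make_ld_scenario()` for pruning tests, but no reference
panel is used), winner's curse in instrument discovery, sample overlap
between the two GWAS, and non-collapsibility subtleties of odds ratios.
Passing recovery tests therefore demonstrate correctness of the estimators
under their stated model, not robustness to those real-data complications.

## Numerical conventions and degenerate inputs

* All CI/p computations use normal quantiles; all internal comparisons run
  at full double precision, with rounding to three decimals only in report
  layers.
* Strict `<` at every p-threshold; a record at exactly 5e-8 is dropped.
* The ML optimizer brackets θ at IVW ± 20 SE and errors if the optimum
  lands on the boundary rather than returning an untrusted value.
* Zero exposure beta makes a Wald ratio undefined and is an error, not an
  NA.
* LD lookups default missing pairs to r² = 0; conflicting asymmetric
  entries (beyond 1e-9) are an error.
* An empty instrument set fails fast in every estimator with the method's
  arity in the message.

## Known limitations

The fixture's outcome table publishes no per-SNP EAF, so outcome-side
frequency checks (and palindrome resolution) cannot run on it — harmless
here because its alleles are pre-aligned and non-palindromic, but real
analyses should supply outcome EAFs. MR-PRESSO-style outlier removal,
contamination-mixture and multivariable MR, Steiger filtering, and
distance-based clumping are out of scope. The power approximation treats
the instrument set's r² as fixed and known; it inherits the usual optimism
of noncentrality approximations at very small sample sizes.
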