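---
title: "Lactation-curve modelling and casein haplotype association: methods"
author: "caprihap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lactation-curve modelling and casein haplotype association: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprihap)
```

## The problem

Dairy-goat milk recording produces sparse longitudinal data: a handful of
monthly "test-day" controls per lactation, each recording daily milk yield
(kg), component percentages (fat, protein, dry matter, lactose) and somatic
cell count (SCC, in 10^3 cells/mL). Two analysis layers sit on top of such
records:

1. **Lactation-curve modelling** — fit a parametric curve over days in milk
   (DIM) to each lactation and trait, summarize the curve by *peak* and
   *persistency* parameters, and standardize total yield to a fixed horizon
   (210 DIM here, matching breeds whose lactations commonly run 210–240
   days).
2. **Haplotype association** — group animals by the haplotype variants they
   carry across the casein complex on caprine chromosome 6 (CSN1S1, CSN2,
   CSN1S2, CSN3, jointly ~48 SNPs) and test whether trait levels and
   curve-shape parameters differ across variant groups, with both
   frequentist F statistics and Jeffreys–Zellner–Siow (JZS) Bayes factors.

caprihap implements both layers plus a synthetic herd generator, so every
stage is testable end to end without access to raw milk-recording archives
(which are typically not public).

## 210-day standardization

`standardize_210()` uses the Fleischmann-style interval rule. With controls
at DIM $t_1 < \dots < t_m$ (controls past day 210 discarded) and daily
yields $M_i$:

$$Y_{210} = M_1 t_1 + \sum_{i<m} \frac{M_i + M_{i+1}}{2}(t_{i+1}-t_i)
          + M_m(210 - t_m).$$

The first control's yield is carried back to kidding, consecutive controls
are trapezoid-weighted, and the last within-horizon control is carried
forward to day 210. This is the ICAR-endorsed reference computation; breed
associations use operationally equivalent variants. The rule is linear in
the yields, non-negative for non-negative yields, and invariant to records
beyond day 210 — all three properties are tested, and the value itself is
checked against an independent day-by-day midpoint-rule integration of the
same piecewise-linear daily curve. Days in milk are integer date
differences, 1-based on the first day after kidding.

## Curve models and fitting

The registry (`lactation_models()`) ships seven classical models; the two
that matter downstream are

* **Ali–Schaeffer** (milk and components), linear in its five parameters:
  $y(t) = b_0 + b_1 x + b_2 x^2 + b_3 \ln(1/x) + b_4 \ln^2(1/x)$ with
  $x = t/T$. The scaling horizon defaults to $T = 340$ days — the value in
  the model's original formulation — and is configurable; every quantity
  the pipeline extracts (fitted values, RSS, shape parameters as defined
  below) is invariant to $T$ up to the reparameterization, and the tests
  exercise the default only.
* **Parabolic yield-density** (SCC): $y(t) = 1/(b_0 + b_1 t + b_2 t^2)$,
  defined where the denominator is positive.

Also included: Wood, Wilmink (customary fixed decay 0.05/day, making it
linear in parameters), quadratic, inverse quadratic and mixed-log, plus an
extension point (`register_model()`) for user models. The full 49-model
catalogue sometimes used in curve-comparison studies is not reproduced;
the shipped subset covers the families the selection stage needs, and the
pipeline's reproduction mode pins the selected pair (Ali–Schaeffer for
milk/components, parabolic yield-density for SCC) so downstream stages do
not depend on what a small synthetic herd would happen to select.

`fit_lactation()` is multi-start damped least squares
(Levenberg–Marquardt): a small moment-based start grid (mean level,
perturbed slope terms; log-linearized starts for Wood and the reciprocal
models), relative-RSS convergence at $10^{-8}$, at most 2000 iterations,
best-of-starts by RSS. Two numerical choices matter:

* Linear-in-parameter models use their design matrix as the exact
  Jacobian, and every converged fit takes one final undamped Gauss–Newton
  polish step. For linear models this lands exactly on the closed-form
  ordinary-least-squares solution — the suite verifies agreement with an
  independent normal-equations oracle at $10^{-8}$ — and for nonlinear
  models it is a standard cheap refinement.
* A start whose steps can no longer reduce RSS is treated as converged at
  a stationary point; a start whose model evaluation overflows is reported
  `converged = FALSE` rather than raising.

With 5 controls and the 5-parameter Ali–Schaeffer model the fit is an
exact interpolation (RSS 0). That mirrors the data regime of monthly goat
recording and has a visible consequence: per-lactation curve-shape
estimates are extremely noisy, which is exactly why level effects can be
highly significant while shape effects stay null (see below).

## Selection criteria and ranking

`fit_criteria()` computes RSS, MSPE = RSS/n, adjusted $R^2$, and the
least-squares information criteria AIC $= n\ln(\mathrm{RSS}/n) + 2k$,
AICc, BIC (likelihood constants common to all models omitted — rankings
are unaffected), plus Shapiro–Francia normality of residuals (squared
correlation with Blom scores; Royston's approximation for the p-value) and
the Durbin–Watson statistic. Durbin–Watson is intended to be applied to
residuals averaged per day in milk across lactations
(`residuals_by_dim()`), not to raw per-record residuals.

No standard aggregation rule exists for combining these criteria across
models; `select_best()` first drops any candidate below 100% fit success,
then ranks by the sum of ranks over mean MSPE, adjusted $R^2$, AIC, AICc
and BIC, breaking ties by fewer parameters then lexical id. Rank-sum
respects dominance (a model better on every criterion ranks first) and is
invariant to candidate order; both properties are tested. Criteria require
$n \ge k + 2$, so with 5-control lactations the 5-parameter models are
fitted but not ranked — another reason reproduction mode pins the model
pair rather than re-selecting.

## Curve-shape parameters

* Ali–Schaeffer: peak $= b_0$, persistency $= (b_1, b_2)$ — the identity
  on the first three parameters.
* Parabolic yield-density: peak $= -b_1/(2b_2)$ and persistency
  $= 2 b_0 \cdot \mathrm{Days} + b_1$ with Days $= 210$ by default.
  $-b_1/(2b_2)$ is mathematically the *location* (in days) of the curve's
  extremum; the conventional table label "peak yield" is kept without a
  units claim, and whether Days should be 210 or a lactation-specific
  length is genuinely open — both read-ins are isolated in `shape_pyd()`
  so an alternative interpretation is a one-line change.

## Haplotype statistics

Haplotype assignments are inputs (phasing is out of scope): one CSV row
per (animal, phase) with space-delimited allele tokens per locus block.
Tokens are single bases, the deletion token `.-`, or multi-base insertion
tokens such as `AATC`; requiring delimiters avoids the ambiguity of
concatenated display strings in which genotype-style doubled alleles and
indels interleave. `maf()`, `heterozygosity()` and `ld_pair()` implement
the textbook definitions; for LD, with major/minor alleles A/a and B/b,
$D = p_{AB} - p_A p_B$, $D' = |D|/D_{max}$, $r^2 = D^2/(p_A p_a p_B p_b)$,
computed directly from phased chromosomes (no EM frequency estimation,
since phases are given). Variants with MAF $< 0.05$ are flagged rare.

`group_by_haplotype()` enumerates distinct full-complex sequences. How a
*diplotype* maps onto a one-way factor is not standardized; the package
supports both conventions:

* default — an animal's records contribute to the group of each carried
  haplotype (heterozygotes appear in two groups; maximizes data use);
* `homozygous_only = TRUE` — only homozygous carriers, giving disjoint
  groups.

The default double-counts heterozygotes and therefore correlates group
means; the calibration tests use the homozygous-only switch, where the
one-way model's assumptions hold exactly.

## ANOVA, Bayes factor, posteriors

`anova_decompose()` is the definitional one-way decomposition
($SS_B$, $SS_W$, $MS = SS/df$, $F = MS_B/MS_W$, p from the F
distribution), verified against brute-force summation and `stats::lm`.
`f_from_ss()` reproduces published-table arithmetic from printed SS/df.

The JZS Bayes factor (`jzs_bf()`) uses the standard g-prior formulation:
Jeffreys priors on the grand mean and error variance, effects with prior
covariance $g\sigma^2$ times the inverse design moment, and
$g \sim \mathrm{InvGamma}(1/2,\ N r^2/2)$ — jointly a Cauchy prior of
scale $r$ (default 1, the "standard error of 1" convention) on
standardized effects. Conditional on $g$ the marginal-likelihood ratio is
closed-form in $(N, J, R^2)$:

$$BF_{10}(g) = (1+g)^{(N-1-p)/2}\,\bigl[1 + g(1-R^2)\bigr]^{-(N-1)/2},
  \qquad p = J-1,$$

and the $g$ integral is evaluated by deterministic quadrature after the
substitution $g = e^u$ (the integrand vanishes at both tails, so over- and
underflow map safely to zero). The result depends only on $(N, J, R^2)$,
hence is exactly location–scale invariant, monotone in the evidence, and
deterministic; a $10^6$-draw Monte-Carlo average over the prior on $g$,
derived independently through the projection identity
$V_g = I + gP$, agrees within 2% in the acceptance suite. Reference
implementations differ in their default effect scale (e.g. $r = 1/2$ is
also common); with unbalanced groups the covariance convention also
matters, so reproduced Bayes factors should be compared by order of
magnitude, not digit by digit, against other software.

`group_posteriors()` reports, per group, the posterior of the deviation of
the group mean from the *observation-weighted* grand mean
$d_j = \mu_j - \sum_k n_k \mu_k / N$ under the reference prior. This has
an exact Student-t form,
$d_j \mid y \sim \hat d_j + \sqrt{MS_W (1/n_j - 1/N)}\; t_{N-J}$, and a
group is flagged significant when 0 falls outside the central 95%
credible interval. The grand-mean term is part of the contrast on
purpose: the posterior scale then equals the sampling standard deviation
of $\hat d_j$, so under a null simulation the flag fires at the nominal
5% rate. Dropping the $1/N$ term (i.e. treating the grand mean as known)
would make the flag conservative and visibly miscalibrated with few
groups. The interval endpoints are verified against a joint
posterior-sampling oracle ($\sigma^2$ from its scaled inverse-$\chi^2$,
group means conditionally normal).

One published-table feature is deliberately *not* reproduced: ANOVA rows
for curve-shape parameters showing more between-groups than within-groups
degrees of freedom (86 vs 15) imply fewer observations than groups, a
design the source table does not explain. The package reports whatever
degrees of freedom the supplied grouping yields.

## The synthetic herd: stated world

`sim_config()` defaults restate the target study's structure: 159 goats,
28 farms, mean 3.91 lactations/goat, 5 controls per lactation, first
control ~day 21 (SD 4), 4–6-week control intervals, 210–240-day
lactations, and Hardy–Weinberg diplotype draws over configurable
haplotype frequencies. Choices the source does not determine, fixed once
here:

* lactations per goat $\sim 1 + \mathrm{Poisson}(2.91)$ — exact mean
  3.91, SD 1.71 (vs the reported 2.01; no distribution is stated);
* per-trait base curves giving typical Murciano-Granadina levels (milk
  ~2–3 kg/day, fat ~5%, protein ~3.5%, dry matter ~14.5%, lactose ~4.9%,
  SCC in the 10^5–10^6 cells/mL range) and residual SDs
  (`default_noise_sd()`) chosen as realistic for goat test-day data —
  these are package defaults, not study estimates;
* haplotype effects act additively on the curve level $b_0$ only (the
  association literature this emulates reports level differences, not
  shape differences), summed over the two carried copies;
* SCC is generated on the natural scale from the parabolic yield-density
  curve with multiplicative lognormal noise (strictly positive,
  right-skewed);
* farm and lactation number are carried as metadata but not modelled,
  mirroring the one-way analysis.

What the generator does **not** emulate: animal-level random effects
beyond the haplotype (no permanent environment or pedigree), seasonality,
farm effects, SNP genotyping error, phasing uncertainty, or realistic LD
structure within blocks (token sequences are label-coded, not
population-simulated). A green calibration test therefore establishes
that the inference machinery is correct *under the stated model*, not
that the model captures every feature of real milk-recording data.

Replicate-based acceptance checks (null calibration at 200 replicates,
planted-effect detection at 100) run on a scaled herd of 80 goats rather
than 159, purely for test-runtime reasons; the end-to-end determinism
check uses 60 goats for the same reason. The 159-goat configuration is
the shipped default and is what `scripts/acceptance.R` runs.

## Known limitations

* With 5 controls per lactation the Ali–Schaeffer fit is an exact
  interpolation; per-lactation shape parameters are then high-variance
  summaries, and their ANOVAs have correspondingly low power. This is a
  property of the data regime, not a defect, but it means shape results
  should be read qualitatively.
* Model selection requires $n \ge k+2$ controls, so 5-parameter models
  cannot be ranked on 5-control lactations (reproduction mode pins the
  model pair instead).
* The default both-carriers grouping violates independence across groups;
  use `homozygous_only = TRUE` when calibrated per-group inference is the
  goal.
* No AM/PM milking-weight correction, gestation/age adjustment,
  multi-factor models, interactions, or multiple-testing correction (the
  emulated analysis used none).
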