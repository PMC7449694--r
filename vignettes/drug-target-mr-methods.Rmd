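---
title: "Sex-specific drug-target MR: models, defaults and design choices"
author: "drugTargetMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sex-specific drug-target MR: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drugTargetMR)
```

# The model

Mendelian randomization treats genetic variants as instruments for an
exposure: if variant $j$ shifts exposure $X$ by $\beta_{Xj}$ (with standard
error $\sigma_{Xj}$) and the outcome $Y$ by $\beta_{Yj}$ ($\sigma_{Yj}$),
and the variant affects $Y$ only through $X$, then every ratio
$\beta_{Yj}/\beta_{Xj}$ estimates the same causal effect $\theta$. For a
drug-target analysis the instruments sit in the gene encoding the drug's
target, so that $\theta$ mimics pharmacological modulation of the biomarker;
for a binary disease outcome the associations are log-odds and $e^\theta$
is an odds ratio per biomarker effect size.

The package's scientific question is a *mediation* one, asked separately by
sex: does a genetically mimicked drug effect on disease run partly through
an intermediate trait (testosterone)? The analysis chain is:

* **univariable (total) effects** of the drug mimic on the mediator and on
  disease, and of the mediator on disease;
* **multivariable (direct) effects**, regressing the SNP-disease
  associations jointly on the SNP-biomarker and SNP-mediator associations;
* **mediation by attenuation**: the proportion $1-\theta_{direct}/
  \theta_{total}$. This is deliberately *not* a formal product-of-
  coefficients decomposition; it only argues mediation from shrinkage, and
  the `Contrast` object raises caveat flags when the two estimates disagree
  in sign or the total effect is weak ($|\beta| < 2\,se$), where the ratio
  is meaningless.

## Estimators

All estimators work on a `HarmonizedSet`: exposure and outcome associations
aligned to a common effect allele (the exposure file's), with sign flips
applied to the outcome and, via `alignLD()`, to the off-diagonals of a
signed LD matrix.

**IVW.** Weighted zero-intercept regression,
$\hat\theta = \sum w_j \beta_{Xj}\beta_{Yj} / \sum w_j \beta_{Xj}^2$ with
$w_j = 1/\sigma_{Yj}^2$, fixed-effect SE $(\sum w_j\beta_{Xj}^2)^{-1/2}$.
Multiplicative random effects scale the SE by $\max(1, \sqrt{Q/(J-1)})$,
where $Q$ is Cochran's statistic: heterogeneity inflates uncertainty but can
never deflate it below the fixed-effect value (the floor at 1 prevents
anti-conservatism when $Q$ falls below its expectation). At $J=1$ the
estimator is the Wald ratio with the first-order delta-method SE
$\sigma_Y/|\beta_X|$ (a second-order option propagating $\sigma_X$ exists).

**Correlated instruments.** When instruments are in LD the weight matrix
becomes $\Omega = D\rho D$ with $D = \mathrm{diag}(\sigma_{Yj})$ and the
estimate is generalized least squares. A condition-number ceiling (default
$10^{12}$) rejects near-singular $\rho$ with advice to prune or add a small
ridge to its diagonal; the pipeline's sensitivity analysis uses a $10^{-6}$
ridge routinely, which perturbs well-conditioned problems negligibly and is
applied identically on every run for determinism.

**Weighted median.** Per-SNP ratios ordered, weights
$(\beta_{Xj}/\sigma_{Yj})^2$ normalized, and the 50th percentile taken with
linear interpolation between the mid-cumulative weight positions
$p_j = (\sum_{k\le j} w_k) - w_j/2$. The SE comes from a seeded parametric
bootstrap (default 10,000 draws; the seed is mandatory so pipelines are
reproducible).

**MR-Egger.** Each SNP is first oriented so $\beta_{Xj} \ge 0$ (negating
both betas), making the fit invariant to the arbitrary allele labelling of
the input files; then a weighted regression with a free intercept is fitted.
The intercept estimates average directional pleiotropy. Inference uses the
normal reference distribution by default (matching how the accompanying
tables' CIs back-calculate), with a t option.

**Correlated-SNP policy.** The weighted median and MR-Egger *refuse* input
with an attached LD matrix rather than generalize: with correlated
instruments the "majority of weight valid" and InSIDE arguments lose their
interpretation. This restraint is intentional; the pipeline reports IVW-GLS
for correlated sensitivity sets and nothing else.

**Steiger filtering.** Direction is declared from the summed per-SNP
variance explained, $r^2 = t^2/(t^2+n-2)$ with $t = \beta/\sigma$. For a
log-odds outcome the same transform is applied to the logistic z-statistic —
an observed-scale approximation, recorded in the result's `note` rather
than silently absorbed. Equal sums within a $10^{-6}$ relative tolerance
give `inconclusive`.

**Multivariable MR.** With $L=2$ exposures, the weighted (or GLS)
regression $\beta_{Yj} = \theta_1\beta_{X1j} + \theta_2\beta_{X2j}$, SE
scaling by $\max(1,\sqrt{Q_{res}/(J-L)})$, and MVMR-Egger adding an
intercept after orienting on the drug-mimicking exposure (exposure 1 by
convention — the analysis is about the drug effect, so its orientation
defines "directional"). A second exposure that is identically zero is
dropped from the design, reducing the fit *exactly* to univariable IVW; the
dropped coefficient is reported `NA`, never a fabricated zero.

**Conditional instrument strength.** For exposure $k$ given the other
exposure $l$, a nuisance slope $\delta$ is fitted by iteratively reweighted
regression of $\beta_{Xk}$ on $\beta_{Xl}$ with weights
$1/(\sigma_{Xk}^2+\delta^2\sigma_{Xl}^2)$, and the conditional F is
$Q_k(\hat\delta)/(J-1)$, the published two-exposure convention (a $J-L$
denominator is switchable). A subtlety worth recording: $\hat\delta$ must be
the *regression* fixed point, not the global minimizer of $Q_k(\delta)$ —
the profile is symmetric under $\delta \mapsto 1/\delta$ with the exposures
exchanged, so full minimization would force both exposures to the same
conditional F, which contradicts the statistic's purpose (a strongly
instrumented mediator and a weakly instrumented drug mimic must score
differently). With covariances between the two exposures' SNP effects
unavailable from summary data, the weights above are the standard summary
approximation.

**Instrument-validity Q.**
$Q_A=\sum_j (\beta_{Yj}-\theta_1\beta_{X1j}-\theta_2\beta_{X2j})^2 /
(\sigma_{Yj}^2+\theta_1^2\sigma_{X1j}^2+\theta_2^2\sigma_{X2j}^2)$ on $J-L$
df. The pipeline flags MVMR-Egger as the primary model when both $Q_A$ and
the Egger intercept are significant at $\alpha$.

# Tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `instruments.p` | 5×10⁻⁸ | genome-wide significance for instrument entry |
| `instruments.r2` | 0.05 | maximum pairwise r² after pruning |
| `instruments.f` | 10 | minimum per-SNP F-statistic |
| `dropPalindromicMaf` | 0.42 | A/T–C/G SNPs with MAF above this are dropped |
| proxy `minR2` | 0.8 | minimum r² for proxy substitution |
| `alpha` | 0.05 | significance level throughout; no multiplicity correction, by design — the study is hypothesis-driven with a positive control |
| `nBoot` | 10,000 (2,000 in the pipeline) | weighted-median bootstrap draws |
| CI critical value | 1.96 | fixed, matching 95% intervals as printed in the field's tables (not 1.959964, so back-calculation from rounded tables round-trips) |

Decisions where practice varies and the package had to pick:

* **Palindromic handling.** Strand-ambiguous SNPs are kept only when the
  minor-allele frequency on *both* sides is at or below 0.42 (frequency can
  then resolve the strand); missing frequency drops the SNP conservatively.
  Both behaviours are configurable because alignment conventions differ
  between GWAS sources.
* **Pruning rank.** Greedy pruning ranks by p-value (tie-breaks: larger
  |β/se|, then lexicographic rsID, making the output a deterministic
  function of the input *set*). Ranking by |β/se| is available; note the
  F-screen-then-prune order matters and the pipeline fixes it as F first.
* **LD sign convention.** Input correlations are signed with respect to the
  stated effect alleles of the file they came from; `alignLD(signedBy=)`
  says whether that file shared the exposure's or the outcome's original
  orientation, and flips recorded during harmonization propagate as row and
  column negations.
* **p-values** are two-sided normal everywhere (CIs are ±1.96·se), matching
  table back-calculation; Egger can switch to t.

# The synthetic cohort generator

`simulateCohort()` emulates the study design the package exists for: two
sex-stratified cohorts; a drug-target locus whose variants shift a biomarker
(`ldl` slot) by `gammaLdl` per allele; testosterone variants of strength
`tau`; a *male-only* drug-locus effect on testosterone (`alphaTMale`,
`alphaTFemale = 0`); disease risk
$\mathrm{logit}^{-1}(c_{sex} + \theta_L\,\mathrm{LDL} + \theta_{T,sex}\,T +
\sum_j g_j\delta_j)$ with $c_{sex}$ calibrated to the target prevalence by
root finding; and optional direct (pleiotropic) SNP effects $\delta_j$ drawn
once per run. Genotypes come from a latent-Gaussian threshold model: two
haplotype draws of correlated normals thresholded at $\Phi^{-1}(maf)$, with
the latent correlation calibrated by root finding so the realized indicator
correlation hits the block's target r (realized values are reported in the
cohort). Summary statistics are computed from the simulated individuals —
closed-form per-SNP linear regression for continuous traits, per-SNP
logistic regression for disease — so logistic-scale non-collapsibility
emerges naturally rather than being assumed away; a fast `asymptotic` mode
(normal draws around the theoretical marginal effects) exists for large-J
tests and does not reproduce that non-collapsibility.

## Preset calibration

The presets are fixed once; they are the package's study conditions, not
dials.

* **Cohort scale.** 20,000 individuals per sex, with disease prevalences
  25,410/179,918 (men) and 12,511/212,080 (women) — the case fractions of
  the motivating cohort, at desk scale.
* **Causal effects** in `statin_mediation` are anchored to the motivating
  study's printed estimates: the drug-locus effect on testosterone is
  −0.15 per biomarker effect size in men and 0 in women; disease log-odds
  are $\log 0.55$ per biomarker effect size and $\log 1.11$ per testosterone
  effect size in men, 0 in women.
* **Instrument strength** is where the scale-down bites: at one-ninth the
  cohort, per-allele effects equal to the real ones would leave the
  instruments too weak to exercise the pipeline meaningfully. The presets
  therefore set `gammaLdl = 0.25` per allele (lead-SNP F ≈ 500 at n =
  20,000, the same *strong-instrument regime* as the original sex-specific
  cohorts) and `tau = 0.1` with per-SNP strength multipliers spread over
  0.6–1.6 (mean testosterone F ≈ 110 and a realistic spread, without which
  MR-Egger's slope would be nearly unidentified). The consequence to keep in
  mind: variance explained per locus is larger than in real GWAS data.
* **`anakinra_reverse`** mirrors the statin pattern with opposite signs
  (drug raises the biomarker, testosterone *and* disease risk in men only).
  Its effect magnitudes are sign- and pattern-faithful but scaled up for
  detectability at two instruments and 20,000 individuals; it is a
  qualitative mirror, not a quantitative replica.
* **`pleiotropic`** plants directional direct effects (mean 0.08, SD 0.02
  log-odds per allele) across twenty spread-strength instruments, sized so
  the Egger intercept test has real power at desk scale.
* The drug block's six variants share one LD block at r = 0.55 with the
  lead variant strongest — so lead selection, correlated-IVW sensitivity
  analysis and proxy logic all have something real to do.

What the generator does *not* emulate: realistic genome-wide LD maps,
X-chromosome dosage (all variants are treated autosomally, although the
real testosterone instruments include X variants), winner's curse from
instrument discovery in the same sample, covariate adjustment artifacts,
and case-control ascertainment. Passing tests therefore certify the
*estimators and pipeline logic*, not robustness to those real-data
complications.

A structural note on the simulated mediation: with the mediator pathway
$\alpha_T/\gamma = -0.15$ and $\theta_T = \log 1.11$, the mediated share of
the drug-disease effect is $0.15 \times 0.104 \approx 0.016$ log-odds —
about 2.5% of the total. The preset reproduces the *pattern* (male-only
pathway, attenuation toward the null in the multivariable model); the large
attenuation printed in the motivating study reflects estimates whose
univariable and multivariable values straddle the null with a weak
conditional instrument, not a numerically recoverable constant, and the
generator does not pretend otherwise.

# Pipeline behaviour

`runStudy()` executes the whole design per sex and writes tidy TSV reports
plus a run log and manifest. Choices worth knowing:

* Instrument lists are kept disjoint: variants genome-wide significant for
  the drug biomarker are excluded from the mediator's instrument set,
  mirroring the use of distinct published instrument lists per trait (in
  the simulation the male drug locus reaches significance for testosterone
  through the planted pathway; as a mediator instrument it would be an
  egregious pleiotropy outlier, and real analyses exclude such loci).
* The "drop exposures with no mediator association" decision rule is
  *reported* (as a gate verdict in the diagnostics) but not enforced unless
  `gateOnExposureOutcomeP = TRUE` — the full table is always reproducible.
* Stage errors are logged with the failing call and downstream dependents
  skipped; independent branches continue. An exposure whose entire
  instrument set is dropped is reported as such, never silently absent.
* Reruns with the same config are byte-identical; all seeds derive from the
  config seed.
* There is no shell entry point: like its Bioconductor peers the package is
  driven from R, and `runStudy()` + presets are the orchestration surface.

# Numerical choices and degenerate inputs

* Zero $\beta_X$ at $J=1$ is an error (undefined ratio); zero columns in
  MVMR reduce the design; collinear exposures error with the condition
  number.
* `filterByF` may empty a set (warned, logged) — downstream stages then
  fail loudly.
* Monomorphic simulated variants are excluded from summary statistics and
  listed in a `flagged` attribute, since a standard error does not exist
  for them.
* The conditional-F inner iteration runs to a $10^{-13}$ relative fixed
  point (at most 200 iterations); the weighted-median interpolation uses
  `approx` with ordered ties.
* Test and acceptance problem sizes are desk scale by design: oracles on
  ≤10-SNP fixtures, 200-replicate recovery studies at 20,000 individuals
  per sex and 20 variants, 500-replicate summary-level power checks. The
  vignette's calibration section explains how preset effects were chosen
  once for that scale.

# Known limitations

* Binary-outcome Steiger uses the observed-scale r² approximation; a
  liability-scale version is not implemented.
* MVMR supports exactly two exposures — the design of the analysis — not
  arbitrary L.
* The weighted median's bootstrap ignores LD by construction (it refuses
  correlated input) and its SE is simulation noise at small `nBoot`.
* `fixedEffectMeta` is fixed-effect only: it pools two sex strata of one
  cohort, where between-stratum heterogeneity is part of the question, not
  a nuisance to average over.
* Attenuation is computed on the log-odds scale for disease outcomes;
  non-collapsibility means it is not exactly a "proportion mediated" even
  under a correct model — hence the caveat flags.
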