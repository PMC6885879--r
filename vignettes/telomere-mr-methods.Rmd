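---
title: "Mendelian randomization of telomere length: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian randomization of telomere length: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question and the design

Observational associations between leukocyte telomere length (TL) and lung
cancer risk are vulnerable to reverse causation (a growing tumour can alter
measured TL) and to confounding (age, smoking). Mendelian randomization (MR)
sidesteps both by using germline variants associated with TL as instrumental
variables: genotypes are fixed at conception and randomized at meiosis, so a
genotype–disease association that flows through TL supports a causal TL
effect. Validity rests on three assumptions: the instruments are associated
with TL; they affect disease only through TL (exclusion restriction); and
they are independent of confounders of the TL–disease relationship.

`telomr` implements both standard MR arms for a case-control outcome:

* **Individual-level (GRS) arm.** A weighted genetic risk score
  $\mathrm{GRS}_i = \sum_j \beta_j x_{ij}$ aggregates effect-allele dosages
  $x_{ij} \in \{0,1,2\}$ with kb-per-allele weights $\beta_j$ from TL GWAS,
  so the GRS is genetically predicted TL in kb (up to a constant).
  Logistic regression of case status on the GRS, adjusted for age, sex,
  pack-years, the first genetic principal component and study membership,
  gives an odds ratio per 1-kb increase in genetically predicted TL.
* **Summary-level (IVW) arm.** With per-SNP outcome log-ORs
  $\beta_{Yj}$ (SE $\sigma_{Yj}$) and exposure effects $\beta_{Xj}$, the
  inverse-variance-weighted estimate is the origin-constrained weighted
  least squares slope
  $\hat\beta = \sum_j \beta_{Xj}\beta_{Yj}\sigma_{Yj}^{-2} \big/
  \sum_j \beta_{Xj}^2\sigma_{Yj}^{-2}$, with
  $\mathrm{se}(\hat\beta) = (\sum_j \beta_{Xj}^2\sigma_{Yj}^{-2})^{-1/2}$.
  Exposure-side uncertainty is ignored, as in the standard first-order
  method; this is the fixed-effect estimator only — random-effects IVW,
  MR-Egger and median estimators are deliberately out of scope.

## Instrument handling

Instruments are filtered on three criteria (genome-wide significance
$p \le 5\times10^{-8}$, reference-population MAF strictly above 0.05, and
pairwise LD $r^2 < 0.5$) and oriented so the long-TL allele is the effect
allele, making every $\beta_{Xj} \ge 0$; effects reported in bp are divided
by 1000 so all weights share the kb scale. LD violations are resolved
greedily in ascending discovery p-value, the same rule as standard
clumping. The greedy order is our choice — the selection criteria
constrain only the pairwise $r^2$ — and is covered by an exhaustive
enumeration oracle in the tests.

The bundled nine-SNP catalog (TERC, TERT, NAF1, OBFC1, ZNF208, RTEL1,
ACYP2, CTC1, ZNF676 regions) carries *approximate*, literature-typical
kb-per-allele weights and East-Asian-plausible MAFs; the file is labelled
`synthetic` and real analyses should supply exact weights from the TL GWAS
being instrumented. This matters for reproduction exercises: every
scale-invariant diagnostic (Cochran Q, its p-value, standardized
residuals, direction and attenuation patterns) is insensitive to a uniform
rescaling of the weights, but the OR per kb itself scales as
$1/c$ under $\beta_X \mapsto c\,\beta_X$, so worked examples computed from
approximate weights can differ from published ORs by a uniform-scale
factor even when all diagnostics agree.

## Pleiotropy diagnostics and sensitivity analysis

Under the exclusion restriction, SNP effects on disease are proportional
to their effects on TL. Cochran's
$Q = \sum_j \sigma_{Yj}^{-2}(\beta_{Yj} - \hat\beta\,\beta_{Xj})^2$ on
$J-1$ df tests that proportionality across instruments. To localize a
violation we refer each standardized residual
$(\beta_{Yj} - \hat\beta\,\beta_{Xj})/\sigma_{Yj}$ to the standard normal
and flag SNPs below a Bonferroni-corrected two-sided threshold
($\alpha/J$, default $\alpha = 0.05$). The per-SNP statistic is our
interpretation — the field uses several — chosen because it is exact under
the fixed-effect model, order-invariant and cheap; the flagged set feeds
an automatic exclusion refit of both arms (`exclude_and_refit()`, and the
GRS arm rebuilt without the flagged SNPs). With one genuinely pleiotropic
SNP the refit removes most of the bias; the contaminated estimate itself
remains biased toward the direct effect, which the simulation tests
quantify. Between-study heterogeneity uses the same fixed-effect Q across
per-study IVW estimates.

A single-SNP IVW has no residual degrees of freedom; we define
$Q = 0$ on 0 df with $p = 1$ (degenerate chi-square) rather than `NA`, so
downstream code need not special-case $J = 1$.

## Decile and nonlinearity analyses

The GRS is cut at its pooled (cases + controls) decile boundaries;
boundary ties go to the lower decile (left-open, right-closed bins), so
group sizes differ only by ties, and an empty group is an error naming the
offending boundary. Per-decile ORs are indicator coefficients against the
lowest decile; the trend OR enters the decile index 1..10 as a continuous
covariate ("per decile increase"), an assumption we document because the
index coding of published trend ORs is rarely stated.

Departure from log-linearity is tested with a restricted cubic spline:
truncated-power basis constrained to be linear beyond the boundary knots,
normalized by $(t_k - t_1)^2$ for conditioning (any consistent scaling
gives identical p-values; asserted in the tests). Defaults: 4 knots at
the 5th/35th/65th/95th percentiles of the pooled GRS — the standard
recommendation; knot count (3–5) and placement are exposed because the
convention is not universal. `p_linear` is the 1-df likelihood-ratio test
of the linear term against the covariates-only null; `p_nonlinear` is the
$(k-2)$-df LRT of the full spline against the linear model. Both are
defined through nested maximum-likelihood fits, so the log-likelihood
ordering null $\le$ linear $\le$ full holds by construction and is
asserted, not assumed.

## The synthetic cohort generator

The generator exists to give the estimators data whose truth is known. It
draws, per individual: dosages $x_{ij} \sim \mathrm{Binomial}(2, p_j)$
independently across SNPs (Hardy–Weinberg, no LD); latent
$TL_i = \mu + \sum_j \beta_{Xj} x_{ij} + \varepsilon_i$ with
$\varepsilon_i \sim N(0, \sigma^2)$; covariates (age normal, sex
Bernoulli, pack-years as a two-part never-smoker/gamma mixture, PC1
standard normal, study uniform); and disease through a logistic model
$\mathrm{logit}\,P = \alpha_0 + \gamma\,(TL_i - \mu) + \text{confounder
terms} + \text{direct SNP terms}$. Individuals are kept by rejection
sampling until the case and control quotas are met exactly, with a
documented cap (`max_draw_factor`) after which an unachievable quota is an
error. Histology strata (adenocarcinoma / squamous / other, default mix
0.67/0.21/0.12 as in a large pooled East Asian case series) get their own
logits, optionally with stratum-specific $\gamma$; a case's stratum is
drawn proportionally to the per-stratum odds.

Chosen defaults, and why:

* `tl_mean` 6.5 kb, a typical adult leukocyte TL; only contrasts matter.
* `tl_sd` is **derived** so the nine instruments explain 1% of TL variance
  ($\sigma^2 = \mathrm{Var}_g(1-h^2)/h^2$ with
  $\mathrm{Var}_g = \sum_j \beta_{Xj}^2\,2p_j(1-p_j)$), the share these
  loci typically explain; the realized share is recorded in the config and
  asserted empirically in the tests.
* `causal_log_or_per_kb` defaults to $\log 2.25$, the magnitude this
  design is powered around; recovery and calibration studies in the tests
  set their own values ($\log 1.5$, 0).
* Confounder log-ORs (age 0.02/yr, female −0.25, pack-years 0.025/py, PC1
  0.15, study 0.1) and covariate distributions (60% female, age 60 ± 10,
  60% never-smokers, gamma(2, 15) pack-years among smokers) are plain
  config values — never hidden constants — at epidemiologically plausible
  magnitudes. No published covariate effect sizes were available to copy,
  so these are stated choices, not inferences.
* `baseline_log_odds` $= \mathrm{logit}(0.25)$ controls sampler
  efficiency, not the case:control ratio (rejection sampling fixes that).
* `pleiotropy` gives named SNPs a direct per-allele log-OR on disease,
  emulating a TERT-region-style exclusion-restriction violation.

What the generator does **not** emulate — and therefore what passing
tests cannot show about real data: LD among instruments (the real set is
pruned only to $r^2 < 0.5$), imputation uncertainty, population
stratification beyond a single PC covariate, genotyping error or
missingness mechanisms, and secular/cohort structure in covariates. A
documented simplification: the `maf` field is treated as the effect-allele
frequency, constrained below 0.5.

Noncollapsibility deserves a note: the per-SNP outcome models necessarily
omit the non-genetic TL variation, so conditional per-allele log-ORs are
mildly attenuated relative to $\gamma \beta_{Xj}$ (about 4–5% at the
default variance share). The recovery tests therefore check unbiasedness
within Monte-Carlo error at $\gamma = \log 1.5$, where the attenuation is
well inside the tolerance, and coverage in the 0.93–0.97 band.

## Numerical choices and degenerate inputs

* Logistic fits use maximum likelihood via IRLS (`stats::glm`); the
  independent test oracle is a hand-coded Newton–Raphson. Non-convergence
  errors. Separation is flagged when fitted probabilities degenerate
  (below $10^{-8}$) together with a coefficient swinging more than 20
  log-odds units per predictor SD — large enough never to fire on strong
  genuine effects, small enough to catch diverging fits.
* Wald 95% CIs on the log-odds scale throughout (published CIs are
  symmetric-Wald; profile likelihood is out of scope); `se_from_ci()`
  inverts that convention with the literal 1.96 multiplier.
* Likelihood-ratio statistics are clamped at 0 to absorb last-digit
  noise in nested fits.
* Instruments with $\beta_X = 0$ are rejected at harmonization
  (uninformative); zero-width CIs yield `se = 0` and are rejected where
  they would enter a weight.
* Reproducibility: the pipeline fans a single seed out to named
  sub-streams, and the generator restores the caller's RNG state.

## Problem sizes

Simulation-based checks use cohorts of 2,000–10,000 individuals and
200–500 replicates (recovery: 200 cohorts of 4,000 at $\gamma=\log 1.5$;
calibration: 500 cohorts of 2,000; pleiotropy power: 100 cohorts of
10,000 with one direct log-OR of 0.3), sizes at which the estimators'
asymptotics are comfortably in force while a full run stays inexpensive.
The end-to-end pipeline example uses 7,127 cases and 6,818 controls, the
scale of the pooled East Asian case-control sample that motivates the
defaults.

## Known limitations

Fixed-effect IVW only; no MR-Egger/median/mode or multivariable MR; no
computation of LD from reference panels (the user supplies the $r^2$
matrix); the bundled instrument weights are approximate stand-ins; VCF
support is a minimal GT-only dialect intended for interchange of the
simulated cohorts, not a general-purpose VCF reader.
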