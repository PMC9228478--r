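---
title: "Methods: twin-based heritability of urinary metabolite panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-based heritability of urinary metabolite panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

twinmetab implements the analysis cycle of a classical-twin-design (CTD)
urinary metabolomics study in children: quality-control driven
preprocessing of targeted LC-MS/GC-MS panels, family-clustered association
scans for sex and age, and variance decomposition of each metabolite by
full-information maximum likelihood (FIML) on monozygotic (MZ) and
dizygotic (DZ) twin pairs. This vignette is the package's account of the
underlying models, the defaults and why they were chosen, and what the
synthetic-data generator does and does not emulate.

## The classical twin design

MZ co-twins share essentially all segregating genetic variants; DZ
co-twins share half on average. Writing the phenotypic variance of a
metabolite as the sum of additive genetic ($A$), dominant genetic ($D$),
common environmental ($C$) and unique environmental ($E$) components, the
expected within-pair covariances are

$$\mathrm{cov}_{MZ} = A + D + C, \qquad
  \mathrm{cov}_{DZ} = \tfrac{1}{2}A + \tfrac{1}{4}D + C.$$

Two observed covariances cannot identify three familial components, so the
ACDE model is never fitted: the package follows the standard rule of thumb
and fits ADE when $r_{MZ} > 2\,r_{DZ}$ and ACE otherwise, with the tie
going to ACE because the rule is a strict inequality. Broad-sense
heritability is $h^2 = (A+D)/V$ under ADE, narrow-sense $h^2 = A/V$ under
ACE, with $V$ the total variance.

### Saturated model and twin correlations

`fit_saturated()` maximizes the raw-data likelihood of a two-group model
with means and variances equated across birth order and zygosity. Each
family contributes the multivariate-normal log-density of its *observed*
sub-vector — complete pairs a bivariate term, singleton twins a univariate
term — so incomplete pairs are used without listwise deletion (this is
what "full-information" buys, and it is exercised by a unit test asserting
that deleting a singleton changes the log-likelihood by exactly that
child's univariate density). The ML twin correlations $r_{MZ}$ and
$r_{DZ}$ are read off this fit.

Mean-model covariates (sex and/or age) are chosen by likelihood-ratio
tests: `select_covariates()` compares the full sex+age saturated model
against each reduced model and retains a covariate exactly when its
removal is rejected at $\alpha = 0.05$. An AIC-based mode is available;
LRT is the default because the removal tests have a direct calibration
check (their type-I error is part of the acceptance suite).

### Variance components, negative estimates, intervals

`fit_ace_ade()` parameterizes $A$, $D$ (or $C$) and $E$ directly as
unconstrained reals. Variance components are deliberately *not* bounded at
zero: when $r_{MZ} > 4\,r_{DZ}$, the unconstrained ADE solution has
negative $A$, and truncating it would bias the broad-sense $h^2$ that is
the quantity of interest. For this reason the broad-sense $h^2$, not the
A/D split, is the headline number reported for ADE fits, and the
significance of D or C components is not tested — with few DZ pairs the
power for those components is known to be poor. Proposals that make a 2x2
family covariance non-positive-definite receive a penalized likelihood,
which keeps the quasi-Newton search (nlminb, relative tolerance 1e-10, up
to 3 jittered restarts) inside the feasible region without constraining
the solution. On complete balanced data both models are exactly identified
by three moments, and the FIML estimates must agree with the closed forms

$$\hat A_{ADE} = 4\widehat{\mathrm{cov}}_{DZ} - \widehat{\mathrm{cov}}_{MZ},\quad
  \hat D = 2\widehat{\mathrm{cov}}_{MZ} - 4\widehat{\mathrm{cov}}_{DZ},\quad
  \hat A_{ACE} = 2(\widehat{\mathrm{cov}}_{MZ} - \widehat{\mathrm{cov}}_{DZ}),\quad
  \hat C = 2\widehat{\mathrm{cov}}_{DZ} - \widehat{\mathrm{cov}}_{MZ},$$

within 1e-4 — an acceptance-level invariant, checked together with the
identity that the ADE broad-sense $h^2$ equals the fitted $r_{MZ}$.

`profile_ci()` reports profile-likelihood intervals on the standardized
shares: the bounds solve $2\{\ell_{\max} - \ell_p(s)\} = \chi^2_{1,0.95}$,
where the profile $\ell_p$ re-maximizes over the mean coefficients, the
total variance (log scale) and the remaining share. Bounds are located by
stepping outward in 0.05 increments and root-bracketing; a bound escaping
the search window $[-1, 2]$ on the standardized scale is reported as
open-ended with a warning. Profile likelihood was chosen as the interval
method on its own merits (invariance under the standardization, good
behaviour near boundary and negative estimates); it is a package choice,
not an assertion about any particular prior analysis.

The saturated model keeps its covariance feasible differently — variance
on the log scale, correlations through tanh — because there the
correlation itself is the parameter of interest and lives in $(-1, 1)$.

## Preprocessing

The preprocessing stack mirrors standard practice for targeted urinary
panels, in this fixed order:

1. **Sample exclusions** (`apply_sample_exclusions()`): insufficient
   urine, not first-morning urine, more than 2 h between collection and
   freezing, second twin pair of multiples in a family, cross-cohort
   duplicates — applied in that order so each child's exclusion reason is
   deterministic. Missing flags pass with a warning.
2. **Metabolite filters** (`filter_metabolites()`): missing rate strictly
   above 10%, then QC relative standard deviation (`compute_rsdqc()`,
   $100\,\mathrm{sd}/\mathrm{mean}$ over pooled-QC injections) at or above
   15% — the RSD threshold is inclusive. Below-LOD entries are known-low
   measurements, not missing items, and do not count toward missingness.
3. **Below-LOD imputation** (`impute_below_lod()`): half the limit when
   known, otherwise half the lowest observed level.
4. **Creatinine normalization** (`normalize_creatinine()`): division by
   the sample's creatinine; units are arbitrary-but-consistent since the
   division cancels them and the next step removes scale.
5. **Inverse normal rank transform** (`inverse_normal_transform()`):
   Blom offset 3/8 with average ranks for ties,
   $\Phi^{-1}\{(r - 3/8)/(n + 1/4)\}$, applied per metabolite within
   cohort (cohorts are analyzed separately downstream). The Blom constant
   is the dominant convention in genetic-epidemiology pipelines, the
   offset is configurable, and downstream results are insensitive to the
   choice because only ranks survive the transform — a property the test
   suite asserts directly (any strictly monotone transform of the raw
   values yields identical output).

Whether the missing-rate filter should run before or after other
corrections is not fully determined by practice; it runs first here, which
makes the filter a pure function of the raw matrix.

## Family-clustered association scans

`fit_family_lmm()` fits $y = X\beta + u_{\mathrm{family}} + \varepsilon$,
$u \sim N(0, \tau^2)$, $\varepsilon \sim N(0, \sigma^2)$ by maximum
likelihood. The likelihood is profiled: for fixed
$\theta = \tau^2/\sigma^2$ the GLS coefficients and $\sigma^2$ are closed
forms via a Sherman–Morrison inverse per family, leaving a 1-D
optimization over $\theta \in [0, 50]$. The upper bound corresponds to an
intraclass correlation of about 0.98; for exactly duplicated responses the
ML likelihood is unbounded in $\theta$, and the bounded search returns the
sensible limit ($\sigma^2 \to 0$, ICC $\to 1$). ML rather than REML is
used so the model composes with likelihood-based reporting; at the
package's default cohort sizes (around 1300 children) the difference is
immaterial. Fixed effects get Wald z tests, which is how per-metabolite
betas and p-values are conventionally reported. A two-level factor such as
zygosity is not usable as a random effect (two levels are degenerate);
family is the clustering unit, which is the stated purpose of the random
term.

`run_association_scan()` runs one of eight layouts — sex + age with age
continuous or dichotomized at 10 years (the cohort median; the boundary
age goes to the older group), age within sex strata (both codings), and
sex within age strata — and applies Benjamini–Hochberg step-up FDR
(`bh_fdr()`, delegating to `stats::p.adjust`) per term within the
analysis, calling significance at $q \le 0.05$. The test count defaults to
the number of metabolites scanned and can be set explicitly (`fdr_m`) when
the correction is defined over a larger panel. Strata with fewer than 10
families are refused. `replication_concordance()` declares a discovery hit
replicated when it is significant in both cohorts with the same effect
sign, and reports the cross-cohort beta correlation.

## The synthetic-data generator

`simulate_cohort()` exists so that every downstream stage has inputs with
known truth. Per metabolite the latent value of child $i$ is

$$y_i = \beta_{sex}\,\mathrm{sex}_i + \beta_{age}\,\mathrm{age}_i
        + a_i + c_i + d_i + e_i,$$

with unit total component variance and within-pair correlations 1/0.5
(a), 1/0.25 (d), 1 (c), 0 (e) for MZ/DZ. The raw relative response ratio
is $\exp(0.5\,y)$ times the child's creatinine draw
(lognormal$(0, 0.4)$); the lowest `lod_quantile` fraction of each raw
distribution is censored below LOD (the limit's value is recorded for
half the metabolites, so both imputation branches stay exercised); items
go missing completely at random; pooled-QC injections are drawn around
the pooled mean at the configured CV, one per 10 study samples. All
masking is recorded in a ground-truth object first, so tests can assert
an exact round trip. One RNG stream keyed by `seed` drives the whole
draw, and the caller's RNG state is restored afterwards.

Defaults are the study conditions of a large children's twin cohort: 531
MZ and 114 DZ complete pairs plus 6 and 4 singleton twins (1300
children), ages uniform on 5.7–12.9 years shared within pair, 48.2%
girls, MZ pairs same-sex, and a panel of 56 amines, 20 organic acids and
10 steroids. DZ co-twin sexes are drawn independently (no sex-limitation
structure is modelled, so opposite-sex composition has no downstream
role, and the generator keeps its surface minimal rather than exposing a
composition knob). `default_var_fracs()` assigns each platform a fixed
ADE/ACE regime mix (50/56, 13/20, 6/10 ADE) with fraction values chosen
once to reproduce platform-level correlation patterns typical of urinary
panels in children (for example amines: ADE with $A=.13$, $D=.38$,
$E=.49$, implying $r_{MZ}=.51$, $r_{DZ}=.16$). Unstated nuisance defaults
were likewise fixed once at values a practitioner would call realistic:
2% LOD censoring, 2% missingness, 8% QC CV.

What the generator does *not* emulate: batch drift beyond QC scatter
(real pipelines correct it upstream with proprietary algorithms),
sex-limitation or age-moderation of the variance components, assortative
mating, non-MCAR missingness, and longitudinal sampling. Passing tests
therefore demonstrate correctness of the estimators under the CTD
assumptions plus MCAR — they do not validate those assumptions for any
particular real cohort.

## Reliability banding and summaries

The MZ correlation is a lower bound on test–retest reliability, so
`classify_reliability()` bands it: excellent $\ge 0.75$, good
$[0.60, 0.75)$, moderate $[0.40, 0.60)$. The printed band edges of the
convention (0.60–0.74, 0.40–0.59) are two-decimal renderings; half-open
real intervals avoid gaps at values like 0.745. Below 0.40 the band is
*indeterminate*, not "low", because a low MZ correlation does not imply
low reliability. `platform_summary()` reports per-platform means and
min–max ranges of correlations and heritability, ADE/ACE counts and band
counts.

## Problem sizes and calibration checks in the test suite

The suite's statistical checks run at sizes chosen to make their
Monte-Carlo error small relative to the asserted bands: moment-formula
checks on latent correlations at 5000 pairs per zygosity; closed-form
FIML equivalence on a 20-metabolite engineered panel; parameter recovery
and 95% profile-interval coverage over 200 replicates at the default
531/114 pair composition (mean absolute bias of the ACE shares below
0.05, coverage within [0.90, 0.99]); LRT and Wald type-I error over 200
null replicates (within [0.03, 0.07] at nominal 0.05); and
false-discovery-proportion control of a fully null 86-metabolite scan
over 200 replicates, assessed per term family because each term is its
own BH correction family. Replicate seeds are fixed constants, so the
suite is deterministic; the calibration bands are tight enough that they
would fail under a real miscalibration but are not re-tuned to any
particular draw.

## Known limitations

* The LMM accepts only binary categorical fixed effects (sex); general
  factor covariates are out of scope for the scans it serves.
* The twin models are univariate per metabolite; bivariate/multivariate
  decompositions, extended pedigrees and moderation models are out of
  scope.
* Profile intervals are reported for the heritability share in the
  pipeline; other shares are available via `profile_ci()` but not
  tabulated by default for runtime reasons.
* With very few DZ pairs the ADE/ACE choice rule is noisy near
  $r_{MZ} = 2 r_{DZ}$; regime recovery is only exact with a separation
  margin, which the pipeline tests make explicit.
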