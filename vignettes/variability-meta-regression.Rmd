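---
title: "Arm-based meta-regression of outcome variability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arm-based meta-regression of outcome variability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armvar)
```

## The scientific question

Precision medicine presupposes *treatment heterogeneity*: that the same
person would respond differently to different treatments. A standard
parallel-group RCT cannot show this directly - it identifies only an
average treatment effect, and between-person outcome differences can arise
from within- and between-person variation that has nothing to do with the
treatment. An indirect, meta-analytic route exists: if treatment effects
genuinely differ between people, the *variability* of the outcome after
treatment will be larger in active-treatment ("verum") arms than in
placebo arms of randomised trials. A second prerequisite is that usable
predictors of that heterogeneity exist; this shows up as
treatment-by-covariate interactions on the variability scale.

`armvar` implements this programme for glycaemic control in type 2
diabetes, with HbA1c after treatment as the outcome and one observation
per *trial arm*.

## The outcome: bias-corrected log SD with inverse-variance weights

Each arm contributes the natural logarithm of its outcome SD on the
percent HbA1c scale, bias-corrected for small samples:

$$y = \log(\mathrm{SD}) + \frac{1}{2n-1},$$

where $n$ is the arm's analysed sample size. $\log$ of a sample SD is
biased downward; $1/(2n-1)$ is the first-order correction. It is worth
being precise about what this correction can do: it removes the $O(1/n)$
term of the bias, so an $O(1/n^2)$ residual remains visible at very small
$n$ (at $n = 5$ roughly $-0.02$ on the log scale, under 20% of the
uncorrected bias). The test suite asserts exactly this: a large reduction
at every $n$, and agreement with the truth to within Monte-Carlo error
from $n \approx 20$ upward.

Arms are weighted by $w = 2n - 1$, the reciprocal of the large-sample
variance of the bias-corrected estimate - the usual inverse-variance
principle. A well-known alternative convention takes the variance of an
uncorrected log SD to be $1/(2(n-1))$; `make_arm_record()` exposes this
as `weight_scheme = "2(n-1)"` for sensitivity analysis but never
substitutes it silently, because the two conventions differ and only one
belongs to the bias-corrected outcome used here.

### Reconstructing SDs from what publications report

Trial publications report variability in several forms. The normalisation
step resolves, in order of preference (least derived first):

1. a reported SD;
2. a standard error: $\mathrm{SD} = \mathrm{SE}\sqrt{n}$;
3. a confidence interval for the mean:
   $\mathrm{SD} = \sqrt{n}\,(\mathrm{hi}-\mathrm{lo})/(2z)$, with $z$ the
   standard-normal quantile at $(1+\text{level})/2$ (normal, not $t$ -
   the elementary conversion convention);
4. medians with quartiles and/or extremes, via the optimal weighted
   combinations of Luo et al. (2018) for the mean and the closed-form
   quantile estimators of Wan et al. (2014) for the SD.

For the quantile route we deliberately use the *closed-form* estimators
(the defaults of the McGrath et al. estimation framework) rather than the
iterative quantile-matching variant: they are deterministic, testable
against explicit formulas, and accurate to within 2% for normal data at
$n \ge 100$ (verified by simulation in the test suite). Arms whose SD,
mean or $n$ cannot be resolved are *excluded, never imputed*, and each
exclusion is logged with a machine-readable reason code so that arm
accounting always reconciles.

### Units

HbA1c appears on two scales. Location statistics (means, medians,
quartiles, CI bounds) convert by the affine master equation
$\%=\text{mmol/mol}\times 0.0915+2.15$; dispersion statistics are
translation-invariant, so SDs and SEs convert with the slope only. All
analysis is done on the percent scale.

## The model

For arm $a$ of trial $j$:

$$y_{ja} = \beta_0 + \beta_t T_{ja} + \beta_m \log \bar x_{ja}
  + u_j + \varepsilon_{ja}, \qquad
  u_j \sim N(0, \tau^2), \quad
  \varepsilon_{ja} \sim N(0, \sigma^2 / w_{ja}),$$

with $T$ the verum indicator and $\log \bar x$ the log mean HbA1c after
treatment in the arm. The log-mean adjustment is mandatory: on the log
scale it accounts for the mean-SD coupling of a positive outcome, so that
$\beta_t$ measures a variability difference *beyond* what the treatment
effect on the mean would induce. The trial-level random intercept absorbs
within-trial correlation. $\beta_t > 0$ means larger verum variability,
i.e. evidence of treatment heterogeneity.

Interaction models add a predictor and its product with treatment; the
reported quantities are the within-placebo slope, the within-verum slope,
and their difference (the interaction coefficient), each with a Wald CI
from the fitted coefficient covariance. Predictors stay on their
reporting scales (years, %, kg/m², weeks, calendar year); no centering or
standardisation, so slopes are directly interpretable per unit. No
multiplicity adjustment is applied across the per-predictor models - each
is a separate model answering a separate question. The drug-class model
replaces the binary treatment term with a class factor (placebo
reference), giving per-class contrasts against placebo.

### Estimation

Estimation is REML by default - the conventional choice for
variance-component models and the default of the major mixed-model
implementations - with ML behind a switch. The fitter profiles $\beta$
and $\sigma^2$ analytically and maximises the restricted likelihood over
the single ratio $\theta = \tau^2/\sigma^2$:

* per-trial block inverses via the Woodbury identity, so a criterion
  evaluation is $O(\text{arms} \times p^2)$;
* the quadratic form is computed from explicit residuals rather than by
  subtracting solved normal equations, which matters on nearly flat
  likelihood surfaces;
* optimisation on $\log\theta$ over three fixed overlapping restart
  intervals plus an explicit boundary evaluation at $\theta = 0$
  ($\tau^2$ is bounded at zero), followed by a local polish to pin the
  argmax on flat surfaces; criterion tolerance $10^{-10}$;
* Wald CIs for fixed effects use normal quantiles. Exact small-sample
  denominator-degrees-of-freedom corrections (e.g. Satterthwaite) are not
  applied; at hundreds of arms and trials the difference is in the third
  decimal;
* the CI for $\tau^2$ is a profile-likelihood interval (deviance cutoff
  $\chi^2_{1,0.95}$), with $\sigma^2$ re-optimised numerically at each
  candidate $\tau^2$;
* rank-deficient fixed-effect designs are rejected with the offending
  columns named; complete-case analysis with the dropped-arm count
  reported on every fit; trials whose arms all share one treatment level
  are retained (they still inform $\tau^2$ and $\beta_m$).

Two identities pin the implementation down and are enforced as tests:
with $\tau^2 = 0$ the fit reduces exactly to weighted least squares, and
rescaling all weights by a constant leaves $\hat\beta$ and $\hat\tau^2$
unchanged while rescaling $\hat\sigma^2$ by that constant - so only the
*relative* weights identify $\beta$, and $\hat\sigma^2 \approx 1$ is a
checkable (not assumed) consequence of the inverse-variance convention.
The fitter is validated against a dual oracle: an independent dense-matrix
direct maximisation of the closed-form restricted likelihood, and
`lme4::lmer` with inverse-variance weights; all three agree to six
significant digits on small fixtures.

### Auxiliary analyses

The corridor-effect check compares the *variance of arm mean HbA1c*
between treatment groups: a glucose-lowering treatment that steers
everyone into a narrow target corridor compresses this variance in verum
arms, and can thereby mask heterogeneity on the SD scale. The CI is the
chi-square interval for a normal variance - a pragmatic choice; arm means
are approximately normal but not i.i.d., so this interval is indicative
rather than exact. Descriptive tables use quantile type 7 (linear
interpolation between order statistics, the R default); other software
defaults differ by at most one order statistic at these sample sizes.

## The synthetic-data generator

Two generators make every pipeline stage testable without any external
data.

**Individual level.** Participants have baselines
$N(66.1, 10^2)$ mmol/mol; changes are the arm mean change plus
$N(0, 44)$ noise, so both arms reach an after-treatment SD of 12 mmol/mol
when nothing else happens (baseline SD 10 and residual change SD
$\sqrt{44}$ were chosen to land exactly there, and the defaults
-2.2 / -7.5 mmol/mol for the placebo change and the extra verum effect
reproduce typical post-treatment means of about 8.0% and 7.3%). Treatment
heterogeneity enters as a responder mixture: a fraction $1-p$ of verum
participants receive an extra change $d$, adding $p(1-p)d^2$ to the verum
variance under random assignment - an identity the tests verify
empirically ($p = 0.5$, $p(1-p)d^2 = 112$ on a 12 mmol/mol base gives
exactly 16 mmol/mol). A `rank_coupled` assignment mode gives the extra
benefit to those who would otherwise end highest: this crossover-style
negative dependence between placebo-path outcome and treatment benefit
compresses the verum SD back to (or below) the placebo value despite
identical person-level heterogeneity. The pipeline is, by construction,
blind to heterogeneity of that kind; the generator exists precisely so
that this blind spot is demonstrable rather than hypothetical.

**Arm level.** The meta-dataset generator is the generative twin of the
fitted model, at the design scale of the real evidence base: 174 trials,
one placebo plus one to three verum arms (mean about 2.6 arms per trial),
arm sizes log-uniform on [5, 8078] to mimic the heavy right skew of real
trial sizes, covariates drawn at trial level from distributions matching
published trial-population descriptives, drug classes with realistic
frequencies, and generating parameters $\beta_t = 0.037$,
$\beta_m = 1.476$, $\tau^2 = 0.112$, $\sigma^2 = 1$, with $\beta_0$ set
so placebo-arm log(SD) centres near 0.10. Optional raw-scale
treatment-by-covariate interaction coefficients and per-covariate
missingness probabilities complete the Table-2-style machinery. One
consequence of the log-uniform choice deserves a note: it reproduces the
range and skew of real arm sizes but centres them somewhat higher than
the real median, which makes the simulated weights slightly more
informative than the real ones; this affects Monte-Carlo standard errors,
not validity.

What the generator does *not* emulate: reporting idiosyncrasies of real
publications (it emits clean schemas; the mixed-format ingestion is
exercised by deliberately degrading its output), non-normal outcome
distributions, dose structure within trials, correlated covariates, and
selective reporting. Passing parameter-recovery tests therefore shows
that the estimator is correct *for the stated model at the stated
design*, not that the model is correct for any particular real dataset.

## Validation problem sizes

The suite validates at these scales, chosen to make Monte-Carlo error
small relative to the assertions: 500 simulated datasets at the full
design scale for bias (within 3 Monte-Carlo SEs) and 95% CI coverage
(accepted between 0.92 and 0.98) of $\beta_t$, $\beta_m$ and $\tau^2$;
300 null-model datasets for coverage of zero; 10,000 replicates per
sample size for the bias-correction property at $n \in \{5, 20, 83\}$;
10,000 participants per arm for the mixture-variance identity (tolerance
0.5 mmol/mol on a target of 16).

## Known limitations

* Similar arm SDs do not *prove* absence of treatment heterogeneity: the
  rank-coupled generator exhibits the counterexample. The method yields
  indirect evidence, informative because the masking scenario requires a
  rather implausible negative dependence.
* The corridor effect can compress verum-arm variability for reasons
  unrelated to heterogeneity; the variance-of-means check quantifies the
  phenomenon but cannot remove it.
* The weight convention follows the printed $2n-1$ inverse-variance rule
  for the bias-corrected outcome; the alternative $2(n-1)$ convention is
  available behind a flag, and with arm sizes in the tens to thousands
  the two are numerically almost indistinguishable.
* Wald/normal CIs and the chi-square variance interval are large-sample
  constructions; at a handful of trials the profile interval for
  $\tau^2$ is the only one that should be trusted.
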