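---
title: "The family social relations model and factor-score regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The family social relations model and factor-score regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famsrm)
```

## The model

A round-robin design in a four-member family (mother M, father F, target
adolescent T, sibling S) yields twelve ordered dyadic measurements
$X_{ij}$, $i \neq j$, where $i$ is the rater (actor) and $j$ the person
being rated (partner).  The social relations model (SRM) decomposes each
measurement additively,

$$X_{ij} = \mathrm{Fam} + \mathrm{Act}_i + \mathrm{Par}_j +
  \mathrm{Rel}_{ij} + \epsilon_{ij},$$

into a family effect, an actor effect (a rater's general level across all
partners), a partner effect (the level a person elicits from all raters),
a relationship effect, and measurement error.  With a single indicator
per dyad — the situation this package addresses — the relationship effect
cannot be separated from the error and the two are absorbed into a single
residual.

As a confirmatory factor model, the nine latent effects (one family, four
actor, four partner) load on the twelve indicators with loadings fixed to
one: the row of the $12 \times 9$ loading matrix $\Lambda$ for dyad
$(i,j)$ has ones at the family, $\mathrm{Act}_i$ and $\mathrm{Par}_j$
columns.  $\Lambda$ has rank 7: the family column equals the sum of the
four actor columns and also the sum of the four partner columns.  This
two-dimensional null space drives everything unusual about Bartlett
scoring below.

The factor covariance $\Psi$ is diagonal except for the four *generalized
reciprocities* (same-role actor–partner covariances $\sigma_r$); the
residual covariance $\Theta$ is diagonal except for the six *dyadic
reciprocities* ($\mathrm{cov}(\epsilon_{ij}, \epsilon_{ji})$).  The
model-implied covariance is $\Sigma = \Lambda \Psi \Lambda' + \Theta$, so
each dyad's variance decomposes as family + actor + partner +
relationship ([`variance_decomposition()`]).

Twenty-one SRM means would correspond to only twelve observed means, so
the usual identification constraints are imposed: actor means sum to
zero, partner means sum to zero, and relationship means are doubly
centered (seven independent constraints).  Under these constraints the
decomposition of any twelve-vector of dyad means is unique and is
computed in closed form by `srm_means_from_observed()`; the family mean
is the average of the twelve entries, and actor/partner means are the
weighted row/column means of the two-way table with empty diagonal,
$\mathrm{Act}_i = \tfrac98\,\overline{row}_i + \tfrac38\,\overline{col}_i
- \tfrac32\,\overline{grand}$ (family size 4).  The same weights applied
to a single family's raw values give the classical ANOVA scores
(`anova_scores()`).

Internally the factors are centered and all means are carried in the
saturated mean structure $\mu(\theta)$; the measurement intercepts are
zero.  Score formulas therefore operate on $x - \hat\mu$.

## Estimation

`fit_srm_ml()` (complete families) and `fit_srm_fiml()` (all families,
pattern-wise observed-data likelihood) maximize the multivariate-normal
likelihood over 43 free parameters: 13 factor (co)variances, 18 residual
(co)variances, and 12 mean parameters.  Families are grouped by
missing-data pattern and each pattern contributes through its
sufficient statistics, so the cost scales with the number of distinct
patterns rather than with $n$.  The deviance gradient is computed
analytically (chain rule through $\Sigma = \Lambda\Psi\Lambda' + \Theta$)
and passed to `nlminb`; standard errors come from the observed
information, obtained by central differences of the analytic gradient.

Three deliberate choices:

* **Variances are optimized unconstrained** (no log transform).  Improper
  Heywood-type solutions can therefore occur, exactly as in standard SEM
  software; they surface as a non-positive-definite fitted $\Sigma$.
* **Convergence** requires both optimizer success and a positive-definite
  fitted $\Sigma$ (smallest eigenvalue above $10^{-10}$).  Non-converged
  fits are still returned for inspection, but the Monte-Carlo harness
  excludes them from all summaries and reports the convergence rate.
* **Starting values** are moment-based: ANOVA-score variances and
  covariances for the components, available-case means for $\mu$.
  `fit_joint_sem(..., warm_start = TRUE)` optionally starts the joint
  model from a preliminary measurement-only FIML fit.

`fit_joint_sem()` is the one-step SEM comparator.  In the
`srm_as_predictor` direction the role-specific outcomes are appended to
the indicator vector ($y_r$ regressed on Fam, $\mathrm{Act}_r$,
$\mathrm{Par}_r$) and the joint 16-variable normal likelihood is
maximized.  In the `srm_as_outcome` direction the model is MIMIC-like:
the latent effects are regressed on observed predictors $z_1,\dots,z_K$
treated as fixed regressors, so the conditional mean of the indicators is
$\mu + \Lambda\Gamma z$.  Identification again requires that actor
coefficients sum to zero per predictor (and likewise partner
coefficients); the M, F, T rows are free and the S row is derived, with
delta-method standard errors for the derived row.

## Factor scores

For a fitted measurement model, the package provides:

* **Regression (Thurstone–Thomson) scores**
  $\hat\eta = \Psi\Lambda'\Sigma^{-1}(x - \mu)$, equal to
  $(\Psi^{-1} + \Lambda'\Theta^{-1}\Lambda)^{-1}\Lambda'\Theta^{-1}(x-\mu)$
  when $\Psi$ and $\Theta$ are invertible.  These shrink toward the
  factor mean and are conditionally biased, but give unbiased regression
  coefficients when used as *predictors*.
* **Regression FIML scores** (`regression_fiml_scores()`): per
  missing-data pattern, $\Lambda$, $\Theta$, $\mu$ are subset to the
  observed indicators and the same weighting applied.  A family with no
  observed indicators is shrunk fully to the factor mean (score zero).
* **Bartlett scores**: the weighting
  $(\Lambda'\Theta^{-1}\Lambda)^{-1}\Lambda'\Theta^{-1}$ requires a
  full-rank loading matrix.  For the SRM the $9\times 9$ system has rank
  7, so the `residual` and `gls` variants fail with an explicit rank
  error and the `pinv` variant substitutes the Moore–Penrose
  pseudo-inverse.  `bartlett_fiml_scores()` is the per-pattern version; a
  family with nothing observed gets missing scores, because the Bartlett
  estimator has no prior mean to fall back on.
* **ANOVA scores**: the classical weighted sum scores; any missing dyad
  makes all nine scores missing for that family.

Numerical choices: the pseudo-inverse treats singular values below
$10^{-10}$ times the largest as zero.  The rank deficit of the SRM system
is structural (exactly 7 of 9 for *any* positive-definite $\Theta$), and
a tight relative tolerance prevents estimation noise in $\hat\Theta$ from
spuriously changing the detected rank.  Scores are reported as deviations
from the factor means; `add_means = TRUE` adds the estimated family,
actor and partner mean components back.

## Why Bartlett scores fail here: the rank-7 projector

With the pseudo-inverse, the product of the Bartlett score coefficients
and the loading matrix is not the identity but the orthogonal projector
onto the row space of $\Lambda$:

$$P = (\Lambda'\Theta^{-1}\Lambda)^{+}\Lambda'\Theta^{-1}\Lambda,$$

a symmetric idempotent rank-7 matrix that is invariant to the choice of
positive-definite $\Theta$ (`bartlett_projection_matrix()`).  Its entries
are simple fractions: $2/3$ at (family, family), $1/6$ between family and
every actor/partner, $19/24$ on the actor/partner diagonal, $-5/24$
within the actor (and partner) block, $1/24$ between actors and partners.
Hence $E(\hat\eta \mid \eta) = P\eta$, and a regression that uses pinv
Bartlett scores as the *dependent* variable estimates $P\Gamma$ rather
than $\Gamma$ (`predicted_bartlett_bias()`).  Whenever actor and partner
coefficients sum to zero per predictor, the expected family row is
exactly $2/3$ of the true family row.  The Monte-Carlo harness reproduces
this: simulated mean Bartlett coefficients sit at the projector-predicted
values, not at the truth (small residual deviations of order one
Monte-Carlo standard error remain because $\hat\Theta$ and $\hat\mu$ are
estimated per replicate; the package reports both the analytic and the
simulated values rather than forcing agreement).

For regression scores used as predictors the corresponding identity
$(FSC_R\,\Sigma\,FSC_R')^{-1} FSC_R\,\Lambda\Psi = I$ certifies
unbiasedness; `regression_identity_check()` verifies it numerically,
restricted to the identified row-space when the loading matrix is rank
deficient.

## Two-step factor-score regression

`fsr_predictor()` and `fsr_outcome()` implement step 3: OLS of an outcome
on (family, actor, partner) scores, or of each effect score on the
predictors.  Naive standard errors are the classical homoskedastic OLS
ones — deliberately, since treating estimated scores as fixed is exactly
the practice whose under-coverage the comparison quantifies.
`fsr_bootstrap()` resamples *families* with replacement and re-runs the
whole pipeline (measurement fit, scores, regression) per resample;
non-converged resamples are redrawn up to $3B$ attempts.  The default
$B = 500$ is a conventional choice.  When an effect is truly zero the
naive and bootstrap standard errors agree closely; for nonzero effects
the bootstrap is wider.

## The synthetic-data generators and what they emulate

The generators *are* the study conditions and their defaults are fixed
accordingly: family variance 1, actor variances 1, partner variances 0.5,
relationship(+error) variances 1.5, generalized reciprocities $\pm 0.05$,
dyadic reciprocities 0.02.  Which roles carry $+0.05$ versus $-0.05$ is
not dictated by the design; the package fixes $+0.05$ for M and T and
$-0.05$ for F and S (overridable through `srm_parameters()`).

* `generate_predictor_condition()`: draws latent effects and residuals
  from the model-implied multivariate normal and builds role-specific
  outcomes $y_r = \gamma_1\mathrm{Fam} + \gamma_2\mathrm{Act}_r +
  \gamma_3\mathrm{Par}_r + e_r$.  The default slopes are $(0.3, 0.2, 0)$
  for every role with unit outcome residual variance — a deliberate mix
  of nonzero effects and one zero effect per role so that bias and
  type-I error can be assessed in the same run.  These slopes are
  package defaults, not reproduction targets.
* `generate_outcome_condition()`: draws $z_1, z_2, z_3$ i.i.d. standard
  normal (mutually independent), sets $\eta = \Gamma z + \zeta$ with the
  SRM-structured disturbance, and emits the indicators.  The default
  $\Gamma$ has family row $(0.021, -0.005, -0.094)$, zero partner rows,
  and nonzero zero-sum actor rows.

Missingness mechanisms (`apply_missingness()`) delete cells independently
at the stated rate within the stratum of families whose conditioning
variable lies strictly below its empirical first quartile
(`stats::quantile()` type 7, R's default interpolation).  The family-level
missing rate — the fraction of families with at least one missing dyad —
has closed forms under these mechanisms: $0.25(1 - 0.6^6) \approx 23.8\%$
for the outcome-condition dyad-dependent mechanism and
$0.25(1 - 0.75^3) \approx 14.5\%$ for the predictor-condition
outcome-dependent one, and the package defines "missing rate" as exactly
this family-level share because it is the definition consistent with
those figures.

What the generators do *not* emulate: bounded 5-point response scales
(everything is Gaussian), non-normality, families of other sizes,
longitudinal structure, or missingness beyond the four stated mechanisms.
Passing tests therefore certify the estimators' behavior under the
model's own assumptions, not robustness to their violation.

## The Monte-Carlo harness

`run_study()` runs generate → delete → fit/score/regress per replicate
for any subset of methods (joint SEM, regression / regression-FIML /
Bartlett-pinv / Bartlett-FIML / ANOVA scores) and summarizes per
coefficient via `summarize_replicates()`:

* **bias z** $= (\mathrm{median} - \mathrm{truth}) /
  (1.2533\,\mathrm{sd}/\sqrt{R})$ — the median is used to damp outliers,
  and $1.2533$ is the asymptotic efficiency factor of the median; values
  beyond $|z| = 1.96$ flag bias;
* **coverage** of the Wald 95% interval built from each replicate's
  standard error;
* **MAD**, the median absolute deviation from the true value;
* the convergence rate and mean family-level missing rate.

Replicates where a method does not converge are excluded from that
method's statistics and counted; cells with fewer than 30 converged
replicates are flagged rather than summarized.  A master seed spawns
per-replicate seeds, so identical configurations are bit-reproducible.

Problem sizes used by the package's own test suite: the method-comparison
properties are checked at $n = 500$ families with 200 replicates
(complete-case SEM coverage and type-I error; regression-FIML bias under
MAR deletion; the Bartlett projector prediction), and FIML parameter
recovery at a single $n = 5000$ dataset under the dyad-dependent
mechanism.  These sizes were chosen as the smallest at which the binomial
and Monte-Carlo error bands are informative for the claims being checked.

## Known limitations

* ANOVA scores require complete families and are biased as outcomes
  unless missingness is completely at random; they are included as the
  widely-used baseline, not as a recommendation.
* No REML estimation, no Bayesian machinery, and no Croon or
  Hoshino–Bentler corrections: none of the implemented score estimators
  is simultaneously usable as outcome *and* predictor, and correcting
  Bartlett scores in the rank-deficient case is an open problem.
* Fit indices (CFI/SRMR/RMSEA) are out of scope; model adequacy is judged
  here by convergence, positive definiteness, and likelihood comparisons.
* Fixed four-role family structure; no self-ratings; one indicator per
  dyad (relationship and error confounded).
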