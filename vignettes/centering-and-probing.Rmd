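---
title: "Centering semantics in moderated and polynomial OLS regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centering semantics in moderated and polynomial OLS regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centermod)
```

## The model and what centering does to it

centermod fits ordinary least-squares models of two families:

* moderation: $\hat Y = b_0 + b_1 X_1 + b_2 X_2 + b_3 X_1 X_2$
* polynomial: $\hat Y = b_0 + b_1 X + b_2 X^2$

Mean centering a predictor is the subtraction of a constant from every score.
It is a pure location shift: it does not change a variable's dispersion or its
structural relationship to the other predictors (essential collinearity), only
the correlations that exist because of scaling (non-essential collinearity),
such as the typically enormous correlation between $X$ and $X^2$ when the mean
of $X$ is far from zero.

Two consequences drive the whole package design:

1. **First-order coefficients in these models are conditional effects.** With
   a product term present, $b_1$ is the slope of $X_1$ *at* $X_2 = 0$; with a
   quadratic term, $b_1$ is the slope of the parabola *at* $X = 0$. Centering
   moves the zero, so it changes $b_1$, $b_2$, and the intercept — not because
   any effect got weaker or stronger, but because a *different conditional
   effect* is being estimated. These coefficients are never main effects,
   centered or not.
2. **Everything of substantive interest is invariant.** The highest-order
   coefficient with its SE, $t$, $p$ and CI; $R^2$ and adjusted $R^2$; fitted
   values and residuals; hierarchical $\Delta R^2$ increments; semipartial
   correlations assessed in the step where a term enters; and any conditional
   effect evaluated at an equivalent point (raw 85 is centered $85 - \bar X$)
   are identical under every choice of centering constants, to double
   precision. Centering is a relabeling of zero, nothing more.

`audit()` turns claim 2 into a machine check: it refits one model spec under
several centering schemes — always recomputing product/power columns from the
transformed base columns — and partitions every reported quantity into an
*invariant block* (verified to a tolerance, default relative 1e-9) and a
*changed block*, each changed entry annotated with the conditional
interpretation it now carries ("conditional effect of x1 when x2 = 85"). A
discrepancy in the invariant block is raised as an error, because these
identities hold mathematically: a violation can only mean the
derived-terms-rebuilt discipline was broken, never that the data are special.

## Estimation and numerical choices

* `fit_ols()` solves via QR factorization, not inversion of $X'X$. Rank is
  detected with a relative tolerance of 1e-10 on the diagonal of $R$; a
  deficiency names the offending columns. The old textbook fear of "division
  by a near-zero determinant" does not apply to orthogonal factorizations in
  double precision, which is also why severe non-essential collinearity is
  harmless here.
* Coefficient covariance is $\hat\sigma^2 (X'X)^{-1}$ with
  $\hat\sigma^2 = SSE/(n-p)$; $p$-values are two-sided from the $t$
  distribution with $n - p$ df, and CIs are $b \pm t_{n-p}\,SE$ (default level
  0.95). No small-sample CI adjustment is applied: plain $t$ intervals
  reproduce the reference software's output to print precision.
* Sample SDs use the $n-1$ divisor everywhere (centering resolution,
  `standardize()`, z-scoring for betas), matching SPSS/Jamovi/JASP.
* Missing data: listwise deletion over the variables a model actually uses,
  with a logged count of dropped rows.
* Centering constants are carried at full precision in the design metadata;
  any rounding (3 decimals in printed tables) is purely a display concern.

## Term semantics

A `model_spec()` holds terms built from `term_raw()`, `term_centered()`,
`term_standardized()`, `term_product()`, `term_power()`. Products and powers
are *derived*: they are recomputed after their components are transformed, and
it is an error to center a derived column in place — multiply-then-center and
center-then-multiply are different models, and the builder never silently
substitutes one for the other.

A `center_scheme()` maps variables to constants (`"mean"` or any number) and
applies to **raw terms only**; a term explicitly declared centered or
standardized keeps its declaration. This makes `audit(spec, data, schemes)` a
comparison of pure reparameterizations of a single model, which is the
invariance being certified. Mixed specifications (raw first-order terms next
to a product of centered ones) are expressible but trigger a warning: their
first-order coefficients are conditional effects at a zero the analyst
probably did not intend.

## Probing

`conditional_slope(fit, focal, moderator, h)` returns
$b_1 + b_3 h$ with delta-method SE
$\sqrt{V_{11} + h^2 V_{33} + 2h V_{13}}$, $t$ with the full model's residual
df, and the raw-scale equivalent of $h$ recovered from provenance.
`quadratic_slope()` is the analogue $b_1 + 2 b_2 x_0$. Both are identical (to
1e-9, verified by test) to the brute-force alternative of recentering the
moderator at the probe point, rebuilding the product, and refitting. Probe
values are interpreted on the fitted parameterization's scale; reports print
the raw-scale meaning so "at 0" is never ambiguous. The default pick-a-point
strategy is mean ± 1 SD, and arbitrary values are first-class.

Main effects require a model *without* the product term: `hierarchical_fit()`
fits nested steps and tests each increment with
$F = (\Delta R^2/m) / ((1-R^2_{step})/df_{resid})$. Plot data
(`interaction_plot_data()`, `parabola_plot_data()`) always evaluates the full
final-step equation; asking for plot data from a reduced fit is a hard error,
not a warning, because no correct plot can be derived from the reduced model.

## Effect sizes: default β, corrected β, sr, VIF

Common packages compute β by z-scoring every *final* design column — including
an already-formed product or power, which they cannot know is special. That
order of operations is wrong for derived terms, and its result is not even
centering-invariant. `beta_default()` reproduces it (flagged with a caveat)
because users will meet those numbers in other software; `beta_correct()`
z-scores the base variables and the response first, rebuilds the derived
terms from the z-scores, and reports the unstandardized coefficients of that
fit — a quantity invariant to any prior centering, since z-scoring absorbs
location.

`semipartial()` computes $sr_i = \mathrm{sign}(t_i)\sqrt{R^2 - R^2_{(-i)}}$
by drop-one refits, cross-checked internally against
$t_i\sqrt{(1-R^2)/df}$. $sr^2$ is the variance uniquely explained — the
drop-one $\Delta R^2$ — which is why sr is the better default effect size;
$|\beta_{default}| = |sr|\sqrt{VIF}$ exactly, so β inflates apparent
importance by $\sqrt{VIF}$ whenever predictors are correlated.

One subtlety the audit encodes deliberately: in the **full** model the
semipartial correlations of the *first-order* terms are conditional
quantities — they move with the centering scheme exactly as $b_1$ and $b_2$
do, because dropping a first-order column from differently-parameterized full
models leaves different column spaces. What is invariant is the sr of each
term assessed *in the step where it enters the hierarchy*: Step-1 sr for the
first-order terms and full-model sr for the product/power term. The audit's
`sr_hierarchical` entry is exactly that vector, and the tests assert both the
invariance of that vector and the non-invariance of full-model first-order sr.

## The synthetic fixtures

`generate_interaction()` / `generate_quadratic()` are seeded (Mersenne-Twister
with inversion sampling, recorded in output metadata) and emulate the worlds
the package's demonstrations need:

* interaction: n = 30, predictor means (74.93, 77.67) far from zero, SDs
  (8.94, 10.50), correlation 0.649, coefficients (160, 0.85, 0.54, −0.03),
  noise SD 5.4. Means far from zero make the non-essential collinearity
  severe (base–product correlations near 0.9, product VIF in the hundreds),
  which is precisely the regime the centering debate worries about.
* quadratic: n = 31, mean 53.61, SD 12.08 (mean/SD ≈ 4.4 makes
  $r(X, X^2) > 0.99$ before centering), coefficients (−76.53, 5.727, −0.055),
  noise SD 15.5.

The noise SDs are back-derived once from the demonstrations' printed summary
statistics (an intercept SE of ≈1 at n = 30 implies residual SD ≈ 5.4; an
outcome SD of 18.41 with final $R^2 = 0.293$ implies residual SD ≈ 15.5) and
are not tuned thereafter.

The generators draw exact bivariate-normal predictors and Gaussian noise.
They do **not** emulate bounded support (relative humidity cannot leave
[0, 100], exam times cannot be negative — the Gaussian tails can), discrete
recording (integer minutes), heteroscedasticity, or measurement error. A green
property suite therefore establishes the algebraic and sampling behavior of
the estimators under the stated Gaussian world, not robustness to real-data
pathologies. The centering-invariance results, however, are algebraic
identities and hold for any numeric dataset whatsoever.

## Design choices that were genuinely open

* **Audit on additive models.** The audit is primarily about models with a
  derived term, but it accepts additive models too: there the first-order
  coefficients are themselves invariant (the intercept absorbs the shift) and
  the report annotates them as constant (additive) effects — a useful
  contrast when teaching what the product term changes.
* **df for conditional tests** is the full model's residual df (n − p of the
  model actually fitted), since the probe is a linear combination of that
  model's coefficients.
* **sr sign** follows the sign of the term's t statistic; the magnitude comes
  from the signless $\Delta R^2$.
* **Reports** always annotate first-order lines with their conditional
  interpretation and never call them main effects; the wording is fixed, not
  configurable, to keep the guardrail.
* **Seeds**: every generator call takes an explicit integer seed and restores
  the caller's RNG state, so fixtures are reproducible and tests cannot
  contaminate each other.

## Limitations

OLS with continuous predictors only: no weighted/robust/generalized variants,
no categorical predictors or contrast coding, no Johnson–Neyman regions, no
three-way interactions (probing supports one product of two variables or one
squared term per call). Standardization-scheme audits beyond location shifts
(i.e. scale changes) are out of scope.
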