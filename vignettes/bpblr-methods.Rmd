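---
title: "Methods: the bivariate polynomial binary logit model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the bivariate polynomial binary logit model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpblr)
```

## The model

Two binary responses $(Y_1, Y_2)$ are observed per unit together with
$k$ continuous predictors. Their joint distribution per unit is a
four-cell multinomial over the $2\times 2$ table with cells
$\pi_{gh} = P(Y_1 = g, Y_2 = h)$, and it is parameterized by three
quantities: the two marginal success probabilities $\pi_1, \pi_2$ and
the global odds ratio
$\psi = \pi_{00}\pi_{11}/(\pi_{01}\pi_{10})$. Each of the three gets
its own link equation, polynomial in every predictor:

$$
\operatorname{logit} \pi_1(x) = \alpha_1 + \sum_{j=1}^k \beta_{1j}^T x_j^{(r_j)},
\qquad
\operatorname{logit} \pi_2(x) = \alpha_2 + \sum_{j=1}^k \beta_{2j}^T x_j^{(r_j)},
\qquad
\ln \psi(x) = \alpha_3 + \sum_{j=1}^k \gamma_{j}^T x_j^{(r_j)},
$$

with $x_j^{(r_j)} = (x_j, x_j^2, \ldots, x_j^{r_j})^T$. The degree
vector $r = (r_1, \ldots, r_k)$ controls both the flexibility and the
parameter count $p = 3 + 3\sum_j r_j$; the polynomial form lets the
log-odds bend without abandoning the linear-predictor machinery.

Modelling the dependence through $\psi$ (the Plackett construction,
also used by Dale's global cross-ratio model) has two virtues: the
marginal models remain ordinary logistic regressions, and $\psi$ has a
direct epidemiological reading — $\psi = 1$ is independence,
$\psi > 1$ positive association. Given $(\pi_1, \pi_2, \psi)$ the cell
$\pi_{11}$ is the admissible root of a quadratic; the package computes
it in the cancellation-free form

$$
\pi_{11} = \frac{2\psi \pi_1 \pi_2}{a + \sqrt{a^2 + b}}, \qquad
a = 1 + (\psi - 1)(\pi_1 + \pi_2), \quad
b = -4\psi(\psi - 1)\pi_1\pi_2,
$$

which is algebraically identical to the textbook root
$(a - \sqrt{a^2+b})/(2(\psi-1))$ but stable as $\psi \to 1$ (the
$|\psi - 1| < 10^{-10}$ branch returns the independence product
$\pi_1\pi_2$ outright; the two branches agree to $10^{-8}$ across the
switch, which the test suite checks). The same formula covers
$\psi < 1$; the round-trip property $\pi_{00}\pi_{11}/(\pi_{01}\pi_{10})
= \psi$ is property-tested on both sides of 1. The remaining cells
follow from $\pi_{10} = \pi_1 - \pi_{11}$,
$\pi_{01} = \pi_2 - \pi_{11}$,
$\pi_{00} = 1 - \pi_1 - \pi_2 + \pi_{11}$.

Assumptions worth stating: units are independent; each unit is a
single multinomial trial; the dependence is fully captured by one
(unit-varying) odds ratio; predictors enter through raw integer powers
— no interactions, no fractional powers.

## Likelihood and score

With one-hot indicators $y_{gh,i}$ the log-likelihood is
$\ln L(\theta) = \sum_i \sum_{gh} y_{gh,i} \ln \pi_{gh,i}$. The
canonical parameter order is
$(\alpha_1, \beta_1\text{-block}, \alpha_2, \beta_2\text{-block},
\alpha_3, \gamma\text{-block})$, blocks following the design's
predictor-major, power-minor column order.

The analytic score is obtained by the chain rule through the Plackett
inversion. Implicit differentiation of the constraint
$\ln\pi_{11} + \ln\pi_{00} - \ln\pi_{10} - \ln\pi_{01} = \ln\psi$
gives, with
$\Delta_2 = (1/\pi_{11} + 1/\pi_{10} + 1/\pi_{01} + 1/\pi_{00})^{-1}$,

$$
\frac{\partial \pi_{11}}{\partial \eta_3} = \Delta_2, \qquad
\frac{\partial \pi_{11}}{\partial \pi_1} =
  \Delta_2\left(\frac{1}{\pi_{00}} + \frac{1}{\pi_{10}}\right), \qquad
\frac{\partial \pi_{11}}{\partial \pi_2} =
  \Delta_2\left(\frac{1}{\pi_{00}} + \frac{1}{\pi_{01}}\right),
$$

so with
$c_i = y_{11i}/\pi_{11i} - y_{10i}/\pi_{10i} - y_{01i}/\pi_{01i} +
y_{00i}/\pi_{00i}$ the per-unit derivative with respect to $\eta_3$ is
$\Delta_{2i} c_i$, and with respect to $\eta_1$ it is
$\pi_{1i}(1-\pi_{1i})\left[y_{10i}/\pi_{10i} - y_{00i}/\pi_{00i} +
c_i\,\partial\pi_{11}/\partial\pi_1\right]$ (symmetrically for
$\eta_2$). Slope entries are the intercept entry of their block times
the design feature. Because hand-derived scores for this model are
easy to get subtly wrong, the package treats the likelihood as primary
and validates the analytic score against a central finite-difference
oracle (step $10^{-6}$, relative tolerance $10^{-5}$) over random
parameter/dataset pairs with degrees up to 3 — both in the routine
suite and in a 50-case acceptance block. Those comparisons are run
away from the probability clamps (below), where the surface is by
construction non-smooth and a derivative comparison is meaningless.

## BHHH estimation

The information matrix is approximated by the BHHH outer-product sum
$B = \sum_i g_i g_i^T$ over per-observation scores $g_i$ — the form
the method defines. (A variant built from the outer product of the
*total* gradient is rank one and necessarily singular for $p > 1$; it
cannot drive the update.) The iteration is

$$\theta^{(t+1)} = \theta^{(t)} + s_t\,B^{-1} q(\theta^{(t)}),$$

with an Armijo line search on $s_t \in \{1, 1/2, 1/4, \ldots\}$
(sufficient-decrease fraction $10^{-4}$, up to 30 halvings, a
machine-precision allowance of $10^{-12}(1+|\ln L|)$ so exact ties do
not stall the search). Singular $B$ triggers a ridge
$\lambda I$ with $\lambda = 10^{-8}\operatorname{tr}(B)/p$, escalated
multiplicatively if needed; if no direction can be produced the fit is
returned flagged. Non-convergence is a reported state, never an
exception.

Convergence is declared when

1. the parameter-change max-norm falls at or below $\varepsilon$
   (default $10^{-6}$; max-norm chosen over the Euclidean norm so the
   criterion does not loosen as $p$ grows, and configurable in spirit
   by scaling $\varepsilon$), or
2. the proposed full step is already below $\varepsilon$, or
3. two consecutive accepted steps improve the log-likelihood by less
   than $10^{-10}(1+|\ln L|)$ while the parameter change is below
   $10^3\varepsilon$.

Rule 3 deserves a note. At the study's scale ($n = 119$ with a weakly
identified association block) the outer-product approximation differs
enough from the true curvature that the iteration converges linearly:
the likelihood reaches its maximum (verified against a BFGS oracle
during development: identical log-likelihood, parameters within
$10^{-3}$) while the step norm can hover just above a tight parameter
tolerance for hundreds of iterations. Relative-likelihood convergence
is the standard supplementary criterion for BHHH implementations, and
it is reported as convergence only when the parameters are also
essentially still. Default `max_iter` is 500 for the same reason.

Genuine failures are still reported as such: with very few discordant
units the odds-ratio block can quasi-separate ($\hat\psi \to \infty$),
the likelihood keeps creeping along a boundary ray, and no rule fires
— which is exactly the honest outcome.

Starting values: each marginal logit block from an ordinary logistic
fit (`glm.fit`), $\alpha_3$ from the pooled sample log odds ratio
(+0.5 continuity correction on zero cells), $\gamma = 0$; on failure a
block falls back to zeros with the marginal log-odds intercept.

### The intercept-only null model

The three-parameter model saturates the pooled $2\times 2$ table, so
its MLE has a closed form: fitted cells equal observed cell
proportions, $\hat\alpha_3$ is the sample log odds ratio. The package
still runs BHHH to tolerance from the closed-form start (one
iteration) and asserts the closed form as a postcondition in its
tests; deviance is $-2\ln L(\hat\theta)$ throughout.

## Inference and degree selection

The simultaneous test compares the full model with the intercept-only
null: $G^2 = 2(\ln L_{\text{full}} - \ln L_{\text{null}})$, referred
to $\chi^2_v$ with $v = (3 + 3\sum_j r_j) - 3 = 3\sum_j r_j$. The
implementation computes $G^2$ both as a deviance difference and as the
direct sum of observed-cell log-probability ratios and insists the two
agree to $10^{-8}$; negative values beyond $-10^{-8}$ raise an error
(an optimizer-failure signal), tiny negatives clamp to zero.

Per-parameter inference uses Wald $z$ statistics with standard errors
from the inverse of the final $B$. This is an approximation on two
counts — the normal reference is asymptotic and the outer-product
information is exact only in large samples — and the type-I error of
the $\gamma$-block Wald tests is checked by simulation rather than
assumed. Where sharper per-parameter inference matters, a
likelihood-ratio test of the single parameter (refit without it) is
the fallback a user can build from the exposed pieces.

Degree selection is an exhaustive grid over
$\{1, \ldots, d_{\max}\}^k$, each combination fitted and compared by
deviance; rows are emitted in lexicographic degree order, ties in the
minimum are broken by smallest total degree $\sum_j r_j$, then
lexicographically (parsimony first — a deliberate choice where the
selection criterion alone is silent). Each grid fit warm-starts from
the all-degree-1 fit padded with zeros, which both cuts runtime and
guarantees every higher-degree fit starts at (hence ends at or above)
the base fit's likelihood. The univariable screen fits one predictor
at a time at each degree ($v = 3d$) and passes a predictor that is
significant at any tested degree; a non-convergent cell is recorded as
missing rather than counted as evidence against the predictor.

VIF diagnostics are computed on the raw degree-1 predictors
($1/(1-R_j^2)$ via least squares), matching how the screen is used in
practice; powers of a predictor are of course collinear with it, which
is a property of the model basis, not something VIF is asked about.

## Numerical choices

* probability clamp $\varepsilon_p = 10^{-12}$ on marginals, and
  $\pi_{11}$ confined to its Fréchet box
  $[\max(\varepsilon_p, \pi_1+\pi_2-1+\varepsilon_p),\,
  \min(\pi_1,\pi_2)-\varepsilon_p]$ so all four cells stay positive
  before any logarithm;
* $\eta_3$ clipped to $\pm 35$ before exponentiation — beyond that the
  cells are at their boundary to machine precision anyway;
* raw (uncentered, unscaled) powers are the default so coefficients
  keep their natural units; `standardize = TRUE` z-scores each
  predictor before powering. For covariates whose scales span orders
  of magnitude (percentages near 100 vs growth rates near 5), raw
  squared terms make $B$ hopelessly ill-conditioned at moderate $n$,
  so every study-scale example in this package standardizes —
  estimates are then on the per-SD scale.

## The synthetic-data generator

`generate_predictors()` draws truncated normals by inverse-CDF
sampling (exact, no rejection loop), per-predictor
`(mean, sd, min, max)`; the `"paper-like"` preset carries the
published summary statistics of the five district covariates.
`generate_responses()` pushes a truth vector through the three links
and the Plackett inversion and draws each unit's cell from the
resulting four-outcome distribution. One master seed drives the two
sub-streams (`seed` for predictors, `seed + 1` for responses), so new
response sets can be drawn on fixed predictors.
`paper_like_scenario()` bundles the study conditions: $n = 119$, the
four screened covariates, intercepts that reproduce the observed
margins (41/119, 39/119) and log odds ratio $\ln(73\cdot 34/(5\cdot
7)) \approx 4.26$, and zero slopes.

What the generator emulates: the sampling model itself (so estimator
and test calibration checks are exact in distribution), the study's
size, covariate ranges, and dependence strength. What it does not:
spatial autocorrelation among districts, covariate correlation (an
independent-draws design; real literacy and schooling co-move),
measurement error, and any true covariate effects on poverty — so a
passing recovery or calibration suite validates the *method*, not any
substantive conclusion about real districts.

Problem sizes used by the validation suite, chosen to make Monte-Carlo
noise small relative to the tolerances while keeping the full run in
the low minutes: gradient checks at $n = 40$ over 50 cases; parameter
recovery at $n = 1000 \times 100$ replicates (median bias per
component below 0.1 on the logit scale, 3-SE coverage at least 95%);
type-I error of $G^2$ at $n = 500 \times 200$ replicates (empirical
size within $[0.01, 0.10]$ at $\alpha = 0.05$); grid-search behaviour
at the study scale $n = 119$.

## Limitations

* The BHHH covariance is a large-sample object; at $n \approx 119$
  with 20+ parameters, Wald SEs for the association block are rough
  and the simultaneous $G^2$ is the more trustworthy test.
* Quasi-separation of the odds-ratio block (few discordant pairs) is
  detected only through non-convergence, not through a dedicated
  diagnostic.
* The degree grid grows as $d_{\max}^k$; beyond $\sim 4096$
  combinations the search warns and a staged/greedy strategy (not
  provided) would be preferable.
* Dependence is a single global odds ratio per unit; models with
  richer dependence (e.g., covariate-specific cross-ratios beyond the
  polynomial form, or negative-dependence-focused parameterizations)
  are out of scope.
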