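---
title: "Methods: the adaptive decision-making battery and the informative-prior severity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the adaptive decision-making battery and the informative-prior severity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbdm)
```

`vbdm` implements a complete, simulation-testable pipeline for studying
impulsive value-based decision-making in addictive disorders: an adaptive
four-task behavioural battery, a synthetic longitudinal cohort, severity
outcome construction, and an informative-prior Bayesian regression engine
with directional probabilities and reverse-Bayes prior sensitivity. This
vignette explains the models, the tunable parameters, the numerical choices,
and what the simulation-based tests do and do not establish.

## The four decision models

Three discounting tasks and a mixed-gambles task each measure one facet of
impulsive choice through a single decision parameter:

* **Delay discounting.** The subjective value of an amount $A$ delayed by
  $D$ days declines hyperbolically, $V = A / (1 + kD)$. Larger $k$ (per day)
  means steeper devaluation of the future.
* **Probability discounting (gains and losses).** The same hyperbola applied
  to the odds against winning, $\theta = (1 - p)/p$:
  $V = A / (1 + k\theta)$. For gains a lower $k$ indicates greater
  risk-seeking; in the loss task both options are losses (negative amounts)
  and a lower $k$ indicates lower risk-seeking to avoid certain losses. The
  odds-against form is the standard hyperbolic parameterisation for
  probability discounting; the battery's published description says only
  "hyperbolic", and this is the design choice we fixed.
* **Loss aversion.** A 50/50 mixed gamble of gaining $G$ or losing $L$ has
  linear utility $U = 0.5G - 0.5\lambda L$ against a rejection utility of 0;
  $\lambda > 1$ means losses loom larger than gains.

Choices are linked to values by a logistic (softmax) rule with one
inverse-temperature $\beta \ge 0$ per task,
$P(\text{B}) = 1/(1 + e^{-\beta(V_B - V_A)})$. The behavioural battery this
package re-creates does not name its noise model; the logistic link is
required to make sequential Bayesian updating well-defined and is the
convention of the adaptive-design literature this battery descends from. We
flag it as a reconstruction, not a documented fact about the original
implementation.

## The adaptive battery

Estimation runs on a discrete joint grid over the log decision parameter and
$\log\beta$, starting uniform:

| grid | range | nodes | rationale |
|---|---|---|---|
| $\log k$ | $[-7, 2]$ | 41 | covers reported human discount rates for both delay (per day) and odds-against units |
| $\log\lambda$ | $[-2, 2]$ | 41 | $\lambda \in [0.14, 7.4]$, generous around the typical 1–3 |
| $\log\beta$ | $[-3, 2]$ | 11 | random responding to near-deterministic choice |

A uniform initial grid is the reproducible default; the update multiplies
each node's mass by the likelihood of the observed choice under that node's
parameters and renormalises (total mass is restored to 1 within $10^{-9}$,
enforced by tests). Offer construction places each trial at the indifference
point of the current posterior-mean parameter (posterior mean of the log
parameter, exponentiated): in the discounting tasks the certain/sooner
amount is set against a fixed 10 € delayed or probabilistic amount, rounded
to 0.01 € and clipped to [0.30, 10.00] €; the delay or probability is drawn
uniformly from its menu (3/7/14/31/61/180/365 days; 2/3, 1/2, 1/3, 1/4,
1/5). In the mixed-gambles task the loss is drawn on a 0.50 € lattice in
[5, 20] € and the gain set to $\hat\lambda \times$ loss, clipped to
[1, 40] €. Discounting tasks run 30 trials, mixed gambles 40; the 10 €
gamble endowment is bookkeeping only. On the first trial the uniform grid
makes the posterior mean equal the grid midpoint, so the opening offer sits
at the grid-median parameter's indifference point. MAP extraction breaks
ties toward the smallest parameter value, deterministically.

Whether the original loss-probability task adapted the certain or the
probabilistic loss is not documented; we adapt the certain loss against a
fixed 10 € probabilistic loss, mirroring the gains task.

Parameter recovery (100 consistent agents per task, $\beta = 20$, true
parameters uniform over the central grid) yields Spearman correlations above
0.95 for all four tasks and median absolute errors well below the 0.5
(log-$k$) and 0.3 (log-$\lambda$) bands asserted in the tests. With
$\beta = 0$ (random responding) the parameter marginal stays centred with
large dispersion — choices carry no directional information.

## The synthetic cohort

`generate_cohort()` emulates the statistical structure the downstream
analysis assumes: three groups (SUD $n=100$, ND $n=118$, controls $n=120$;
total 338), one-year retention 0.92 (Bernoulli thinning; follow-up fields of
dropped participants are masked), demographics matched to the baseline
sample description (age 19–27, mean 21.8; IQ ~104; ~59% female; ~76% income
below 1500 €/month; Abitur rates by group).

Standardised decision parameters are drawn $N(\text{shift}, 1)$ with
group-minus-control shifts defaulting to the published likelihood (data-only)
means, and independently across tasks: no cross-parameter correlations were
reported, so independence is a stated simplification.

Criterion counts use a latent-Gaussian construction. Baseline class sums in
the case groups are $2 + \max(0, \text{round}(N(\mu, \sigma)))$ with
$(\mu, \sigma)$ = (0.8, 1.5) for SUD and (1.8, 2.0) for ND, anchoring the
case-group medians at 3 and 4; non-case classes are Bernoulli(0.25) at the
0/1 sub-diagnostic level, so the diagnostic invariants (≥ 2 own-class
criteria for cases, ≤ 1 elsewhere) hold by construction. One-year change is
generated on the latent standardised scale,
$z(\Delta) = \sum_t a_t z_t + \text{covariate terms} + N(0, \sigma_\epsilon)$,
with the prediction coefficients $a_t$ defaulting to the published
likelihood means and $\sigma_\epsilon = \sqrt{1 - \sum_t a_t^2}$ so the
latent change has unit variance. The latent change maps to integers as
baseline $+$ round($2 z(\Delta)$ + drift), clipped at 0 and the class cap:
2 criteria per latent SD is a fixed calibration (a 1-SD change should move a
mild case across about one severity specifier), and the drifts (−1 SUD,
−2 ND in the case groups) reproduce the observed median decline over the
year. Covariate effects default to zero but are configurable, so the
adjustment machinery is exercised without biasing recovery.

Quantities and frequencies per behaviour are generated log-normal
(sd 0.5 on the log scale) around per-group medians anchored to the
published consumption table, with engagement probabilities per behaviour
and group; follow-up quantities couple to the latent class-QFI change
(factor $e^{0.45 z}$). Rounding, floor effects, and the two-stage QFI
standardisation attenuate the QFI path relative to its generating
coefficients, so the quantitative recovery tests target the criteria
outcomes (where the end-to-end fitted coefficients reproduce the generating
values within ±0.05 averaged over 20 seeds); the QFI path is exercised
structurally. What passing tests show is internal consistency — the
pipeline recovers what it generates at the study's n — not that real data
share this generative structure: real criterion counts are not rounded
Gaussians, real parameters are correlated across tasks, and retention is
unlikely to be independent of severity.

## Severity outcomes

The quantity-frequency index multiplies the quantity per occasion by the
frequency category's weekly maximum: almost daily = 7, 3–4/week = 4,
1–2/week = 2, 1–3/month = 0.75, less than monthly = 0.25. The published
protocol defines the index as the maximum of the category times the quantity
without stating the scale; the weekly mapping is chosen because all printed
QFIs are per week, and the two sub-weekly categories (0.75 and 0.25
occasions/week) are the monthly maxima rescaled — whether the original
"less often than monthly" contributed a nonzero multiplier is unstated, and
the mapping is configurable. QFIs are z-standardised per behaviour in long
format (both waves pooled, so time trends survive), summed per class
(substance/non-substance), and re-standardised; z-scores use the sample sd
($n-1$), the convention of the original statistics package. Change
outcomes are follow-up minus baseline, z-standardised, with the baseline
value carried as a covariate against regression to the mean. The outlier
filter is the box-plot whisker rule (outside quartile ± 1.5 IQR excluded),
with linear-interpolation (type 7) quantiles fixed for reproducibility.

## The Bayesian engine

The regression engine is a Gibbs sampler for the normal linear model with
independent normal priors on coefficients and an inverse-gamma(0.01, 0.01)
prior on the residual variance — both full conditionals are exact, which
suits the "normal prior + linear regression" setting; no Metropolis step is
needed. The production chain follows the analysis protocol: 100,000
iterations, burn-in 5000, thinning 2 (47,500 kept), fully seed-reproducible.
Priors: group differences $N(0.37, 0.02)$ (delay, direction "greater"),
$N(-0.16, 0.02)$ (both probability tasks, "less"), $N(-0.44, 0.02)$ (loss
aversion, "less"); predictions $N(\pm 0.25, 0.016)$ — the normal whose
central 95% interval is exactly $[0, 0.5]$ (sd $0.25/1.959964 = 0.1276$), a
"medium association" belief. Covariates and the intercept get vague
$N(0, 10^4)$ priors so the coefficient of interest dominates; income and
education enter as binary indicators (< 1500 €/month; Abitur yes/no), as
they were reported.

Directional probabilities are the posterior mass on the hypothesised side
of zero: $100\,\Phi(\pm m/s)$ for a normal summary, the draw fraction for a
chain, with draws exactly at zero counting half (unbiased for discrete
ties). The SUD-vs-ND contrast is the elementwise difference of the two
group coefficients' paired draws from one fitted model. Published summary
rows are inverted to normal summaries by
$s = (\text{upper}-\text{lower})/(2 \times 1.959964)$, and the
precision-weighted combination
$m^\ast = (m_0/s_0^2 + m_1/s_1^2)/(1/s_0^2 + 1/s_1^2)$,
$1/s^{\ast 2} = 1/s_0^2 + 1/s_1^2$ serves as the closed-form oracle for the
sampler (tested to agree within Monte-Carlo error) and as the deterministic
reproduction of the published posterior column.

That two-number combination reproduces the published posterior means within
±0.01 for seven of the 24 analysis blocks — exactly the blocks where the
covariate-adjusted MCMC posterior happens to coincide with the naive
combination; elsewhere the covariates, which the two printed numbers cannot
carry, move the posterior. The same caveat applies to the published
reverse-Bayes thresholds: they are not reproducible from the printed
likelihood summaries alone, so `reverse_bayes()` takes the likelihood as
given, exposes both anchoring choices for the 0.1-step walk (`"start"`:
from the original prior mean; `"decimal"`: snapped to the 0.1 lattice), and
hard-codes no published thresholds. On the bundled delay-discounting ND
likelihood the decimal-anchored walk stops at a prior mean of 0.30, the
start-anchored walk at 0.27.

## Numerical choices and degenerate inputs

* Grid mass renormalised every update; an all-zero likelihood raises a
  diagnostic error instead of silently renormalising.
* The Gibbs coefficient draw uses the Cholesky factor of the conditional
  precision; rank-deficient designs are rejected up front.
* `standardize_long()` refuses constant columns (degenerate scale) rather
  than returning zeros; missing follow-up waves drop the participant with a
  warning.
* Tukey fences with zero IQR collapse onto the common value and exclude
  nothing.
* All randomness flows through R's RNG seeded once per entry point, so
  identical seeds replay bit-identically (choice logs, cohorts, chains).

## Problem sizes in the test suite

The suite exercises the battery at 100 agents per task (30–40 trials each),
conjugate-equivalence checks on five randomised regressions at a reduced
chain (burn-in 500, 10,000 iterations, thinning 2), and end-to-end
coefficient recovery over 20 cohort replicates of 338 participants — sizes
chosen so the whole suite completes in well under a minute on one core while
leaving the Monte-Carlo error an order of magnitude below the asserted
tolerances. The analysis scripts under `analysis/` run the production chain
length.

## Known limitations

* The adaptive offer rule uses the posterior-mean indifference point, not a
  full expected-information-gain criterion; it is a faithful, simpler stand-
  in for the cited adaptive framework's behaviour.
* The cohort generator matches first-order structure (group sizes, shifts,
  medians, retention) but not every marginal of real data (e.g. follow-up
  initiation of behaviours absent at baseline).
* The conjugate reproduction of published posteriors is exact only where a
  two-number summary suffices; blocks dominated by covariate adjustment
  cannot be recovered from the printed rows, by construction.
* Hierarchical models, Bayes factors, and reaction-time modelling are out
  of scope.
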