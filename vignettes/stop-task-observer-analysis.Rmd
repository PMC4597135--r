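---
title: "Methods: the Stop-task Bayesian observer analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Stop-task Bayesian observer analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selfprior)
```

## The model

On each trial of the Stop task a subject stops a sweeping ball on a target
and then points at where they believe it stopped. Working in target-centred
screen-pixel coordinates (rightward positive), let `p` be the performance
error (true stopping position) and `e` the estimation error (reported minus
true stopping position).

The observer combines two Gaussian cues:

* a **prior** over outcomes centred on the target (position 0) with SD
  $\sigma_p$ — the expectation of success set by the goal of the action;
* **sensory evidence** centred on the true stopping position `p`, with SD
  $\sigma_e$ and an optional constant spatial shift $s$ attributed to the
  pointing procedure (left hand, hence a leftward/negative default).

The reported position is the reliability-weighted combination

$$\hat{x} = w \cdot 0 + (1 - w)(p + s + \varepsilon), \qquad
  w = \frac{\sigma_e^2}{\sigma_p^2 + \sigma_e^2}, \qquad
  \varepsilon \sim \mathcal{N}(0, \sigma_e^2),$$

so the estimation error $e = \hat{x} - p$ is Gaussian with

$$\mathbb{E}[e \mid p] = -w\,p + (1 - w)\,s, \qquad
  \mathrm{SD}[e \mid p] = (1 - w)\,\sigma_e.$$

`predictive_law()` implements exactly this conditional. Two model variants
are fitted per subject: **model 1** (constrained; $s = 0$; 2 free
parameters) and **model 2** (evidence shift free; 3 parameters).

## Likelihood and its closed-form maximizer

The source analysis specifies the estimate equation and maximum-likelihood
fitting but not the likelihood itself; we derive it from the standard
Bayesian-observer construction above: the log-likelihood is the sum over
trials of the Gaussian log-density of `e` under the conditional law
(`loglik_bayes()`).

Because the conditional mean is linear in `p` with constant variance, the
likelihood is an ordinary linear regression in disguise. The identified
quantities are the slope $b = -w$, intercept $a = (1-w)s$ and ML residual
SD $\sqrt{RSS/n} = (1-w)\sigma_e$; the map back to
$(\sigma_p, \sigma_e, s)$ is bijective for $w \in (0,1)$:

$$w = -b,\quad s = \frac{a}{1-w},\quad
  \sigma_e = \frac{\sqrt{RSS/n}}{1-w},\quad
  \sigma_p = \sigma_e\sqrt{\frac{1-w}{w}}.$$

`closed_form_fit()` computes this exactly (model 1 uses regression through
the origin). `fit_mle()` re-maximizes numerically over
$(\log\sigma_p, \log\sigma_e[, s])$ with L-BFGS-B from the closed-form
start; on interior data the two must agree (this is an enforced invariant,
log-likelihood to 1e-6 and parameters to 1e-4 relative), and the numerical
route exists to handle boundary cases and to serve as a cross-check. The
log-parameterization guarantees positivity; optimization is deterministic
(fixed start, no stochastic restarts), so fits are exactly reproducible.

**Boundary policy.** When the OLS slope falls outside $(-1, 0)$ — no graded
bias toward the target — the inverse map diverges. We clip $w$ into
$[10^{-3}, 1 - 10^{-3}]$, flag the fit `boundary = TRUE`, and by default
(`pipeline_config(exclude_boundary = TRUE)`) drop flagged subjects from the
normalized-prior correlation analyses, because $\sigma_p$ is then an
artefact of the clip. SD bounds are $[10^{-3}, 10^4]$ px; a screen is 1024
px wide, so the upper bound is far outside any interpretable value.

## Model comparison

Models are compared per subject by BIC with the natural-log convention,
$k\ln n - 2\ell$; differences above 6 are labelled *strong* evidence, and
ties go to the 2-parameter model (`select_model()`). The cohort-level
summary is an exact two-sided sign test on the number of subjects whose BIC
favours model 2. Note an asymmetry inherent to the rule: when the generator
truly has no shift, strong evidence *for* model 1 is impossible at
$n \approx 100$, since model 2's log-likelihood is never lower and
$\mathrm{BIC}_2 - \mathrm{BIC}_1 = \ln n - 2\Delta\ell \le \ln n < 6 + 2\Delta\ell$
bounds the difference below 6 whenever $\Delta\ell \ge 0$. The package's
model-selection checks therefore score the BIC *winner*, not the strong
label, against the generating model.

## Exclusion rules and conventions

Preprocessing applies, in order:

1. **skip removal** — skipped trials carry no estimate and are dropped;
2. **slow-trial rule** — per subject, trials with estimation time above the
   subject mean plus 2 sample SDs are removed;
3. **subject rule** — per group, subjects whose mean estimation time
   (computed from retained trials) exceeds the group mean plus 3 group SDs
   are excluded.

Where the source analysis left the details open we fixed these conventions
(all configurable):

* **one-sided upper** for both rules — the stated motivation is
  interference from *longer* estimation times; a `sided = "two"` variant
  exists;
* **single pass** — means and SDs include the candidate outliers and are
  not recomputed after exclusion;
* **strict inequality** at the threshold — a value exactly at
  mean + k·SD is retained;
* **sample SD** (n − 1) in all descriptive statistics; the ML (n)
  denominator appears only inside the likelihood.

A consequence of the single-pass convention worth knowing: the largest
achievable z-score among `n` values is $(n-1)/\sqrt{n}$, so the 3-SD
subject rule cannot fire in groups smaller than 11 regardless of how
extreme the outlier is. That is fine for the 20-per-group design the
package targets but matters for small pilot cohorts.

## Normalized prior and prior accuracy

The normalized prior scales the fitted prior SD against the subject's own
performance-error SD into $(0, 1)$, equalling 0.5 exactly at equality. Two
formulas satisfy these constraints and the available description does not
distinguish them: the SD ratio $\sigma_p/(\sigma_p + s_{perf})$ and the
variance ratio $\sigma_p^2/(\sigma_p^2 + s_{perf}^2)$. The SD ratio is the
default (`normalized_prior(variant = "sd")`) as the simpler of the two;
the variance ratio sits behind `variant = "variance"`, and any report
should state which was used. Prior accuracy is
$|\mathrm{normalized\ prior} - 0.5|$: the distance of the prior from the
true performance distribution, direction ignored.

## Group statistics

* **t-tests** use the pooled-variance form, df $n_1 + n_2 - 2$ (a 20 + 20
  design gives df 38); effect size is Cohen's d.
* The **sign test** is exact (binomial tail enumeration, two-sided by tail
  doubling).
* **Spearman** correlations are Pearson correlations of mid-ranks with the
  t approximation for p; **partial Spearman** rank-transforms all
  variables, residualizes the ranks of x and y on the covariate ranks by
  least squares and correlates the residuals, with df reduced by the number
  of covariates. This rank-residual definition is the common convention;
  exact permutation p-values are not implemented.
* **ANCOVA** (`ancova_type3()`) fits
  `value ~ group + covariate + group:covariate` with effects (±1) coding
  and type-III sums of squares; the effect size is partial
  $\eta^2 = SS_{eff}/(SS_{eff} + SS_{err})$, the modern convention where a
  plain $\eta^2$ is ambiguous. The covariate is mean-centred by default so
  the group main effect is evaluated at the average covariate value;
  centring leaves the interaction test unchanged.
* **Bonferroni** families are caller-specified (`bonferroni(p, m)`): the
  analyses this package mirrors mix corrected and uncorrected p-values
  without stating family sizes, so the pipeline records `m` explicitly per
  test rather than guessing a family structure.

## The synthetic-data generator

`simulate_cohort()` emulates the statistical structure the analysis
assumes, from known ground truth, so every downstream stage is testable
without any subject data:

* 20 patients + 20 controls, 2 blocks × 52 trials (defaults);
* per-subject Gaussian performance errors (SD drawn uniformly from 35–65 px
  for patients, 25–50 px for controls; mean −10 px, a small leftward
  offset echoing reported near-target intercepts);
* estimates generated by the observer equations with prior-SD/performance-SD
  ratios of 0.45–0.85 (optimistic priors), evidence SDs of 18–40 px, and a
  leftward evidence shift of −20 ± 8 px;
* independent Bernoulli skips at 4% per trial (≈ 4 of 104), optionally
  topped up so the non-skipped count matches the design
  (`replace_skipped`);
* log-normal estimation times with medians 1.07 s (patients) and 0.88 s
  (controls) — the distribution family is our choice, made for positivity
  and right skew, the medians are the reported group values — and sdlog
  0.3, a typical response-time dispersion;
* optionally (`lde_link = TRUE`) a monotone map from levodopa dose
  equivalent (uniform 200–1800 mg/day, matching the observed clinical
  range) to the prior-width ratio (0.35 → 1.10 across the dose range, with
  multiplicative log-normal jitter, sdlog 0.12), producing the
  wider-priors-at-higher-dose structure used for end-to-end demos.

What the generator does **not** emulate: ball kinematics, sweep timing and
starting position (the sweep count is sampled as a label only and the
stopping time is decorative — no analysis consumes either);
touch-digitizer noise; within-session learning or fatigue (trials are
i.i.d.); medication-state fluctuation; any dependence between skipping and
trial difficulty. A green end-to-end test therefore establishes that the
pipeline correctly recovers the structure *this* generator puts in — not
that real patients behave like the generator.

## Numerical and degenerate-input choices

* Seeds: every simulation function takes an explicit seed and restores the
  caller's RNG state; two runs with the same seed are byte-identical.
* Fitting requires ≥ 4 trials and a non-constant performance-error vector;
  regression requires ≥ 3 trials. Violations are errors naming the subject.
* Fewer than 2 trials after exclusion flags the subject rather than
  applying the slow-trial rule; groups below 3 subjects skip the subject
  rule with a warning.
* `loglik_bayes()` refuses predictive SDs below 1e-12 instead of returning
  infinities.
* BIC ties (ΔBIC = 0) select model 1 by parsimony.
* Positions are stored as absolute screen pixels (1024 × 768 at 26 px/cm by
  default); all model mathematics is target-centred internally, and
  translating all positions by a constant provably leaves model-2 fits
  unchanged (tested).

## Known limitations

* The p-values for Spearman and partial Spearman use the t approximation;
  for n = 20 this is adequate for screening but exact permutation tests
  would be preferable at extreme ρ.
* The ANCOVA is the two-group, one-covariate, single-interaction case only.
* Boundary-flagged fits are excluded from prior correlations by default;
  with small cohorts this can meaningfully shrink n, and the exclusion
  count should always be reported (the pipeline's report lists it).
* Hierarchical (shrinkage) estimation across subjects, non-Gaussian priors
  and loss functions other than the posterior mean are out of scope.
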