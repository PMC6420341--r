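---
title: "Measuring face-body integration with adaptation aftereffects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring face-body integration with adaptation aftereffects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psyadapt)
```

## The scientific question

A body posture expressing one emotion biases how the facial expression it
accompanies is categorized: a disgusted face on an angry body is often called
angry. Does that bias arise *early* in the visual hierarchy, before the
stages whose adaptation produces facial-expression aftereffects, or *late*,
after them? Adaptation gives the two accounts opposite signatures. If
integration is early, adapting to a disgusted face in an angry body should
act like adapting to anger and push the point of subjective equality (PSE)
of a disgust-anger morph continuum the opposite way from the same face in a
disgusted body. If integration is late, the physical face drives adaptation
and the body context is irrelevant to the aftereffect, however strongly it
biases categorization.

`psyadapt` implements the complete measurement chain for this logic:
Psi-adaptive 2AFC test sessions, cumulative-Gaussian psychometric fits with
a bootstrap goodness-of-fit screen, PSE-shift aftereffect scores,
signal-detection bias indices for the categorization task, and the group
statistics (paired and one-sample t tests with Hedges' g, within-subject
2x2 ANOVA contrasts, directional JZS Bayes factors with robustness sweeps,
Bayesian Pearson correlations) — together with a synthetic-observer
generator that implements both integration hypotheses so the whole chain can
be exercised and validated without human data.

## Conventions

The morph axis runs from 0 (fully disgusted) to 1 (fully angry); the
modelled "target" response is *anger*. The psychometric function is

$$P(\text{anger}\mid x) \;=\; \gamma + (1 - \gamma - \lambda)\,
  \Phi\!\left(\frac{x - \alpha}{\sigma}\right)$$

with PSE $\alpha$, spread $\sigma$ (the reported slope is $1/\sigma$), guess
rate $\gamma$ (fixed at 0: the 2AFC task has two symmetric labels, not a
forced asymmetric guess) and lapse rate $\lambda$ (fixed at 0.03). Adapting
to disgust makes ambiguous targets look angrier, raises
$P(\text{anger}\mid x)$, and so *lowers* the PSE. Aftereffects are the
difference scores `PSE(baseline) - PSE(adapted)`; under this convention
disgust adaptation gives positive aftereffects and anger adaptation negative
ones. When a day contributes several baseline sessions their PSEs are
averaged before differencing.

## The Psi procedure

Each test trial's morph level is chosen by the Psi rule: over a discrete
grid of (PSE, spread) hypotheses carrying a posterior $p(\theta)$, the
candidate $x$ minimising the expected Shannon entropy

$$E[H](x) = \sum_{r\in\{0,1\}} p(r\mid x)\, H\big(p(\theta\mid x, r)\big),
  \qquad p(r \mid x) = \sum_\theta p(r\mid x,\theta)\, p(\theta)$$

is presented, the response observed, and the posterior updated by Bayes'
rule. Defaults, chosen once: 41 PSE points on $[0,1]$, 21 log-spaced spreads
on $[0.02, 0.5]$, 41 candidate levels on $[0,1]$, a uniform prior, and a
fresh state per session (whether real sessions carried priors over is not
knowable from a protocol description, so the package makes the conservative
independent-sessions choice). Entropy uses natural logs — the base cannot
change the argmin — and ties are broken toward the lowest candidate so runs
are exactly reproducible. Posterior weights are floored at $10^{-300}$; with
the likelihood clamped away from 0 and 1 the posterior cannot collapse.

Internally a batched engine runs many sessions against one shared likelihood
table. Observer responses are drawn by comparing pre-generated per-session
uniform streams with the true response probability, which makes batched and
single-session runs trial-for-trial identical (this is tested).

## Fitting and screening

Final parameter estimates are maximum-likelihood refits of the binned
responses with $\gamma, \lambda$ held fixed; the interim Psi posterior mean
is recorded alongside (the two agree to a few hundredths of a morph unit at
144 trials). The binomial log-likelihood is maximised over
$(\alpha, \log\sigma)$ by bounded quasi-Newton search from the best point of
a coarse 10 x 10 grid, so the fit is deterministic. Bounds
($\alpha \in [-0.5, 1.5]$, $\sigma \in [0.01, 1]$) allow PSEs slightly
outside the morph range without unbounded drift; an optimum on a bound is
flagged not-converged. Data in which every response is identical are
non-identifiable and raise an error rather than a silent boundary fit.

Goodness of fit is a parametric bootstrap of the deviance
$D = 2(\ell_{\text{saturated}} - \ell_{\text{fit}})$ (with $0\log 0 := 0$):
datasets are simulated from the fitted function at the observed stimulus
placements, refitted, and the observed deviance compared with the simulated
distribution. Four hundred simulations is the reference setting; the p value
uses the smoothed estimator $(1 + \#\{D_{sim} \ge D_{obs}\})/(n + 1)$ so it
is never exactly zero. Fits with $p < 0.05$ are excluded, and an observer
excluded in any condition is dropped from the adaptation analyses (but kept
in the exclusion log; the report conserves observers).

## Bias indices

For the categorization task only disgust and anger responses in disgust and
anger body contexts are considered. With $p_c$ the proportion of correct
(face-emotion) responses among disgust+anger responses in context $c$,

* **Index 1** is the ratio $p_{con}/p_{incon}$ — intuitive but undefined at
  $p_{incon} = 0$ and outlier-prone;
* **Index 2** is $z(p_{con}) - z(p_{incon})$, a d'-style difference of
  standard scores, with extreme proportions of 0 or 1 replaced by $1/N$ and
  $1 - 1/N$.

The reference text does not say whether $N$ is the context's response count
or its trial count; the package uses the disgust+anger response count — the
denominator of the proportion being adjusted — and records that choice in
the output metadata. No-response trials are excluded throughout.

## Group statistics

Aftereffects are tested per condition (one-sample t, effect size $g_1$) and
contrasted between congruent and incongruent contexts (paired t, Hedges' g
with $J = 1 - 3/(4(n-1)-1)$; the paired effect-size denominator is the SD of
the difference scores). The 2x2 face-present/absent by body-context ANOVA is
computed as one-sample tests on the within-observer contrasts, with
$F = t^2$ at 1 and $n-1$ df — the exact classical decomposition for 1-df
within-subject effects (cross-checked against `aov` in the tests).

Evidence *for* null contrasts uses a directional JZS Bayes factor: a
half-Cauchy prior of scale 0.707 (the common software default) on the
standardized effect, truncated to the direction predicted by early
integration, which is an explicit argument and never inferred from the data.
The substitution $\delta = s\tan(\pi u/2)$ maps the prior mass exactly onto
the uniform measure on $(0,1)$, giving a well-conditioned one-dimensional
integral evaluated to relative tolerance $10^{-6}$. Robustness sweeps report
BF01 across prior widths and the smallest width still giving substantial
(BF01 >= 3) null evidence. Bayesian Pearson correlations use the stretched
Beta(1/w, 1/w) prior (width 1) with the exact sampling density of r; the
Gaussian hypergeometric factor is evaluated by its power series, and an
independent Euler-integral implementation serves as the test oracle.

## The synthetic-observer generator

The generator is the package's study-conditions definition, not a tuning
knob. Each observer has a true psychometric function
(PSE ~ truncated normal, mean 0.5, SD 0.05; spread mean 0.12, SD 0.03), an
adaptation shift magnitude `delta` (mean 0.08, SD 0.02 morph units — the
order of magnitude adaptation paradigms report), a context-bias strength
`kappa` (default 1: the full-reversal regime in which categorization of the
incongruent compound flips to the body emotion), and congruent-context base
rates. The extracted reference text contains no numeric confusion-table
values, so the base rates are the package's own choice: 0.90 correct, with
the remainder spread over the other labels — high recognizability consistent
with validated expression databases viewed in a supporting body context. An
incongruent disgust/anger body captures a fraction `kappa` of the
face-emotion probability mass; fear and sad bodies capture `kappa/2`,
reflecting the weaker off-pair similarity.

Hypotheses enter only through the session's effective shift. Late:
`delta_eff = delta` whatever the context. Early:
`delta_eff = delta * (2q - 1)`, with `q` the probability the adaptor is
categorized as its physical emotion in that context. This linear
percept-weighting is the model's one invented quantitative assumption — the
qualitative predictions fix only its endpoints (`q = 1` full shift, `q = 0`
equal-magnitude reversal, `q = 0.5` nothing) — and is the natural
sensitivity-analysis dial. Body-only adaptors produce no shift under either
hypothesis. Under the defaults, the early-integration congruent-incongruent
contrast is `2 * delta * q_con ~ 1.8 * delta`, and the late contrast is 0.

One master seed fans out to per-observer, per-stream substreams by a counter
scheme, so cohorts are byte-identical across runs and any single session can
be regenerated in isolation.

What the generator does *not* emulate: response times, sequential carryover
between sessions (real protocols used long washouts), day/order effects
(counterbalanced away in real designs), no-responses, and any dependence of
the lapse rate on adaptation state. Passing tests therefore validate the
computation chain under the stated statistical structure, not the
psychology of real observers.

## Problem sizes and runtime choices

The test suite and the acceptance script run at desk scale, chosen as the
package's own balance of power against turnaround: 100 observers for Psi
recovery (144 trials each, the protocol's session length), 500 datasets with
100 bootstrap replicates for the goodness-of-fit calibration, cohorts of 24
observers and 50 replicates per hypothesis for the discrimination check, and
2,000 null cohorts for type-I control. The goodness-of-fit reference setting
of 400 simulations is retained as the default for single-study analyses.

## Known limitations

* The slope scaling of the original analysis toolbox is unspecified, so
  absolute slope values are comparable only within this package.
* With the directional Bayes factor at scale 0.707 and n = 24, BF01 >= 3
  requires the contrast t to fall below about 0.52; under a true null that
  happens in about 70% of cohorts. "Substantial" null evidence in a single
  cohort of this size is therefore partly a matter of sampling luck — a
  property of the Bayes factor at this design size, not of the
  implementation.
* Index 1 is reported as undefined (not infinite) when `p_incon = 0`, which
  under the default full-reversal generator is the typical case; Index 2 is
  the primary robust measure.
* The Psi implementation is the plain two-parameter variant; lapse-
  marginalized Psi and other adaptive schemes are out of scope.
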