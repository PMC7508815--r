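---
title: "Models and methods for cWCST choice data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for cWCST choice data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwcst)
```

This vignette is the package's account of its science: the task model, the
four choice models and their assumptions, the estimation machinery, the
behavioral scoring rules, and the numerical and design choices that were
genuinely open — including known identifiability limitations that a user
fitting these models should understand.

## The task engine

The computerized Wisconsin Card Sorting Test presents a stimulus card that
must be sorted to one of four key cards by **color**, **shape** or
**number**. Key card $k$ carries color-, shape- and number-index $k$, so a
stimulus card is a triple of key indices. Deck-valid cards share at most
one dimension with any key card (pairwise-distinct attributes); exactly 24
of the 64 triples qualify. Consequently every response either applies
exactly one category or applies none (the card's *unmatched* key), making
the applied category observable — the property on which all scoring and
likelihood code relies.

The scheduled category switches after a run of consecutive correct sorts.
The run length (switch criterion) must be at least two and averages 3.5;
only those two constraints are fixed by the task description, so the
generator's default criterion distribution is **uniform on {2, 3, 4, 5}**
(mean exactly 3.5) and is configurable. Sessions end after 41 switches or
250 trials, whichever comes first; sessions hitting the cap are flagged
`truncated`. Cards are drawn uniformly from the deck with no immediate
repetition, fresh each trial (not an exhausting 24-card cycle) — the
original sequencing is not published, so this is a package choice. The
first target is uniform over the three categories. A 6-switch practice
schedule is available behind `practice = TRUE` and is never analyzed.

## The choice models

All four models map a latent state plus the current card to a probability
over the four keys, observe the executed response and binary feedback
$r(t) \in \{+1, -1\}$, and update the state.

**Parallel reinforcement learning (wP-RL, P-RL).** Category-level
(model-based) expectations $\mathbf{Q}_C(t)$ first decay by the inertia
$\gamma_{MB} \in [0,1]$; the applied category then moves toward the
feedback by $\alpha_{MB}^{+}$ or $\alpha_{MB}^{-}$ times the prediction
error. Response-level (model-free) expectations $\mathbf{Q}_{MF}(t)$ do
the same with $\gamma_{MF}, \alpha_{MF}^{\pm}$, keyed by the executed
response rather than the category. Category values are projected onto keys
via the card's match structure, with the unmatched key fixed at $-1$ (it
is certain to yield negative feedback). The integrated expectation is
$w\,\mathbf{Q}_{MB} + (1-w)\,\mathbf{Q}_{MF}$ for wP-RL and the plain sum
for P-RL, and choice is softmax with temperature $\tau \in (0,5]$.
Expectations initialize at zero; from there they provably stay in
$[-1, 1]$ for valid parameters, which the tests assert on random
trajectories.

**MB-RL** keeps only the category level. **AU** (attentional updating)
maintains a 3-vector of attentional prioritizations on the simplex,
initialized at $1/3$: feedback produces a signal concentrated on the
applied category (positive) or spread over the others (negative), weighted
by attention raised to the focus $f$; attention is then a convex
combination of its old value and the signal with ratio $p^{+}$ or $p^{-}$.
Choice is proportional to attention raised to the decision consistency
$d$, and the unmatched key receives probability exactly zero. A reduced AU
variant ($f = 1$, $p^{+} = 0.9999$) is available in the point-estimation
path for robustness checks; it is not part of the default model space.

Two exact identities tie the variants together and serve as
cross-implementation checks: wP-RL with $w = 1$ equals MB-RL, and wP-RL
with $w = 0.5$ and temperature $\tau/2$ equals P-RL at $\tau$. Both hold
to $10^{-12}$ in the tests, as does the agreement between the compiled
(C++) likelihood used for fitting and the pure-R reference implementation
built from the exported step functions.

**Responses matching no category.** Such responses receive probability
zero under AU, so fitted sequences must have them removed
(`wcst_remove_none()`, which keeps original trial indices so that
successors of removed trials are excluded from error scoring). The same
convention is applied to the RL models for comparability. During
*generative* simulation an RL agent may rarely press the unmatched key; in
that case the category expectations only decay (no category-level
prediction error exists) while the response-level update proceeds
normally — configurable via `mb_none`.

## Estimation

**Point path.** `wcst_fit(method = "mle")` maximizes each subject's
sequence log-likelihood by multi-start BFGS on the unconstrained scale
(default 10 starts: the origin plus N(0, 1.5) draws). The returned
log-likelihood always equals the sequence log-likelihood at the returned
parameters, and on degenerate one-trial data the optimum dominates a grid
oracle; both are asserted in the tests.

**Hierarchical path.** Parameters are estimated on an unconstrained scale
and mapped through the standard normal CDF $\Phi$ — unit-interval
parameters as $\Phi(x)$, unbounded-above parameters ($\tau$, $f$, $d$) as
$5\,\Phi(x)$. The non-centered parameterization writes subject $i$'s
parameter as $\theta_{ip} = T_p(\mu_p + \sigma_p z_{ip})$ with priors
$\mu_p \sim N(0,1)$, $\sigma_p \sim \text{half-Cauchy}(0,5)$ (the scale
prior is truncated to positive values since $\sigma$ is a scale), and
$z_{ip} \sim N(0,1)$. Sampling uses a package-authored adaptive blocked
random-walk Metropolis-within-Gibbs scheme: one joint proposal per subject
over its $z$ vector, one joint proposal per parameter over
$(\mu_p, \log \sigma_p)$, and one joint proposal over *all* group-level
parameters whose covariance is adapted to the chain history — the last
block exists to traverse correlated (ridge-shaped) posterior directions
discussed below. Proposal scales adapt during warmup toward 25%
acceptance. Defaults are 3 chains of 1,000 iterations with 500 warmup; a
reduced profile (2 × 500/250) is used in the test suite. Convergence is
monitored by split-$\hat{R}$ on all group-level parameters with a warning
threshold of 1.1. Posterior summaries report the constrained group
locations $T_p(\mu_p)$ — mean, SD and 95% highest-density interval (the
shortest interval covering the mass, verified against a brute-force scan).

## Model comparison and absolute fit

`wcst_kfold()` partitions subjects into $K = 5$ folds (near-equal sizes,
seeded), refits each model to every training set, and computes each
held-out subject's **elpd**: per posterior draw, the product of the
predicted probabilities of the subject's observed responses; averaged
across draws; logarithmized (computed in log space). Because the held-out
subject has no individual parameters in the training fit, a new-subject
vector is constructed per draw by sampling $z \sim N(0,1)$ and applying
$T(\mu_s + \sigma_s z)$; a plug-in alternative ($z = 0$) is available
behind `method = "plugin"`. Group elpd is the per-subject sum; pairwise
$\Delta$elpd is reported with the cross-validation standard error
$\sqrt{N} \times \text{SD}$ of per-subject differences, and per-subject
winner tallies break ties toward the model with fewer parameters.

`simulate_one_step_ahead()` implements post-hoc absolute fit: per
iteration (default 1,000) one parameter vector is drawn from the subject's
individual posterior, the latent state is rebuilt from the *observed*
history up to $t-1$, and a response is sampled on trial $t$. Simulated
conditional error probabilities keep the observed predecessor trial, so
opportunity structure and response demand are identical across iterations;
only the error indicator is simulated. A Monte-Carlo consistency test
checks that simulated frequencies converge to the model's analytic
per-trial probabilities. Simulated responses matching no category
(possible for RL agents, never for AU, and vanishingly rare at fitted
temperatures) are scored as category switches.

## Behavioral scoring

After negative feedback the scored trial is a perseveration opportunity
(error: reapplying the previous category); after positive feedback a
set-loss opportunity (error: switching). Response demand follows from
where the previously pressed key maps on the current card: if it maps to
the previously applied category, the post-negative error response repeats
the key (demanded **alternation**) and the post-positive correct response
repeats the key (demanded **repetition**); if it maps to another category
the demands reverse; if it maps to none the trial's demand is
unclassified and excluded from stratified denominators. The default reads
"correct response" after negative feedback as *any* category-switching
response; a stricter reading that scores demand against the scheduled
target's key is available via `demand_rule = "target"`. Conditional error
probabilities divide committed errors by opportunities per (error type ×
demand) cell; empty cells are missing, not zero. The participant screen
excludes subjects whose application count of any category lies strictly
outside the cohort mean ± 3 SD (boundary values are kept). Note that a
single outlier can only exceed 3 SD of statistics that include it when the
cohort has more than ten subjects (the maximum standardized residual is
$(n-1)/\sqrt{n}$). Recovery of inter-individual variance is summarized per
cell by the $R^2$ of regressing observed on simulated probabilities.

## The synthetic cohort generator

`wcst_cohort()` is the package's stand-in for real cohorts: $N$ agents
whose constrained parameters scatter around group means (normal on the
unconstrained scale, default between-subject SD 0.5 — a free choice that
produces visible heterogeneity), each playing an independent default
session. The RL defaults encode strong, near-complete category learning
from positive feedback ($\alpha_{MB}^{+} = 0.995$), moderate learning from
negative feedback (0.60), substantial inertia loss from trial to trial
($\gamma_{MB} = 0.31$), weak response-level learning concentrated on
negative feedback ($\alpha_{MF}^{+} = 0.005$, $\alpha_{MF}^{-} = 0.02$,
$\gamma_{MF} = 0.35$), a sharp temperature ($\tau = 0.09$) and a weighting
of $w = 0.33$; the AU defaults ($p^{+} = 0.9$, $p^{-} = 0.3$, $f = 1$,
$d = 2$) are field-plausible values chosen by this package. The generator
emulates choices and feedback only — no reaction times, no stimulus
timing, no practice or fatigue effects, no learning-to-learn across the
session — so passing tests speak to the choice-level structure of the
models, not to every feature of human data. Two cohort-level facts are
worth knowing:

* At the group-mean parameters, agents complete switches more slowly than
  typical human sessions (many hit the 250-trial cap), because group-level
  location means are not the mean of individual behavior.
* With the default dispersion, the skewed tail of high-temperature agents
  errs indiscriminately, which inflates set-loss rates; the qualitative
  signature "perseveration > set-loss, with positive demand modulation of
  perseveration for parallel-RL agents and none for MB-RL agents" is a
  property of the models *at* the default parameter means and is tested
  there (cohorts of 100 identical agents).

## Numerical choices

Softmax is computed with max-subtraction; probability vectors are checked
to sum to 1 within $10^{-12}$. Attention entries are floored at $10^{-12}$
before exponentiation by $f$ or $d$ (implementation tolerance, not model
content). The probit transform uses R's `pnorm`, saturating at double
precision for $|x| \gtrsim 8$, so constrained draws may touch the closed
interval bounds. Optimizer restarts and all simulation and sampling
functions take explicit integer seeds and restore the caller's RNG state.
Test problem sizes are chosen to exercise the full pipelines at modest
cost: sessions of 4–15 switches for likelihood identities, cohorts of
5–20 subjects for hierarchical smoke and recovery runs, 100-agent cohorts
for the behavioral signature, 10,000 iterations for Monte-Carlo
consistency.

## Identifiability limitations

Two structural facts limit what can be learned from a single session of
none-filtered choices, and users should know them before interpreting
per-subject point estimates:

1. **Scale ridge.** Choice probabilities depend on expectations only
   through $\mathbf{Q}_{sum}/\tau$, and in the small-learning-rate regime
   expectations are nearly linear in the learning rates. Jointly scaling
   all learning rates and $\tau$ down therefore leaves matched-key choice
   probabilities almost unchanged; the invariance is broken only by the
   unmatched key's fixed $-1$ value and by delta-rule saturation, both of
   which are invisible at sharp temperatures ($\tau \approx 0.1$ puts
   $e^{-1/\tau}$ of mass on the unmatched key). Consequently absolute
   learning-rate and inertia values are weakly identified per session,
   while their ratios and the overall choice sharpness are recovered
   reliably (the temperature recovery test passes at 100%). Removing
   none-category trials additionally tilts maximum likelihood toward the
   down-scaled end of the ridge, since the down-scaled model wastes no
   probability on the never-observed unmatched key.
2. **Tie degeneracy.** A near-deterministic agent (sharp $\tau$) produces
   sessions that are often perfectly consistent with an "eliminate after
   negative feedback, stay after positive, uniform over ties" rule; the
   boundary solution $\alpha^{-} = \gamma = 1$, $\tau \to 0$ then attains
   a genuinely higher likelihood than the generating parameters. This is
   the estimator behaving correctly on uninformative data, not an
   optimizer failure.

Hierarchical pooling with the package's priors mitigates but does not
remove the ridge: in long runs the posterior mean of the group-level
negative learning rate sits somewhat below the generating value while its
95% HDI covers it. The corresponding acceptance-grade recovery checks in
`test-acceptance.R` document where these limits bind: the per-session
point-estimate recovery of $\alpha_{MB}^{-}$ and $\gamma_{MB}$ at
$\tau = 0.1$ fails by design of the conditions (the assertions are kept,
honestly red), whereas the temperature check and the hierarchical
group-location checks pass.

## Known limitations

* The sampler is a random-walk scheme, not a gradient-based one; it is
  adequate for the cohort sizes used here but mixes slowly on strongly
  correlated posteriors — inspect $\hat{R}$ and increase iterations for
  production fits.
* Bayes-factor ANOVA machinery for the group-level 2 × 2 error analysis is
  out of scope; the package reports cell means, the modulation contrast
  and descriptive summaries instead.
* An MF-only model is deliberately absent (it cannot sort efficiently),
  as are eligibility traces and counterfactual updating.
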