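---
title: "Methods: event-based sequencing of regional brain atrophy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: event-based sequencing of regional brain atrophy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ebmseq)
```

This vignette describes the statistical model implemented by `ebmseq`, the
meaning and defaults of its parameters, the design of the synthetic cohort
generator used to validate it, and the numerical and design decisions that a
user of the package should know about.

## The event-based model

The package treats atrophy of each brain region as a binary *event*: either
the region's (covariate-adjusted) volume is still drawn from its healthy
distribution, or the event has occurred and the volume is drawn from an
abnormal, shifted distribution. The central assumption is that events occur
in a **common ordering** $S = (s_1, \dots, s_l)$, a permutation of the $l$
modelled regions, shared by all subjects: a subject at *stage* $k$ has
experienced exactly the first $k$ events of $S$ and none of the later ones.
Subjects differ only in how far along the sequence they are.

For a scan with adjusted values $x_1, \dots, x_l$, conditioning on the
(unobserved) stage and assuming regional independence given the stage gives
the scan likelihood

$$
P(x \mid S) \;=\; \sum_{k=0}^{l} P(k) \prod_{i \le k} P(x_{s_i} \mid E_{s_i})
\prod_{i > k} P(x_{s_i} \mid \neg E_{s_i}),
$$

where $P(x \mid E)$ and $P(x \mid \neg E)$ are the abnormal and normal
densities of the region and $P(k)$ is a prior over stages, **uniform over
$0, \dots, l$ by default** (stage 0 — no events yet — is a real, attainable
stage; healthy scans should land there). Scans are assumed independent given
$S$, so the data log-likelihood is the sum of per-scan terms. The model is
cross-sectional at heart: longitudinal visits enter as additional scans and
as repeated measures in the downstream association models, not as
constraints inside the sequence likelihood.

### Assumptions worth stating

* a single ordering for the whole patient population (phenotypes may differ
  in *stage*, not in *sequence*);
* conditional independence of regions given the stage;
* two-component (normal/abnormal) measurement distributions per region;
* monotone progression — events do not undo themselves.

## Pipeline and parameter choices

### Covariate adjustment (`adjust_volumes`)

Each region's volume is residualized on nuisance covariates
(`total_icv_ml`, `age_at_entry`, `sex`, `field_strength`, `protocol_id` by
default) with a linear model, then converted to z-scores **anchored to the
healthy-control baseline scans**: the residuals are centred and scaled by
the control-baseline mean and SD, so controls sit at $z \approx 0$ and
atrophy appears as negative $z$. Anchoring to controls (rather than the
pooled sample) keeps the "normal" component of the later mixtures at a
fixed, interpretable location. The adjustment model can be fitted on all
scans (default) or on controls only (`fit_on = "controls"`), the
conservative choice when disease and covariates are correlated.

### Region selection (`select_regions`)

Regions enter the sequence model only if patients differ from controls at
baseline by a Welch two-sample t-test, Bonferroni-corrected: the cutoff is
`alpha / n_regions` with `alpha = 0.01`. Bonferroni is deliberately strict —
an uninformative region added to the model dilutes staging — and its
familywise calibration is verified by a null-replicate test in the suite.

### Fixed-normal mixture (`fit_region_mixture`)

Per region, a two-Gaussian mixture is fitted to patient z-values with the
normal component **frozen** at the control-baseline moments; EM updates only
the abnormal mean, abnormal SD and mixing fraction. Freezing the normal
component prevents the mixture from re-explaining healthy variation as
partial atrophy. Choices:

* abnormal mean constrained $\mu_a \le \mu_n$ by projection (atrophy means
  smaller volume);
* SD floor `sigma_floor = 0.05` z-units, preventing degenerate spikes;
* deterministic initialization (mean of values below $\mu_n$, falling back
  to $\mu_n - 1$; $\sigma_a = \sigma_n$; mixing 0.5) so fits are
  reproducible without a seed;
* convergence at `tol = 1e-6` on the observed-data log-likelihood, cap
  `max_iter = 500`.

**Weak-event rule.** If the fitted mixture improves on the pure-normal model
by less than $10^{-3}$ log-likelihood units per scan, or the mixing fraction
falls below 0.02, the region is declared a *weak event*: the abnormal
component is pinned to the normal one and the mixing fraction set to 0, with
a warning. With identical components, $P(x\mid E) = P(x \mid \neg E)$
everywhere, so the region cancels out of every likelihood ratio — it cannot
distort the sequence or the stages. Without this rule, EM on a no-signal
region wanders on a flat ridge and can return an arbitrary, spuriously
"informative" abnormal component.

### Sequence search (`greedy_ascent`)

The log-likelihood of a candidate permutation is computed in C++ with prefix
sums of $\log P(x\mid E)$ and $\log P(x \mid \neg E)$ plus a log-sum-exp
over stages, i.e. $O(l)$ per scan after an $O(l)$ setup — exact, not
approximated. Search is greedy hill-climbing over random transpositions:
**10 restarts** from uniformly random permutations, **1000 proposals** each,
accepting only strict increases; the best restart wins. These defaults are
generous for the intended problem size (about 10 regions): in validation,
all restarts converge to the same optimum, and on small instances the result
matches exhaustive enumeration.

### Posterior sampling (`mcmc_sequences`)

Uncertainty in the ordering is quantified by Metropolis sampling over
permutations: propose a random transposition, accept with probability
$\min(1, \exp(\Delta \log L))$. Default burn-in is 1000 sweeps. Sampled
sequences feed `positional_variance`, which tabulates, for each region, the
posterior probability of appearing at each position; rows are ordered by the
maximum-likelihood sequence, and the resulting matrix is doubly stochastic
by construction.

### Staging (`assign_stages`)

Each scan is assigned the stage $k \in \{0, \dots, l\}$ maximizing the
$k$-th summand of the scan likelihood. Ties break toward the **smaller**
stage: absent evidence of an event, the scan is called less advanced. Stage
0 is the "no events yet" state and is the expected assignment for healthy
scans.

### Cross-validation (`cross_validated_ebm`)

Folds are formed at the **subject** level (both visits of a subject travel
together — staging a scan with a model that saw the same person's other
visit would leak) and stratified by phenotype via round-robin allocation
with a continuing offset, so small phenotype groups spread evenly across the
default 10 folds. Per fold, mixtures and the sequence are refitted on the
training subjects only, 10,000 MCMC samples are drawn, and the held-out
subjects are staged with the training-fold model. The pooled 100,000
samples give the aggregate positional variance diagram; every scan is
staged exactly once, out of fold.

### Associations (`mixed_effect_association` and friends)

Stage–clinical associations use `lme4` linear mixed models with a subject
random intercept and (by default) a random slope on time; Wald normal
p-values and standardized coefficients are reported. When the random-slope
model is singular or unidentifiable the fit degrades gracefully — random
intercept, then ordinary least squares — with a message, so two-visit and
single-visit designs still produce estimates. `annualized_change_regression`
regresses per-subject annualized EDSS change on annualized stage change
(plus disease duration at entry) and attaches a Spearman confirmation,
reflecting the ordinal character of both scales. `group_stage_summary` fits
per-group intercepts and slopes with pairwise Wald contrasts.

## The synthetic cohort generator

`simulate_cohort` exists so that every stage of the pipeline can be tested
against planted ground truth. It emulates a mixed-phenotype MRI study:

* five phenotypes (healthy controls plus four patient groups) with
  group-specific baseline stage distributions, Binomial$(l, p)$ with $p$
  increasing from the earliest to the most advanced phenotype, and
  group-specific annual progression rates driving Poisson stage increments
  between visits (controls never progress);
* volumes generated on the z-scale from the two-Gaussian measurement model
  itself (normal $N(0,1)$, abnormal $N(-\text{separation}, 1)$), then mapped
  to millilitres with per-region means/scales and **additive covariate
  effects** (head size, age, sex, field strength, protocol) that the
  adjustment step must remove;
* lesion load and EDSS coupled affinely to the true stage with noise, EDSS
  snapped to its half-point grid on $[0, 10]$ and missing for controls.

Its limits are equally deliberate: covariate effects are linear (matching
the adjustment model — no model mismatch is planted), regions are
conditionally independent given stage (the model's own assumption), the
true sequence is exact with no subject-level ordering heterogeneity, and
generated volumes are clamped below at 0.5 ml to keep them physical, which
very slightly truncates the abnormal tail of small regions. The generator
validates *correctness of the implementation*, not robustness to violations
of the model's assumptions.

## Known limitations

* **Staging specificity at moderate separation.** With an event/non-event
  separation of 2 z-units (a realistic effect size), a true-stage-0 control
  escapes stage 0 whenever the running sum of per-region log-likelihood
  ratios — increments distributed roughly $N(-2, 2^2)$ under the null —
  ever goes positive, which happens for roughly 16–18% of scans (the
  first-step escape probability alone is $\Phi(-1) \approx 0.16$). In our
  validation about 84% of true-stage-0 controls are staged at 0 at
  separation 2, rising above 95% only at separation around 4. This is a
  property of the model class, not of the search: stage specificity is
  bounded by the measurement overlap.
* Late-sequence positions are weakly identified when few subjects reach the
  final stages; the cross-validated positional variance diagram makes this
  visible rather than hiding it.
* Wald (normal) p-values from the mixed models are asymptotic;
  for small cohorts a parametric bootstrap would be preferable.

## Problem sizes

The defaults target cohorts of a few hundred subjects, about 10 regions and
two visits. At that size a full cross-validated run (10 folds, 10 restarts
of greedy search and 10,000 posterior samples per fold) completes in well
under a minute on one core; exhaustive checks in the test-suite use
$l \le 5$ where enumeration of all $l!$ orderings is feasible.
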