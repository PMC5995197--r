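# ebmseq

Event-based modelling of the sequence in which brain regions become
atrophic, from cross-sectional and short longitudinal cohorts of regional
MRI volumes.

## The science in brief

In progressive neurological disease, grey-matter regions do not atrophy all
at once: some regions (deep grey structures such as the thalamus) tend to go
early, others late. An **event-based model (EBM)** treats each region's
atrophy as a binary event and assumes a single ordering of events shared by
the population; a subject's **stage** is how many events they have
experienced so far. The data needed are a single scan per subject (more
help, but are not required) — the ordering is recovered from the pattern of
which regions are abnormal together across subjects at different stages,
not from following individuals over time.

For a scan with covariate-adjusted regional values $x$ and a candidate
ordering $S = (s_1, \dots, s_l)$, the scan likelihood marginalizes the
unknown stage:

$$
P(x \mid S) = \sum_{k=0}^{l} P(k)\,
  \prod_{i \le k} P(x_{s_i} \mid E_{s_i})
  \prod_{i > k} P(x_{s_i} \mid \neg E_{s_i}),
$$

with a uniform stage prior and per-region normal/abnormal densities from a
two-Gaussian mixture whose normal component is pinned to healthy controls.
The package finds the maximum-likelihood ordering, quantifies its
uncertainty by MCMC (**positional variance diagrams**), assigns each scan a
stage, cross-validates everything at the subject level, and relates the
stage to clinical variables with mixed models. A synthetic cohort generator
with planted ground truth underpins the test-suite. See the vignette
(`vignettes/atrophy-sequencing-methods.Rmd`) for the full methods.

## Worked example

```r
library(ebmseq)

# a synthetic study: 100 controls, 400 patients, 8 regions, 2 visits
cfg <- sim_config(n_per_phenotype = c(HC = 100, CIS = 80, RRMS = 200,
                                      SPMS = 60, PPMS = 60),
                  n_regions = 8, separation = 2.5, seed = 42)
sim <- simulate_cohort(cfg)

# 1. covariate adjustment (anchored to healthy-control baseline)
adj <- adjust_volumes(sim$cohort)

# 2. Bonferroni region selection
sel <- select_regions(adj)
print(sel, digits = 3)
#>                region mean_patients mean_controls       t        p selected
#> 1             caudate       -2.4664      5.87e-17 -19.185 1.12e-50     TRUE
#> 2            thalamus       -2.3876      6.31e-17 -21.098 5.54e-48     TRUE
#> 3           brainstem       -2.2269     -6.20e-17 -19.309 8.93e-45     TRUE
#> 4             putamen       -1.2617     -7.43e-17 -10.389 1.45e-20     TRUE
#> 5           precuneus       -0.6817     -3.55e-17  -5.556 8.26e-08     TRUE
#> 6    middle_cingulate       -0.5340      1.28e-18  -4.506 1.16e-05     TRUE
#> 7 posterior_cingulate       -0.1991     -3.67e-17  -1.696 9.17e-02    FALSE
#> 8            pallidum       -0.0453      1.33e-17  -0.411 6.82e-01    FALSE
regions <- sel$region[sel$selected]

# 3. fixed-normal two-Gaussian mixtures per region
mix <- fit_mixtures(adj, regions)
print(mix$caudate)
#> Two-Gaussian mixture (normal fixed): normal N(0.000, 1.000^2),
#> abnormal N(-2.891, 1.121^2), mixing 0.845 (24 EM iterations, converged)

# 4. maximum-likelihood event sequence (10 random restarts)
lik <- event_likelihoods(adj, mix, scans = "patients")
fit <- greedy_ascent(lik, seed = 1)
print(fit)
#> Maximum-likelihood event sequence (log-likelihood -7921.9765):
#> 1 thalamus -> 2 brainstem -> 3 caudate -> 4 putamen -> 5 precuneus -> 6 middle_cingulate
#> Final log-likelihood range over restarts: [-7921.9765, -7921.9765]
sim$truth$true_sequence_regions[1:6]   # the planted ordering — recovered
#> [1] "thalamus" "brainstem" "caudate" "putamen" "precuneus" "middle_cingulate"

# 5. posterior uncertainty: positional variance diagram
samp <- mcmc_sequences(lik, fit$sequence, n_samples = 10000, seed = 2)
pvd <- positional_variance(samp, fit$sequence)
round(unclass(pvd), 2)   # identity here: the ordering is certain
#>                  1 2 3 4 5 6
#> thalamus         1 0 0 0 0 0
#> brainstem        0 1 0 0 0 0
#> caudate          0 0 1 0 0 0
#> putamen          0 0 0 1 0 0
#> precuneus        0 0 0 0 1 0
#> middle_cingulate 0 0 0 0 0 1

# 6. stage every scan (controls included)
st <- assign_stages(event_likelihoods(adj, mix, scans = "all"),
                    fit$sequence)
m <- merge(st, sim$truth$stages, by = c("subject_id", "visit_time_years"))
cor(m$stage, m$true_stage, method = "spearman")
#> [1] 0.943

# 7. stage vs clinical variables (mixed model, patients only)
a <- mixed_effect_association(st[st$phenotype != "HC", ], "lesion_load_ml")
print(a, digits = 3)
#>             term estimate     se std_estimate     z         p
#> 1    (Intercept)    2.979 0.1148           NA 25.94 2.17e-148
#> 2 lesion_load_ml    0.157 0.0158        0.272  9.97  2.08e-23
```

`run_pipeline()` chains steps 1–7 plus subject-level stratified
cross-validation (per-fold refits, pooled MCMC samples, held-out staging)
and can write all artefacts as CSV; `load_cohort()`/`write_cohort()` handle
validated cohort CSV I/O.

## Running the tests

```sh
R CMD INSTALL --no-docs --no-html --no-help .
Rscript -e 'testthat::test_dir("tests/testthat", package = "ebmseq",
                               load_package = "installed")'
```

The suite checks every module against independent pure-R oracles
(direct-summation likelihood, exhaustive enumeration of all orderings,
brute-force staging) and runs end-to-end recovery of planted ground truth
on study-sized synthetic cohorts. One known-honest failure is expected in
`test-acceptance.R`: at an event/non-event separation of 2 z-units, the
fraction of true-stage-0 controls staged at 0 is ~84%, below the asserted
95% — an information-theoretic limit of the model at that effect size, not
a search or implementation defect (see the vignette's "Known limitations";
the ≥95% behaviour is demonstrated at separation 4 in `test-staging.R`).

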