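---
title: "Genetic evaluation of honey bee colonies from maternal pedigrees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genetic evaluation of honey bee colonies from maternal pedigrees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A tested honey bee colony produces one record per season: honey yield in
kg and two behaviour scores (defensiveness and swarming tendency, each a
1–5 category obtained by averaging repeated inspections and rounding to
the nearest integer; exact .5 averages round towards the higher
category by default, configurable). The colony phenotype reflects two
genomes — the worker group's and the queen's — but only the queen
reproduces, and in open breeding registries her mates are unknown, so
pedigrees carry dam links only.

`beeval` fits two parameterizations of the colony record
`y`, both with fixed test-year and tester-apiary effects and a random
year × apiary interaction (the apicultural analogue of a herd-year
effect):

* **model 1** adds a worker-group direct effect `w` and a queen maternal
  effect `mq` with covariance; worker groups are pseudo-individuals in a
  two-tier pedigree (dam = colony queen, sire unknown). The genetic
  variance expressed at colony level is
  `sigma2_C = sigma2_W + sigma2_MQ + 2 Cov_W-MQ`.
* **model 2** attributes a single direct effect `q` to the queen.

Relationships use standard diploid pedigree rules with every unknown
sire treated as a distinct, unrelated, non-inbred base individual. This
is a modelling convention, not a biological claim: honey bee
haplodiploidy and polyandry are deliberately not modelled, matching the
registry evaluation this package re-implements. Under this convention a
maternal pedigree has all inbreeding coefficients exactly zero and unit
diagonal relationships; the inverse relationship matrix is assembled
sparsely by Henderson's rules with the unknown-parent Mendelian-sampling
variances (1 for both parents unknown, `0.75 - 0.25 F_dam` for a known
dam only). A dense tabular-method oracle and a gene-dropping Monte-Carlo
oracle back the unit tests. Two consequences worth stating because they
are easy to guess wrong: two worker groups of the same queen have
additive relationship 0.25 (maternal half-sib groups, since each
colony's drones are treated as unrelated), and worker groups of two
same-dam queens have 0.0625.

## Estimation

**Continuous trait (REML).** The restricted likelihood is evaluated
through the sparse mixed-model equations (log-determinants from a sparse
Cholesky factorization; a dense phenotypic covariance is never formed).
Updates use the average-information (AI) matrix, computed exactly by the
data-vector identity (one extra sparse solve per parameter against the
already-factorized equations); the score is obtained by central finite
differences of the restricted likelihood, whose ~1e-5 absolute noise at
registry scale dictates the differencing step. The iteration runs in an
unconstrained parameterization — log variances and, under model 1, the
atanh of the direct–maternal correlation — so the positive-definiteness
cone never truncates a step, with Marquardt damping that interpolates
towards a scaled gradient step whenever the AI step fails to improve the
likelihood. A step is accepted only if the likelihood does not decrease,
so the trace is monotone by construction. Convergence is declared at a
maximum relative parameter change below `tol` (default 1e-12, the
registry software's criterion) or a likelihood gain below 1e-10 — the
resolution of the finite-difference score; well-identified problems stop
on the first criterion in a handful of iterations. Standard errors come
from the inverse AI matrix; components pinned at the variance floor
(1e-8 of the phenotypic variance) are flagged as boundary estimates with
their standard errors marked unreliable.

Model 1 deserves a warning that the damping exists to address: with one
worker group per colony the worker direct effect is separated from the
residual only through pedigree ties, and the restricted likelihood
develops a long, curved, nearly flat ridge (the same pathology that
makes registry-scale model-1 fits of categorical traits report residual
standard errors exceeding the estimates). The fit terminates cleanly on
such ridges — the reported components are then one point on a ridge the
data cannot resolve, which the inflated standard errors signal.

**Categorical traits (threshold Gibbs).** Scores are modelled as a
censored Gaussian liability cut at ordered thresholds. The sampler is
single-site Gibbs with a precomputed sparse structure, written in C++
and driven entirely by R's RNG so chains are bit-reproducible from a
seed: truncated-normal liability draws given the category, univariate
conditional draws for every location effect, uniform conditional draws
for free thresholds, and scaled inverse chi-square / inverse-Wishart
draws for (co)variances with flat priors (`nu = -2` for scalars), which
keeps posterior means comparable to REML. Identifiability for 5-category
traits defaults to fixing the first two thresholds at 0 and 1 and
*estimating* the liability residual variance — the convention required
to report non-unit residual variances on the liability scale, as the
registry analysis does. The alternative (`"unitvar"`: first threshold 0,
residual variance 1) is provided; heritabilities are invariant to the
choice, and a test asserts this on one dataset. Binary traits force
`"unitvar"`.

The multi-trait sampler (queen-direct model only, one continuous plus up
to two categorical traits) draws full T×T genetic and residual
covariance matrices; missing trait values are imputed by conditional
normal draws, so trait-wise missingness is exact rather than
approximate. The year × apiary effect is sampled with independent
per-trait variances — a simplification; the registry software's
treatment of that covariance is not documented. Non-positive-definite
scale matrices are jittered and counted (`n_not_pd` in the chain
object).

Posterior summaries (means, SDs reported as approximate standard errors,
95% credible intervals, Geweke z from AR-spectral variance estimates)
are computed per retained iteration *before* averaging, so
heritabilities and genetic correlations are posterior means of the
per-iteration ratios, not ratios of posterior means.

**A documented limitation.** When a 5-category score is collapsed to 2
categories, the data retain only the sign of one record per queen. The
marginal posterior of the variance components under flat priors is then
extremely diffuse, and the single-site chain traverses it as a slow
random walk — a known property of flat-prior binary threshold models.
Chains remain finite and reproducible, and location sampling at fixed
variances is exact (it matches BLUP shrinkage), but a 10^4-iteration
chain cannot pin the heritability of a binary trait; plan on much longer
chains or informative priors for binary data. With all five categories
(two fixed thresholds plus an estimated residual variance anchoring the
scale) heritability recovery at n = 2000 and 10^4 iterations is
demonstrated in the acceptance tests.

## Derived parameters and the printed-table conventions

Heritabilities are ratios of a genetic variance to the phenotypic
variance, kept at full precision and rounded half-up to 2 decimals only
for presentation. The phenotypic variance of model 1 admits three
summation conventions, all implemented because published tables are not
internally consistent about the covariance term: `"sum_2cov"` (counts
`2 Cov`, consistent with `sigma2_C`; the default), `"table"` (covariance
counted once), and `"abs"` (absolute covariance counted once). Standard
errors of ratios use the first-order delta method with the inverse-AI
covariance (REML) or the SD of per-iteration ratios (Gibbs).

## Predictability

Models are compared by withholding the colony phenotypes of validation
queens — queens whose dam has more than three recorded daughters and
whose maternal granddam is known, 150 drawn at random with a seed —
refitting EBVs on the reduced data, and correlating predictions with the
withheld information. Two definitions are reported because both appear
in field descriptions of the criterion: correlation with the withheld
phenotypes (default; reported both raw and adjusted for the reduced
fit's fixed effects, since year/apiary differences are not something a
breeding value can predict and the expectation bound
`E(r) = k · r_EBV-BV`, with `k` the true-BV-to-phenotype SD ratio,
excludes them) and correlation with the full-data EBVs. For behaviour
scores the default correlates EBVs with the observed integer scores.
The pedigree is never altered by record removal.

## The synthetic registry

The generator emulates the structure of a national queen registry:
186 base queens (scaled with the colony count), yearly cohorts whose
dams come from the two preceding cohorts, family sizes
`1 + NegBin(mu = 1.45, size = 0.25)` truncated at 33 — mean 2.45
daughters per dam, chosen to reproduce both the registry's dam count and
its 1–33 family-size range — 13 test years, 72 tester apiaries, and a
target of 207 observed year × apiary cells allocated so every active
apiary-year receives at least one colony. When scaled down, at least two
apiaries stay active per year so the cell effect never collapses onto
the year effect. True breeding values are gene-dropped
(`a = a_dam/2 + m`, `m ~ N(0, 0.75 G0)` for unknown sires, so the
population variance stays at `G0`); phenotypes add year, apiary, cell
and residual draws; categorical thresholds are placed so the marginal
category masses match the registry's skew (55.4% of defensive scores in
category 4; 88.7% of swarming scores in 3–5); records then lose each
trait at the registry's trait-wise missingness rates (0%, 1.1%, 2.7%).
Default truth components are the registry estimates themselves; the
multi-trait truth uses the multi-trait heritabilities (0.25/0.43/0.42)
on the single-trait phenotypic scales with genetic correlations
0.19/0.41/0.62. Year and apiary fixed-effect SDs (8.4 kg for yield, 0.5
and 0.6 liability units for the scores) are generator choices, set so
the total yield variance approaches the registry's observed spread; they
do not affect heritabilities, which condition on fixed effects.

What the generator does *not* emulate — polyandry and drone genetics,
selection across generations, genotype-by-environment interaction,
inspection-level scoring — bounds what passing tests show: they
demonstrate correctness of the estimation machinery under the model's
own assumptions, not robustness to the biology those assumptions
simplify.

## Problem sizes and numerical choices

The test suite runs the recovery experiments at reduced but structured
sizes chosen to keep the whole suite in the tens of minutes on one CPU:
REML recovery uses 20 replicates of 3000 colonies; threshold recovery
one dataset of 2000 colonies at 10^4 iterations; multi-trait recovery
averages three replicates of 2000 colonies at 2×10^4 iterations (the
per-replicate posterior SD of a genetic correlation is ≈0.09, so
single-replicate point checks would be underpowered); predictability
uses 20 replicates of 900 colonies with 150 validation queens per
level. Production defaults mirror registry practice: 10^5 Gibbs
iterations single-trait, 5×10^5 multi-trait (thinning 10), 10% burn-in,
REML tolerance 1e-12. Other numerical choices: the mixed-model solve
performs iterative refinement to a 1e-12 relative residual; fixed-effect
rank deficiencies from sparse year × apiary layouts are pruned by
pivoted QR (reference level first, then any remaining dependent
columns), which changes no estimable contrast and no EBV; truncated
normal draws collapse to the nearer bound beyond the ~1e-14 tail and are
counted; thresholds are initialized from observed cumulative category
frequencies mapped onto the scheme's fixed points.
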