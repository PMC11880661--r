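---
title: "Covariance reaction norms: models, simulator, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covariance reaction norms: models, simulator, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covrn)
```

## The problem

Life-history trade-offs are negative covariances between fitness-related
traits — fecundity against growth, offspring number against offspring
quality — arising when individuals allocate a finite resource budget.
Despite strong theoretical expectations, trade-offs are hard to detect in
wild populations: among-individual variation in resource *acquisition* can
mask variation in *allocation*, and the strength (even the sign) of the
expressed correlation can depend on the environment.  Standard multivariate
mixed models estimate one fixed residual correlation and therefore cannot
describe this context dependence.

A covariance reaction norm (CRN) makes the correlation itself a regression.
For two traits measured across discrete environmental contexts \(C\)
(typically years), a context-level design matrix \(X_3\) predicts the
among-individual correlation on the inverse-hyperbolic-tangent scale:

\[
\operatorname{atanh} r(C) = X_3 \beta_r ,
\qquad
\operatorname{atanh}(r) = \tfrac{1}{2}\operatorname{logit}\!\big(\tfrac{r+1}{2}\big),
\]

a logistic regression rescaled from \([0,1]\) to \([-1,1]\).  The package
models the correlation rather than the covariance because scale changes in
either trait would otherwise be confounded with changes in association.
Trait variances are estimated per model but deliberately *not* regressed on
covariates (the `variance_model = "intercept_only"` default): the scientific
target is the association, and no predictions are made on the variances.

## Model variants

Three sampling designs are supported, matching what long-term field studies
actually provide.

**Full repeated measures** (`variant = "full"`): both traits measured
repeatedly and in pairs within individual–context.  Each trait has an
among-individual effect \(\alpha\) and a residual \(\epsilon\); *two*
reaction norms are estimated, one for the among-individual correlation
\(r_\alpha(C)\) and one for the within-individual correlation
\(r_\epsilon(C)\).  Implemented for Gaussian trait pairs.

**Non-repeated measures** (`variant = "non_repeated"`): one measurement of
each trait per individual–context.  Among- and within-individual variation
cannot be separated; a single observation-level latent pair
\((o_1, o_2) \sim N(0, P_o(C))\) carries the correlation.  The estimated
\(r_o(C)\) relates to the latent levels through repeatabilities
\(R_1, R_2\):

\[
r_o = r_\alpha\sqrt{R_1 R_2} + r_\epsilon\sqrt{(1-R_1)(1-R_2)} .
\]

`observation_level_correlation()` and `bias_grid()` implement this identity
and its consequence: when \(\operatorname{sign}(r_\alpha) \neq
\operatorname{sign}(r_\epsilon)\) and repeatabilities are low, the
observation-level correlation can have the *opposite sign* of the
among-individual trade-off ("sign bias").  The sign-flip region is exactly
\(|r_\epsilon|\sqrt{(1-R_1)(1-R_2)} > |r_\alpha|\sqrt{R_1R_2}\); cells with
\(r_\alpha = 0\) or \(r_o = 0\) are classified as not flipped (the bias
regions are open sets).  Repeatabilities are user-supplied quantities,
understood as already adjusted for mean effects.  `predict_correlation()`
prints this caveat whenever a non-repeated or hybrid fit is summarised.

**Hybrid** (`variant = "hybrid"`): trait 1 repeated within
individual–context (offspring masses within a litter), trait 2 single
(litter size).  The correlation links the trait-1 among-individual effect
to the trait-2 observation-level effect and is attenuated relative to the
full among-individual correlation by \(\sqrt{R_2}\)
(`hybrid_correlation()`).

Families: Gaussian; Poisson with log link, where the observation-level
latent doubles as an overdispersion term; and cumulative-logit ordinal for
low, bounded counts (e.g. 0–2 lambs), whose trait intercept is absorbed
into the ordered thresholds (asserted at build time).  Measurements of the
same individual in different contexts are treated as independent — the same
simplification the method itself makes — so no cross-context individual
effect is estimated.

## Record selection for litter data (`poisson_log_trunc`)

A litter of zero offspring leaves no record: no litter-size row and no
offspring masses.  Recorded litter sizes are therefore zero-truncated, and
— more subtly — the latent pairs of *recorded* mother-years are a selected,
non-normal subset (mothers with high fecundity latents are over-represented,
more strongly so in harsh years).  Fitting a plain Poisson, or a Poisson
truncated conditionally on the latent, to such records biases the fecundity
coefficients and leaks bias into the mass sub-model through the latent
correlation; we measured ~0.07 absolute bias on the fecundity coefficients
at the validation dimensions, several posterior SDs.

`poisson_log_trunc` therefore implements the exact conditional likelihood
of a record given that it exists: the plain Poisson terms plus
\(-\log \Pr(L \ge 1 \mid X_2\beta_2 (+\delta_2), \sigma_{o2})\), with the
selection probability marginalised over the observation-level latent by
24-node Gauss–Hermite quadrature.  The integral is shared across
observations with identical fixed predictors (all mothers of a year in the
validation design), so its cost is negligible.  With this correction the
recovery experiments cover all generating parameters, not only \(\beta_r\).

## Priors, sampler, and numerical choices

Priors are the regularising defaults used throughout: Normal(0, 1) on all
intercepts and slopes (including \(\beta_r\)), Exponential(rate 2) on SDs,
Normal(0, 2) on ordered thresholds (a choice we flag: thresholds are
weakly identified in sparse categories, and the prior scale matters there).

No external MCMC engine is available to this package, so inference uses a
built-in No-U-Turn Hamiltonian Monte Carlo sampler over exact analytic
gradients:

* latent pairs are non-centred — raw \(N(0,1)\) vectors scaled by the SDs
  and rotated by the context correlation, \(o_2 = \sigma_2(r u_1 +
  \sqrt{1-r^2}\,u_2)\) — which is essential for the funnel-free geometry
  HMC needs;
* Gaussian traits with a single measurement per unit are marginalised out
  of the latent vector (their latent is data-determined), halving the
  dimension and removing a deterministic ridge;
* warmup uses dual averaging towards an acceptance target of 0.9 plus a
  Stan-style expanding-window estimate of a diagonal metric; correlations
  start at \(r = 0\) and latents at \(0.1 \times N(0,1)\) to avoid boundary
  starts;
* the default sampler profile is 3 chains, 1000 warmup, 3000 retained
  draws, no thinning; `mcmc_test_profile()` (2 chains, 500/500) is used for
  tests and the recovery experiments, which is why those runs occasionally
  warn about R-hat slightly above the (deliberately strict) 1.01 threshold;
* split-chain Gelman–Rubin statistics are computed for every stored
  parameter; warnings are never silent.  The warning threshold of 1.01 is a
  package choice — no acceptance cutoff is standard — and divergent
  transitions are counted and reported.

`corr_unlink()` clamps at \(\pm(1 - 10^{-12})\): beyond \(|\eta| \approx
14.2\) the double-precision `tanh` would round to exactly \(\pm 1\),
violating the open-interval contract.  `corr_link()` never clamps; callers
holding degenerate correlations must clamp themselves.

## What the simulator emulates — and what it does not

`simulate_intergenerational()` and `simulate_intraindividual()` generate
the two validation worlds: 30 years, 25 recruits per year (750 individuals),
mean fecundity 2.5, annual survival 0.6, a standard-normal yearly climate
covariate that shifts both trait means and, through
\(\operatorname{atanh} r(C) = \beta_{r0} + \beta_{r1}\,\mathrm{climate}\),
the among-individual correlation.  Defaults not fixed by that stated world
were chosen once as field-realistic and are not tuned: latent SDs
\(\sigma_{o1} = \sigma_{o2} = 0.5\) (moderate overdispersion, litter
repeatability ~0.5), within-litter SD 0.5, trait means on a standardized
scale (intercept 0), climate effects 0.3 and 0.2, and
\(\beta_r = (-0.3, 0.7)\) — a baseline trade-off that strengthens or
reverses across the observed climate range, the regime the method exists to
detect.  The fecundity intercept is `log(2.5) - sigma_o2^2/2`, making 2.5
the realized marginal mean litter size per mother-year (zeros included).

Reproducibility is per-year: each simulated year draws from its own seeded
substream, so editing later-year settings leaves earlier years byte-identical.

Deliberate simplifications: no density dependence, no age structure beyond
covariates, no spatial structure, no measurement error, independence of the
same individual across years, and no attempt to reproduce any particular
realization's event totals (these are seed-dependent).  A green recovery
test therefore establishes that the estimator recovers a known
context-dependent correlation under its own assumptions — not that those
assumptions hold in any real system.  `simulate_marmot_like()` and
`simulate_sheep_like()` are synthetic lookalikes exercising the two
empirical model presets (two context covariates, year random effects,
ordinal fecundity for the sheep schema); they share the real studies'
covariate structure, not their data.

## Validation logic

The package is validated by the same logic it implements for users:

1. closed-form identities checked against brute-force Monte-Carlo oracles
   (two-level bivariate-normal simulation for the repeatability blend);
2. every variant's analytic gradient checked against numerical
   differentiation, and two likelihoods re-derived in independent plain-R
   oracles;
3. prior-only sampling must reproduce the stated priors;
4. simulate-and-recover at the stated dimensions: the 89% credible
   intervals for \(\beta_r\) (intercept and slope) must cover the truth in
   at least 8 of 10 seeded replicates, per design;
5. posterior predictive checks on the recovery fits must be calibrated
   (tail probabilities away from 0 and 1), and must flag injected
   misspecification.

Known limitations: ordinal traits are only available in the non-repeated
variant (they need an observation-level effect); the full variant is
Gaussian-only and has no year random effects; Bernoulli traits are
unsupported by design (their mean fixes their variance, so a correlation
reaction norm is not separately identifiable from mean effects without
repeated measures); and under non-repeated sampling every reported
correlation is observation-level, with the sign-bias caveat attached.
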