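---
title: "Mixed models with relationship covariance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed models with relationship covariance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

kinlmm fits the Gaussian linear mixed model

$$y = X\beta + \sum_t Z_t u_t + e,$$

where each random vector $u_t$ is multivariate normal with a *structured*
covariance $G_t$ supplied by the user, most importantly the polygenic term
$G = \sigma_g^2 A$ with $A$ the additive genetic relationship matrix (twice
the kinship matrix) computed from a pedigree. The residual is either
homoscedastic, $R = \sigma_e^2 I$, or heteroscedastic by a grouping factor
(one $\sigma_{e,\ell}^2$ per level). Heritability is the genetic share of
the summed variance components,
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sum_c \sigma_c^2 + \sigma_e^2)$.

A structured term is reduced to an unstructured one through the
substitution $Z^* = Z L$ with $L L^\top = A$: the Cholesky factor when $A$
is positive definite, and $L = V \Lambda^{1/2}$ from the truncated
eigendecomposition when $A$ is only positive semi-definite. The
semi-definite case is not an edge case in family data: monozygotic twins
duplicate rows of $A$ exactly, so twin studies produce rank-deficient
relationship matrices by construction. `factor_relmat()` dispatches on the
minimum eigenvalue with a relative tolerance (`psd_tol`, default $10^{-8}$
of the largest eigenvalue, scale-free because relationship matrices arrive
on arbitrary scales); eigenvalues below $-$`psd_tol` are a hard error
rather than silent truncation.

### Sex-specific genetic variance (gene–environment interaction)

The genetic variance may differ between the levels of an environment
factor — the motivating case is sex. The genetic block then has parameters
$\sigma_{g_1}, \sigma_{g_2}, \rho_g$ and the covariance between
individuals $i, j$ is $A_{ij} K_{\ell(i)\ell(j)}$, where $K$ has
$\sigma_{g_a}^2$ on the diagonal and $\rho_g \sigma_{g_1}\sigma_{g_2}$ off
it. "No interaction" is the intersection of two testable restrictions:
$\rho_g = 1$ and $\sigma_{g_1} = \sigma_{g_2}$. `fit_gxe()` fits the free
model and both restricted models by ML; `gxe_test_pair()` performs the two
likelihood ratio tests, using the $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$
mixture for the $\rho_g = 1$ null because that null sits on the boundary
of the correlation space. Residual heteroscedasticity between the groups
is supported natively (`residual_spec("by_group", ...)`) rather than
through a dummy random effect on a copied id column: the native form is
identifiable, equivalent (the group's total variance is the sum either
way), and keeps the residual structure explicit. The package verifies the
equivalence where it matters: fixing $\rho_g = 1$, equal genetic sds and
equal residual sds reproduces the homoscedastic polygenic deviance to
$10^{-6}$.

## Likelihood and optimization

For parameters $\theta$ (standard deviations and correlations) the
covariance $\Sigma(\theta) = \sum_t \mathrm{Var}(u_t) + R$ is assembled
explicitly and $\beta$ is profiled out by generalized least squares. The
criterion is $-2\ell$ for ML and the restricted form
$(n-p)\log 2\pi + \log|\Sigma| + \log|X^\top \Sigma^{-1} X| + r^\top
\Sigma^{-1} r$ for REML. REML is the default for variance estimation and
the simulated restricted LRT; ML is mandatory when a likelihood ratio test
compares models that differ in fixed effects, as in the association scan.

Two evaluation paths produce identical values:

* **dense** (small $n$, or dense covariance patterns up to $n = 400$):
  one `chol()` per evaluation with triangular solves;
* **sparse** (large block-sparse problems, e.g. family studies): the union
  sparsity pattern over all components is computed once per model, each
  component's entries are mapped into it, and the symbolic Cholesky
  analysis is cached so every evaluation performs only a numeric
  refactorization. This is what makes fitting cost grow with the density
  of the kinship matrix — the package's timing probe shows median fit time
  non-decreasing as a block-sparse $n = 900$ matrix is densified from
  sparsity 0.98 to 0.60.

Optimization uses `minqa::bobyqa`, a bounded derivative-free local search,
from three deterministic starts (equal split of the phenotypic variance
across components; residual-dominant 90/10; structured-dominant 10/90),
followed by a small-trust-region polish restart at the incumbent. Standard
deviations are searched on $[0, 25\,\mathrm{sd}(y)]$ — the sd scale avoids
the curvature pathology of the variance scale at 0 — and correlations
directly on $[-1, 1]$. The direct correlation box is a deliberate choice:
a tanh-type transform places $\rho = 1$ at infinity, and since $\rho_g =
1$ is both a common small-sample MLE and the interaction null, an
unbounded flat ridge would stall the optimizer and could leave the free
fit above its own constrained submodel. With the direct box the boundary
is attainable and deviance nesting is exact; `fit_gxe()` additionally
warm-restarts the free model from any constrained solution that beats it.

Constraints are applied before the search: fixed parameters are removed
from the free vector, equality groups collapse to one free symbol
(aliasing, exact rather than penalty-based). Parameters within $10^{-4}$
(sd scale) of a bound are flagged `boundary` in the fit. Rows with missing
values in any used column are dropped listwise with a logged count.
A response with zero variance is a hard "degenerate data" error: the
likelihood is unbounded as $\sigma_e \to 0$ with zero residuals, so no
meaningful fit exists.

## Inference

* **Nested LRT** (`lrt()`): $\chi^2_{df}$, or the
  $\tfrac12\chi^2_{df-1}+\tfrac12\chi^2_{df}$ mixture when the null pins a
  parameter at a bound. The naive $\chi^2_1$ p-value is exactly twice the
  mixture p-value for $df = 1$, i.e. always conservative.
* **Simulated restricted LRT** (`rlrt_sim()`): tests a variance component
  against zero by parametric simulation — fit the null, draw responses
  from it, refit both models per draw. The spectral fast algorithms for
  this problem cover only single-random-effect models; the bootstrap
  generalizes to multiple structured terms at desk-scale cost. The
  p-value estimator $(1 + \#\{\text{sim} \ge \text{obs}\})/(1 + n_{sim})$
  never returns exactly 0; `n_sim < 100` is flagged low-resolution. With
  $n_{sim} = 59$, $P(p \le 0.05)$ is exactly 0.05 under the null, which
  the calibration tests exploit.
* **Profile-deviance intervals** (`profile_ci()`): endpoints where the
  profiled deviance rises by $\chi^2_1(level)$ above its minimum.
  Heritability is profiled directly: for fixed $h^2$ the genetic variance
  is $h^2/(1-h^2)$ times the sum of the remaining components, which are
  re-optimized (warm-started along the profile). Endpoints are located by
  monotone bisection to $10^{-4}$ on the target scale; a profile that
  never crosses the threshold before a parameter bound yields a one-sided
  interval with the bound flagged.

## Association scanning

`assoc_scan()` tests each SNP against a structured null model after
per-SNP listwise deletion of missing dosages (no imputation — the simplest
defensible default, with `n_used` exposed per SNP). Three modes:

* `lrt` — ML refits of null and SNP models per SNP, $\chi^2_1$;
* `wald` — $(\hat\beta/\mathrm{se})^2$ from the SNP-model GLS;
* `score2step` — the fast two-step mode: variance components are frozen at
  the null REML fit and each SNP is tested by GLS with the fixed
  $\hat\Sigma$, so no mixed model is refitted per SNP. It is labelled
  approximate in the output; its p-values rank-correlate with the full
  LRT above 0.99 in the package's calibration runs.

MAF filtering removes SNPs *strictly below* the threshold (a SNP at
exactly 1% is kept). Parallelism is an embarrassingly parallel map over
contiguous SNP slices reassembled in SNP order, so results are identical
for any worker count. No multiple-testing correction is applied by
default; `bonferroni_flag()` adds one on request.

## The simulator

`simulate_study()` generates the package's test bed: pedigrees (nuclear,
three-generation, or nuclear with monozygotic twin pairs), genotypes by
gene dropping (founder alleles i.i.d. Bernoulli(maf), one random allele
transmitted per parent, twins copy their co-twin), and phenotypes
$y = X\beta + u + c + e$ with $u$ drawn through the factorization of $A$
(so twin matrices work), a household-shared effect, and i.i.d. or
sex-specific residuals. The random part's total variance is normalized to
1 so `h2` and `c2_household` are directly the simulated fractions, making
recovery tests scale-free. Age is uniform within generation (founders
55–65, children 35–45, grandchildren 15–25) with default
$\beta_{age} = 0.02$ per year and a sex effect of 0.2 — small covariate
effects of the size typical for standardized clinical phenotypes. Default
sibship size is 3; the recovery and power studies use 30 families of 10
(n = 300), the scan calibration 75 families (n = 600), and the densification
probe 90 families (n = 900) — sizes chosen so each property is measured at
the scale where it is informative while the whole suite stays at desk
scale. One master seed drives everything; sub-streams are derived
deterministically per operation, so studies are reproducible bit for bit.

What the simulator does *not* emulate — and hence what passing tests do
not establish about real data: linkage disequilibrium between SNPs
(markers are independent), ascertainment through probands, assortative
mating, genotyping error, and non-Gaussian phenotypes. Results on real
family data inherit all the usual caveats of those features.

## Numerical choices and degenerate inputs

* `psd_tol` $10^{-8}$ relative; factorization reconstruction is verified
  to $10^{-8}$ and failure is an error, never silent.
* Non-positive-definite $\Sigma(\theta)$ during optimization returns a
  large finite penalty ($10^{10}$) so bounded searches continue; at a
  reported optimum the same condition is an error.
* `densify()` fills randomly chosen symmetric zero pairs with a small
  constant and then adds `fill_value`·I, so the perturbed matrix stays
  positive semi-definite for the small fills used in practice.
* Sparsity counts exact zeros only — no epsilon threshold.
* Equality constraints between parameters of different kinds (an sd and a
  correlation) are rejected.
* Ties in the topological sort of a pedigree are processed in file order;
  the relationship matrix is invariant to record order.
* Identifier matching is strict string equality after whitespace
  trimming; a data grouping level absent from the relationship matrix is
  a hard error, never an identity fill.

## Known limitations

Generalized (non-Gaussian) mixed models are out of scope, as are
dominance/epistatic relationship matrices, marker-based GRMs,
X-chromosome kinship, unstructured residual covariance beyond group
heteroscedasticity, small-sample denominator corrections
(Satterthwaite/Kenward–Roger), bootstrap of fitted models, and the
eigendecomposition fast path for single-random-effect GWAS. The two-step
scan mode freezes variance components under the null and is therefore
approximate for SNPs of large effect.
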