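# kinlmm

Linear mixed models whose random effects carry **user-supplied covariance
matrices** — above all the additive genetic relationship matrix **A**
derived from a pedigree — for quantitative-trait studies of related
individuals: heritability estimation, variance-component tests,
sex-specific (gene–environment) genetic variance models, and per-SNP
association scans that respect family structure.

## For whom, and what it computes

Family-based studies (extended pedigrees, twin designs, households)
produce correlated observations. Ignoring the correlation inflates
association signals; modelling it requires random effects whose
covariance is a *given matrix* rather than a free block. kinlmm fits

> y = Xβ + Σ_t Z_t u_t + e,  u_t ~ N(0, G_t),  e ~ N(0, R)

with G = σ_g² A for the polygenic term, optional shared-environment terms
(household), and R = σ_e² I or group-specific residual variances. The
structured covariance is absorbed by the substitution **Z\* = Z L**,
L Lᵀ = A — Cholesky when A is positive definite, truncated
eigendecomposition when it is semi-definite (monozygotic twins make A
rank-deficient by construction). Variance parameters are estimated by
REML/ML with a bounded derivative-free search under **box and equality
constraints** (fix ρ_g = 1, force σ_g1 = σ_g2, …), which is what the
advanced QTL models need.

On top of the fitting engine:

* `heritability()` and `profile_ci()` — h² with profile-deviance
  confidence intervals;
* `rlrt_sim()` — simulation-based restricted LRT for a variance
  component (the null is on the boundary, so the naive χ² test is wrong);
* `fit_gxe()` / `gxe_test_pair()` — sex-specific genetic variances
  (σ_g1, σ_g2, ρ_g) with the two interaction nulls ρ_g = 1 (boundary
  mixture ½χ²₀+½χ²₁) and σ_g1 = σ_g2 (χ²₁);
* `assoc_scan()` — per-SNP LRT/Wald scans against the structured null,
  plus a fast **two-step** mode that freezes the variance components at
  the null REML fit and tests each SNP by GLS;
* `additive_relationship()`, `read_pedigree()`, `densify()` — pedigree
  kinship construction and sparsity experiments;
* `simulate_study()` — pedigrees, gene-dropped genotypes and phenotypes
  under every variance architecture the package fits.

## Worked example

Simulate a 30-family study (10 members each, h² = 0.5, household share
0.2), fit the polygenic model, and test the genetic component:

```r
library(kinlmm)

cfg   <- sim_config(n_families = 30, k_children = 8,
                    h2 = 0.5, c2_household = 0.2, seed = 42)
study <- simulate_study(cfg)

spec <- polygenic_spec("y", c("age", "sex"), study$A, household = "hhid")
f    <- fit(spec, study$pheno)
print(f)
#> <kin_fit> REML, -2 logLik = 762.4448, n = 300
#> Fixed effects:
#> (Intercept)         age     sexmale
#>      0.2244      0.0175     -0.2635
#> Variance parameters (sd scale):
#>   id.sd = 0.9421
#>   hhid.sd = 0.4746
#>   residual.sd = 0.3681

heritability(f)
#> [1] 0.711
profile_ci(spec, study$pheno, f, target = "h2")
#> <kin_interval> h2 = 0.7110, 95% CI [0.2780, 0.9764]
rlrt_sim(spec, 1, study$pheno, n_sim = 199, seed = 7)
#> <kin_test> rlrt_sim: stat = 7.5819, df = 1, p = 0.01
```

The fitted sds are the square roots of the variance components
(σ̂_g = 0.94, σ̂_household = 0.47, σ̂_e = 0.37); `heritability()` is
σ̂_g² over their squared sum — here 0.71 with a wide profile interval
[0.28, 0.98], as expected for 30 families — and the simulated restricted
LRT rejects σ_g² = 0 at its resolution floor for 199 simulations
(p = (1+1)/(1+199) = 0.01).

For a sex-specific analysis replace the spec:

```r
gspec <- gxe_spec("y", "age", study$A, environment = "sex")
trio  <- fit_gxe(gspec, study$pheno)     # free, rho_g = 1, equal-variance fits
gxe_test_pair(trio)                      # the two interaction tests
```

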