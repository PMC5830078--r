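sim_balanced_oneway <- function(seed, k = 20, r = 5, sd_u = 0.7, sd_e = 0.5) {
  withr::local_seed(seed)
  grp <- rep(sprintf("g%02d", seq_len(k)), each = r)
  u <- rnorm(k, 0, sd_u)
  data.frame(y = u[match(grp, unique(grp))] + rnorm(k * r, 0, sd_e), grp = grp)
}

test_that("balanced one-way REML equals the ANOVA mean-square estimators", {
  dat <- sim_balanced_oneway(101)
  spec <- model_spec("y", random = random_term("grp"))
  f <- fit(spec, dat)
  closed <- oracle_anova_oneway(dat$y, dat$grp)
  expect_true(closed["var_group"] > 0)  # interior case
  expect_equal(unname(f$params["grp.sd"]^2), unname(closed["var_group"]),
               tolerance = 1e-6)
  expect_equal(unname(f$params["residual.sd"]^2), unname(closed["var_resid"]),
               tolerance = 1e-6)
  expect_true(f$converged)
})

test_that("REML variance estimates agree with lme4 on a grouped design", {
  skip_if_not_installed("lme4")
  dat <- sim_balanced_oneway(202, k = 15, r = 4)
  f <- fit(model_spec("y", random = random_term("grp")), dat)
  lf <- lme4::lmer(y ~ 1 + (1 | grp), dat, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(unname(f$params["grp.sd"]), vc$sdcor[vc$grp == "grp"],
               tolerance = 1e-4)
  expect_equal(unname(f$params["residual.sd"]), vc$sdcor[vc$grp == "Residual"],
               tolerance = 1e-4)
  expect_equal(unname(f$beta["(Intercept)"]), unname(lme4::fixef(lf)),
               tolerance = 1e-6)
})

test_that("pedigree fits equal a grid-plus-polish brute-force minimum", {
  cfg <- sim_config(n_families = 2, k_children = 18, h2 = 0.5, seed = 303)
  st <- simulate_study(cfg)  # 2 families x 20 = 40 individuals
  spec <- polygenic_spec("y", "age", st$A)
  f <- fit(spec, st$pheno)
  obj <- function(th) neg2_loglik(spec, th, st$pheno, "REML")
  grid <- expand.grid(sg = seq(0.1, 1.6, by = 0.1), se = seq(0.1, 1.6, by = 0.1))
  vals <- mapply(function(a, b) obj(c(a, b)), grid$sg, grid$se)
  start <- as.numeric(grid[which.min(vals), ])
  polish <- optim(start, function(p) if (any(p < 0)) 1e12 else obj(p),
                  method = "Nelder-Mead",
                  control = list(reltol = 1e-13, maxit = 600))
  expect_equal(unname(f$params[c("id.sd", "residual.sd")]), polish$par,
               tolerance = 1e-3)
  expect_lte(f$m2ll, polish$value + 1e-6)
})

test_that("degenerate and incomplete data are handled explicitly", {
  dat <- data.frame(y = rep(2, 10), g = rep(c("a", "b"), 5))
  expect_error(fit(model_spec("y", random = random_term("g")), dat),
               "zero variance")

  cfg <- sim_config(n_families = 6, k_children = 3, seed = 42)
  st <- simulate_study(cfg)
  dat <- st$pheno
  dat$y[c(3, 9)] <- NA
  dat$age[5] <- NA
  expect_message(
    f <- fit(polygenic_spec("y", "age", st$A), dat),
    "dropped 3"
  )
  expect_equal(f$n_obs, nrow(dat) - 3)
  expect_equal(f$n_dropped, 3)
})

test_that("estimates are invariant to row permutation and equivariant in scale", {
  cfg <- sim_config(n_families = 8, k_children = 3, h2 = 0.5, seed = 55)
  st <- simulate_study(cfg)
  spec <- polygenic_spec("y", "age", st$A)
  f1 <- fit(spec, st$pheno)
  perm <- withr::with_seed(9, sample(nrow(st$pheno)))
  f2 <- fit(spec, st$pheno[perm, ])
  expect_equal(f1$params, f2$params, tolerance = 1e-6)
  expect_equal(f1$m2ll, f2$m2ll, tolerance = 1e-6)

  k <- 3.7
  dat_k <- st$pheno
  dat_k$y <- k * dat_k$y
  f3 <- fit(spec, dat_k)
  expect_equal(unname(f3$params), unname(k * f1$params), tolerance = 1e-5)
  expect_equal(heritability(f3), heritability(f1), tolerance = 1e-6)
})

test_that("heritability is the genetic share of the summed variance components", {
  cfg <- sim_config(n_families = 10, k_children = 3, h2 = 0.4,
                    c2_household = 0.2, seed = 66)
  st <- simulate_study(cfg)
  f <- fit(polygenic_spec("y", "age", st$A, household = "hhid"), st$pheno)
  v <- f$params^2
  expect_equal(heritability(f),
               unname(v["id.sd"] / (v["id.sd"] + v["hhid.sd"] + v["residual.sd"])))
  # a genetic variance forced to zero gives h2 = 0
  spec0 <- polygenic_spec("y", "age", st$A, household = "hhid")
  spec0$constraints <- constraint_set(fixes = list("id.sd" = 0))
  f0 <- fit(spec0, st$pheno, quiet = TRUE)
  expect_equal(heritability(f0), 0)
  expect_equal(f0$n_params, f$n_params - 1)
  # heteroscedastic fits refuse a single heritability number
  gspec <- gxe_spec("y", "age", st$A)
  gf <- fit(gspec, st$pheno, criterion = "ML", quiet = TRUE)
  expect_error(heritability(gf), "group-specific")
})

test_that("fixed and equality constraints restrict the search exactly", {
  cfg <- sim_config(n_families = 8, k_children = 3, seed = 77,
                    sex_specific = list(sg1 = 0.9, sg2 = 0.5, rho_g = 0.6,
                                        sde_m = 0.7, sde_f = 0.9))
  st <- simulate_study(cfg)
  spec <- gxe_spec("y", "age", st$A)
  f_free <- fit(spec, st$pheno, criterion = "ML", quiet = TRUE)

  spec_fix <- spec
  spec_fix$constraints <- constraint_set(fixes = list("id.cor.female.male" = 1))
  f_fix <- fit(spec_fix, st$pheno, criterion = "ML", quiet = TRUE)
  expect_equal(unname(f_fix$params["id.cor.female.male"]), 1)
  expect_equal(f_fix$n_params, f_free$n_params - 1)
  expect_gte(f_fix$m2ll, f_free$m2ll - 1e-8)  # nesting

  spec_eq <- spec
  spec_eq$constraints <- constraint_set(
    equalities = list(c("id.sd.female", "id.sd.male"))
  )
  f_eq <- fit(spec_eq, st$pheno, criterion = "ML", quiet = TRUE)
  expect_equal(unname(f_eq$params["id.sd.female"]),
               unname(f_eq$params["id.sd.male"]))
  expect_equal(f_eq$n_params, f_free$n_params - 1)

  expect_error(
    fit(model_spec("y", random = random_term("id", relmat = st$A),
                   constraints = constraint_set(fixes = list("nope.sd" = 1))),
        st$pheno, quiet = TRUE),
    "unknown parameter"
  )
})

test_that("the doubly constrained sex-specific model reproduces the polygenic fit", {
  cfg <- sim_config(n_families = 12, k_children = 3, h2 = 0.5, seed = 88)
  st <- simulate_study(cfg)

  m1 <- fit(polygenic_spec("y", "age", st$A), st$pheno, criterion = "ML",
            quiet = TRUE)
  spec <- gxe_spec("y", "age", st$A)
  spec$constraints <- constraint_set(
    fixes = list("id.cor.female.male" = 1),
    equalities = list(c("id.sd.female", "id.sd.male"),
                      c("residual.sd.female", "residual.sd.male"))
  )
  m_red <- fit(spec, st$pheno, criterion = "ML", quiet = TRUE)
  expect_equal(m_red$m2ll, m1$m2ll, tolerance = 1e-6)
  expect_equal(unname(m_red$params["id.sd.female"]), unname(m1$params["id.sd"]),
               tolerance = 1e-4)
})

test_that("fit_gxe returns properly nested ML fits with the right parameter counts", {
  cfg <- sim_config(n_families = 12, k_children = 3, seed = 99,
                    sex_specific = list(sg1 = 1, sg2 = 0.4, rho_g = 0.5,
                                        sde_m = 0.6, sde_f = 0.8))
  st <- simulate_study(cfg)
  trio <- fit_gxe(gxe_spec("y", "age", st$A), st$pheno)
  expect_equal(trio$m_rho1$n_params, trio$m_free$n_params - 1)
  expect_equal(trio$m_eqvar$n_params, trio$m_free$n_params - 1)
  expect_lte(trio$m_free$m2ll, trio$m_rho1$m2ll + 1e-6)
  expect_lte(trio$m_free$m2ll, trio$m_eqvar$m2ll + 1e-6)
  expect_equal(unname(trio$m_rho1$params["id.cor.female.male"]), 1)
})

test_that("fits serialize to JSON with estimates and convergence state", {
  dat <- sim_balanced_oneway(111, k = 8, r = 3)
  f <- fit(model_spec("y", random = random_term("grp")), dat)
  js <- jsonlite::fromJSON(fit_to_json(f))
  expect_equal(js$criterion, "REML")
  expect_true(js$converged)
  expect_equal(js$params$grp.sd, unname(f$params["grp.sd"]), tolerance = 1e-12)
  expect_equal(js$n_obs, nrow(dat))
})
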