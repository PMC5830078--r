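test_that("simulated pedigrees have the declared structure and are reproducible", {
  ped <- simulate_pedigree(sim_config(n_families = 3, k_children = 2, seed = 1))
  expect_equal(nrow(ped), 12)  # (2 parents + 2 children) x 3
  expect_equal(length(unique(ped$family_id)), 3)
  ped_b <- simulate_pedigree(sim_config(n_families = 3, k_children = 2, seed = 1))
  expect_identical(as.data.frame(ped), as.data.frame(ped_b))

  p3 <- simulate_pedigree(sim_config(n_families = 2,
                                     family_structure = "three_generation",
                                     seed = 2))
  expect_equal(nrow(p3), 20)  # 10 per family
  expect_equal(sum(is.na(p3$father_id)), 2 * 4)  # 4 founders per family

  tw <- simulate_pedigree(sim_config(n_families = 4, k_children = 2,
                                     family_structure = "with_mz_twins",
                                     mz_rate = 1, seed = 3))
  expect_equal(sum(!is.na(tw$mz_group)), 8)  # every sibship is an MZ pair
  A <- as.matrix(additive_relationship(tw)$values)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(min(ev), 1e-10)   # twins make A rank deficient
  expect_gt(min(ev), -1e-10)
})

test_that("gene-dropped genotypes obey founder frequency and transmission", {
  ped <- simulate_pedigree(sim_config(n_families = 40, k_children = 2, seed = 4))
  g <- simulate_genotypes(ped, m_snps = 2000, maf = 0.3, seed = 5)
  expect_true(all(g %in% 0:2))

  founders <- ped$id[is.na(ped$father_id)]
  p_hat <- mean(g[founders, ]) / 2
  se <- sqrt(0.3 * 0.7 / (2 * length(founders) * 2000))
  expect_lt(abs(p_hat - 0.3), 3 * se + 1e-9)

  # parent-offspring dosage correlation ~ 0.5 for a biallelic additive locus
  kids <- ped$id[!is.na(ped$father_id)]
  dads <- ped$father_id[match(kids, ped$id)]
  corr <- cor(as.vector(g[kids, ]), as.vector(g[dads, ]))
  expect_lt(abs(corr - 0.5), 0.05)

  # near-zero founder frequency gives a monomorphic panel
  g0 <- simulate_genotypes(ped, m_snps = 100, maf = 1e-6, seed = 6)
  expect_true(all(g0 == 0))

  expect_identical(simulate_genotypes(ped, 50, 0.3, seed = 9),
                   simulate_genotypes(ped, 50, 0.3, seed = 9))
})

test_that("monozygotic twins receive identical gene-dropped genotypes", {
  tw <- simulate_pedigree(sim_config(n_families = 5, k_children = 2,
                                     family_structure = "with_mz_twins",
                                     mz_rate = 1, seed = 7))
  g <- simulate_genotypes(tw, 200, 0.3, seed = 8)
  for (grp in unique(na.omit(tw$mz_group))) {
    pair <- tw$id[which(tw$mz_group == grp)]
    expect_identical(g[pair[1], ], g[pair[2], ])
  }
})

test_that("phenotypes carry the requested variance architecture", {
  # h2 = 0: sibling phenotypic correlation vanishes
  cfg0 <- sim_config(n_families = 250, k_children = 2, h2 = 0, seed = 10,
                     beta = c(intercept = 0, age = 0, female = 0))
  st0 <- simulate_study(cfg0)
  sib1 <- st0$pheno$y[seq(3, nrow(st0$pheno), by = 4)]
  sib2 <- st0$pheno$y[seq(4, nrow(st0$pheno), by = 4)]
  expect_lt(abs(cor(sib1, sib2)), 3 / sqrt(250))

  # h2 = 0.5: sib-sib correlation ~ A_ss * h2 = 0.25 (1000 sib pairs)
  cfg5 <- sim_config(n_families = 1000, k_children = 2, h2 = 0.5, seed = 14,
                     beta = c(intercept = 0, age = 0, female = 0))
  st5 <- simulate_study(cfg5)
  s1 <- st5$pheno$y[seq(3, nrow(st5$pheno), by = 4)]
  s2 <- st5$pheno$y[seq(4, nrow(st5$pheno), by = 4)]
  expect_lt(abs(cor(s1, s2) - 0.25), 0.05)

  expect_error(sim_config(h2 = 0.8, c2_household = 0.4), "must lie in")
})

test_that("simulated polygenic effects match sigma_g^2 A entrywise", {
  cfg <- sim_config(n_families = 3, k_children = 2, h2 = 1, c2_household = 0,
                    seed = 12, beta = c(intercept = 0, age = 0, female = 0))
  ped <- simulate_pedigree(cfg)
  A <- additive_relationship(ped)
  reps <- 1500
  U <- sapply(seq_len(reps), function(b) {
    cfg_b <- cfg
    cfg_b$seed <- 20000 + b
    simulate_phenotype(ped, A, cfg_b)$y
  })
  emp <- cov(t(U))
  Ad <- as.matrix(A$values)
  # entrywise Monte-Carlo 3-SE band (normal products have var 1 + A_ij^2)
  se <- sqrt((1 + Ad^2) * outer(diag(Ad), diag(Ad))) / sqrt(reps)
  expect_true(all(abs(emp - Ad) <= 3.5 * se + 0.01))
})

test_that("the sex-specific generator reduces to the shared architecture at rho = 1", {
  base <- sim_config(n_families = 400, k_children = 2, h2 = 0.5, seed = 13,
                     beta = c(intercept = 0, age = 0, female = 0))
  reduced <- sim_config(n_families = 400, k_children = 2, seed = 13,
                        beta = c(intercept = 0, age = 0, female = 0),
                        sex_specific = list(sg1 = sqrt(0.5), sg2 = sqrt(0.5),
                                            rho_g = 1,
                                            sde_m = sqrt(0.5), sde_f = sqrt(0.5)))
  y1 <- simulate_study(base)$pheno$y
  y2 <- simulate_study(reduced)$pheno$y
  # same first two moments within Monte-Carlo tolerance
  expect_lt(abs(mean(y1) - mean(y2)), 0.1)
  expect_lt(abs(var(y1) - var(y2)), 0.15)
  expect_lt(abs(var(y2) - 1), 0.15)  # total variance normalized to 1
})

test_that("study simulation is reproducible end to end under one seed", {
  cfg <- sim_config(n_families = 4, k_children = 3, h2 = 0.4, m_snps = 20,
                    seed = 14)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(as.matrix(s1$A$values), as.matrix(s2$A$values))
  expect_identical(unclass(s1$geno), unclass(s2$geno))
})
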