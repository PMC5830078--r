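write_ped_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".ped", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("LINKAGE ped files parse, preserve order, and report structure errors", {
  path <- write_ped_lines(c(
    "f1 dad 0 0 1",
    "f1 mom 0 0 2",
    "f1 kid dad mom 1"
  ))
  ped <- read_pedigree(path)
  expect_s3_class(ped, "kin_pedigree")
  expect_equal(nrow(ped), 3)
  expect_equal(ped$id, c("dad", "mom", "kid"))
  expect_equal(ped$father_id[3], "dad")
  expect_equal(ped$mother_id[3], "mom")
  expect_equal(ped$sex, c("male", "female", "male"))

  selfpath <- write_ped_lines("f1 kid kid 0 1")
  expect_error(read_pedigree(selfpath), "cycle")

  ghostpath <- write_ped_lines(c("f1 kid 99 0 1"))
  expect_error(read_pedigree(ghostpath), "99")

  # optional 7th column tags MZ twins; column 6 (phenotype) is ignored
  twinpath <- write_ped_lines(c(
    "f1 dad 0 0 1 0 0",
    "f1 mom 0 0 2 0 0",
    "f1 t1 dad mom 1 0 mz1",
    "f1 t2 dad mom 1 0 mz1"
  ))
  tw <- read_pedigree(twinpath)
  expect_equal(tw$mz_group, c(NA, NA, "mz1", "mz1"))
})

test_that("pedigree validation rejects malformed structures", {
  base <- data.frame(
    family_id = "f", id = c("a", "b"), father_id = NA, mother_id = NA,
    sex = "male"
  )
  dup <- base; dup$id <- c("a", "a")
  expect_error(pedigree(dup), "duplicated")

  # mutual parenthood is a cycle
  cyc <- data.frame(
    family_id = "f", id = c("a", "b"), father_id = c("b", "a"),
    mother_id = NA, sex = "male"
  )
  expect_error(pedigree(cyc), "cycle")

  # MZ members must share parents and sex
  tw <- data.frame(
    family_id = "f", id = c("p", "q", "t1", "t2"),
    father_id = c(NA, NA, "p", "p"), mother_id = c(NA, NA, "q", "q"),
    sex = c("male", "female", "male", "female"),
    mz_group = c(NA, NA, "m", "m")
  )
  expect_error(pedigree(tw), "sex")
})

test_that("additive relationship recursion reproduces textbook coefficients", {
  founders <- pedigree(data.frame(
    family_id = "f", id = c("a", "b"), father_id = NA, mother_id = NA,
    sex = c("male", "female")
  ))
  expect_equal(as.matrix(additive_relationship(founders)$values),
               diag(2), ignore_attr = TRUE)

  ped <- fixture_pedigree()
  A <- as.matrix(additive_relationship(ped)$values)
  expect_equal(A["p1", "s1"], 0.5)     # parent-offspring
  expect_equal(A["s1", "s2"], 0.5)     # full sibs
  expect_equal(A["p1", "p2"], 0)       # unrelated founders
  expect_equal(A["gc", "p1"], 0.25)    # grandchild
  expect_equal(A["gc", "s2"], 0.25)    # avuncular (A_s1,s2 / 2)

  # half sibs: one shared parent
  hs <- pedigree(data.frame(
    family_id = "f", id = c("d", "m1", "m2", "c1", "c2"),
    father_id = c(NA, NA, NA, "d", "d"), mother_id = c(NA, NA, NA, "m1", "m2"),
    sex = c("male", "female", "female", "male", "male")
  ))
  Ah <- as.matrix(additive_relationship(hs)$values)
  expect_equal(Ah["c1", "c2"], 0.25)

  # offspring of a full-sib mating is inbred: A_ii = 1 + 0.5 * A_sibs
  inb <- pedigree(data.frame(
    family_id = "f", id = c("p", "q", "s", "t", "z"),
    father_id = c(NA, NA, "p", "p", "s"),
    mother_id = c(NA, NA, "q", "q", "t"),
    sex = c("male", "female", "male", "female", "male")
  ))
  Ai <- as.matrix(additive_relationship(inb)$values)
  expect_equal(Ai["z", "z"], 1.25)
})

test_that("monozygotic twins duplicate rows and make A rank deficient", {
  tw <- pedigree(data.frame(
    family_id = "f", id = c("p", "q", "t1", "t2"),
    father_id = c(NA, NA, "p", "p"), mother_id = c(NA, NA, "q", "q"),
    sex = c("male", "female", "male", "male"),
    mz_group = c(NA, NA, "m", "m")
  ))
  A <- as.matrix(additive_relationship(tw)$values)
  expect_equal(A[c("t1", "t2"), c("t1", "t2")],
               matrix(1, 2, 2), ignore_attr = TRUE)
  expect_equal(A["t1", "p"], A["t2", "p"])
  expect_lt(min(eigen(A, symmetric = TRUE)$values), 1e-10)  # rank deficient
  expect_gt(min(eigen(A, symmetric = TRUE)$values), -1e-10) # but PSD
})

test_that("additive relationship matches a gene-dropping Monte-Carlo oracle", {
  ped <- fixture_pedigree()
  A <- as.matrix(additive_relationship(ped)$values)
  mc <- oracle_gene_drop_A(ped, reps = 4000, seed = 7)
  tol <- 3 * mc$se + 1e-12
  expect_true(all(abs(A - mc$A) <= tol))
})

test_that("A is invariant to record permutation and PSD over random pedigrees", {
  cfg <- sim_config(n_families = 3, k_children = 3, seed = 11)
  ped <- simulate_pedigree(cfg)
  A1 <- additive_relationship(ped)
  perm <- withr::with_seed(1, sample(nrow(ped)))
  ped2 <- pedigree(as.data.frame(ped)[perm, ])
  A2 <- additive_relationship(ped2)
  expect_equal(as.matrix(A2$values)[A1$ids, A1$ids], as.matrix(A1$values),
               tolerance = 1e-12)

  structures <- c("nuclear", "three_generation", "with_mz_twins")
  for (s in seq_len(60)) {
    cfg <- sim_config(n_families = 2, k_children = 1 + (s %% 4),
                      family_structure = structures[1 + (s %% 3)], seed = 100 + s)
    A <- as.matrix(additive_relationship(simulate_pedigree(cfg))$values)
    expect_gte(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
})

test_that("sparsity counts exact zeros and families make A block sparse", {
  expect_equal(matrix_sparsity(rel_matrix(diag(10), paste0("i", 1:10))), 0.9)
  expect_equal(matrix_sparsity(rel_matrix(matrix(1, 4, 4), paste0("i", 1:4))), 0)

  cfg <- sim_config(n_families = 20, k_children = 3, seed = 5)  # 100 individuals
  A <- additive_relationship(simulate_pedigree(cfg))
  expect_equal(length(A$ids), 100)
  expect_gte(A$sparsity, 0.7)
})

test_that("densify reaches target sparsity reproducibly and stays PSD", {
  I10 <- rel_matrix(diag(10), paste0("i", 1:10))
  expect_identical(densify(I10, 0.9, seed = 1)$values, I10$values)  # no-op

  full <- densify(I10, 0, fill_value = 0.05, seed = 2)
  expect_equal(full$sparsity, 0)
  expect_error(densify(I10, 0.95, seed = 1), "exceeds")

  cfg <- sim_config(n_families = 12, k_children = 3, seed = 9)
  A <- additive_relationship(simulate_pedigree(cfg))
  d1 <- densify(A, 0.5, fill_value = 0.01, seed = 3)
  d2 <- densify(A, 0.5, fill_value = 0.01, seed = 3)
  expect_identical(as.matrix(d1$values), as.matrix(d2$values))
  expect_equal(d1$sparsity, 0.5, tolerance = 0.01)
  expect_gte(min(eigen(as.matrix(d1$values), symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
  d3 <- densify(A, 0.5, fill_value = 0.01, seed = 4)
  expect_false(identical(as.matrix(d1$values), as.matrix(d3$values)))
})

test_that("incidence matrices are one-hot with columns in level order", {
  Z <- incidence_from_factor(c("a", "a", "b"), c("a", "b"))
  expect_equal(Z, matrix(c(1, 1, 0, 0, 0, 1), 3, 2,
                         dimnames = list(NULL, c("a", "b"))))
  expect_equal(incidence_from_factor(c("x", "y", "z"), c("x", "y", "z")),
               diag(3), ignore_attr = TRUE)
  expect_error(incidence_from_factor(c("a", "c"), c("a", "b")), "unknown")
})
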