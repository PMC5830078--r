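#' Simulation configuration
#'
#' Describes a synthetic family study: pedigree structure, variance
#' architecture and genotypes. The phenotypic variance of the random part
#' is normalized to 1, so `h2` and `c2_household` are directly the
#' simulated variance fractions.
#'
#' @param n_families number of independent families.
#' @param family_structure `"nuclear"`, `"three_generation"`, or
#'   `"with_mz_twins"`.
#' @param k_children children per sibship (nuclear / twin structures).
#' @param mz_rate probability that a sibship's first two children are
#'   monozygotic twins (`"with_mz_twins"` only).
#' @param h2 additive genetic variance fraction.
#' @param c2_household shared-household variance fraction.
#' @param sex_specific `NULL`, or a list with `sg1`, `sg2` (male/female
#'   genetic sds), `rho_g` (cross-sex genetic correlation) and `sde_m`,
#'   `sde_f` (sex-specific residual sds); overrides `h2`/`c2_household`.
#' @param beta fixed effects: named vector with `intercept`, `age`,
#'   `female`.
#' @param maf founder minor-allele frequency for simulated SNPs.
#' @param m_snps number of SNPs to gene-drop.
#' @param seed master integer seed; all operations derive reproducible
#'   sub-streams from it.
#' @return a `kin_sim_config`.
#' @export
sim_config <- function(n_families = 30L,
                       family_structure = c("nuclear", "three_generation",
                                            "with_mz_twins"),
                       k_children = 3L, mz_rate = 0.5,
                       h2 = 0.5, c2_household = 0,
                       sex_specific = NULL,
                       beta = c(intercept = 0, age = 0.02, female = 0.2),
                       maf = 0.3, m_snps = 0L, seed = 1L) {
  family_structure <- match.arg(family_structure)
  if (is.null(sex_specific)) {
    if (h2 < 0 || c2_household < 0 || h2 + c2_household > 1) {
      stopf("h2 + c2_household must lie in [0, 1] (got %g + %g)", h2, c2_household)
    }
  } else {
    need <- c("sg1", "sg2", "rho_g", "sde_m", "sde_f")
    miss <- setdiff(need, names(sex_specific))
    if (length(miss)) stopf("sex_specific is missing: %s", paste(miss, collapse = ", "))
    if (abs(sex_specific$rho_g) > 1) stopf("|rho_g| must be <= 1")
  }
  if (maf <= 0 || maf > 0.5) stopf("maf must lie in (0, 0.5]")
  structure(
    list(n_families = as.integer(n_families),
         family_structure = family_structure,
         k_children = as.integer(k_children), mz_rate = mz_rate,
         h2 = h2, c2_household = c2_household, sex_specific = sex_specific,
         beta = beta, maf = maf, m_snps = as.integer(m_snps),
         seed = as.integer(seed)),
    class = "kin_sim_config"
  )
}

#' Simulate a pedigree
#'
#' Nuclear families are two founder parents plus `k_children` offspring of
#' random sex. Three-generation families add a founder grandparental
#' couple whose two children each marry a founder spouse and have two
#' offspring (10 individuals). The twin structure is nuclear with the
#' first two children replaced by a same-sex monozygotic pair at rate
#' `mz_rate`.
#'
#' @param cfg a [sim_config()].
#' @return a [pedigree()], reproducible under `cfg$seed`.
#' @export
simulate_pedigree <- function(cfg) {
  with_seed(sub_seed(cfg$seed, 1L), {
    rows <- list()
    add <- function(fam, id, fa, mo, sex, mz = NA_character_, gen = 0L) {
      rows[[length(rows) + 1L]] <<- data.frame(
        family_id = fam, id = id, father_id = fa, mother_id = mo,
        sex = sex, mz_group = mz, generation = gen, stringsAsFactors = FALSE
      )
    }
    for (f in seq_len(cfg$n_families)) {
      fam <- sprintf("F%02d", f)
      mk <- function(i) sprintf("%s_I%02d", fam, i)
      if (cfg$family_structure %in% c("nuclear", "with_mz_twins")) {
        add(fam, mk(1), NA, NA, "male")
        add(fam, mk(2), NA, NA, "female")
        mz <- cfg$family_structure == "with_mz_twins" &&
          cfg$k_children >= 2 && stats::runif(1) < cfg$mz_rate
        sexes <- sample(c("male", "female"), cfg$k_children, replace = TRUE)
        if (mz) sexes[2] <- sexes[1]
        for (k in seq_len(cfg$k_children)) {
          add(fam, mk(2 + k), mk(1), mk(2), sexes[k],
              mz = if (mz && k <= 2) paste0(fam, "_mz1") else NA_character_,
              gen = 1L)
        }
      } else {  # three_generation
        add(fam, mk(1), NA, NA, "male")
        add(fam, mk(2), NA, NA, "female")
        csex <- sample(c("male", "female"), 2, replace = TRUE)
        for (c in 1:2) {
          cid <- mk(2 + c)
          add(fam, cid, mk(1), mk(2), csex[c], gen = 1L)
          sid <- mk(4 + c)
          add(fam, sid, NA, NA, if (csex[c] == "male") "female" else "male", gen = 1L)
          fa <- if (csex[c] == "male") cid else sid
          mo <- if (csex[c] == "male") sid else cid
          for (k in 1:2) {
            add(fam, sprintf("%s_I%02d", fam, 6 + 2 * (c - 1) + k), fa, mo,
                sample(c("male", "female"), 1), gen = 2L)
          }
        }
      }
    }
    df <- do.call(rbind, rows)
    ped <- pedigree(df[, c("family_id", "id", "father_id", "mother_id",
                           "sex", "mz_group")])
    attr(ped, "generation") <- df$generation
    ped
  })
}

#' Simulate genotypes by gene dropping
#'
#' Founders draw two alleles i.i.d. Bernoulli(`maf`); each non-founder
#' inherits one uniformly chosen allele from each parent. Monozygotic
#' twins copy their co-twin's genotype. Dosage is the allele sum.
#'
#' @param ped a [pedigree()].
#' @param m_snps number of independent SNPs.
#' @param maf founder allele frequency.
#' @param seed integer seed.
#' @return a [genotype_table()] (individuals x SNPs).
#' @export
simulate_genotypes <- function(ped, m_snps, maf, seed = 1L) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- ifelse(is.na(ped$father_id), NA_integer_, idx[ped$father_id])
  mo <- ifelse(is.na(ped$mother_id), NA_integer_, idx[ped$mother_id])
  ord <- pedigree_order(ped)
  with_seed(seed, {
    a1 <- matrix(0L, n, m_snps)
    a2 <- matrix(0L, n, m_snps)
    mz_first <- list()
    for (i in ord) {
      g <- ped$mz_group[i]
      if (!is.na(g) && !is.null(mz_first[[g]])) {
        r <- mz_first[[g]]
        a1[i, ] <- a1[r, ]
        a2[i, ] <- a2[r, ]
        next
      }
      if (is.na(fa[i])) {
        a1[i, ] <- stats::rbinom(m_snps, 1L, maf)
      } else {
        pick <- stats::runif(m_snps) < 0.5
        a1[i, ] <- ifelse(pick, a1[fa[i], ], a2[fa[i], ])
      }
      if (is.na(mo[i])) {
        a2[i, ] <- stats::rbinom(m_snps, 1L, maf)
      } else {
        pick <- stats::runif(m_snps) < 0.5
        a2[i, ] <- ifelse(pick, a1[mo[i], ], a2[mo[i], ])
      }
      if (!is.na(g)) mz_first[[g]] <- i
    }
    genotype_table(a1 + a2, ids = ped$id,
                   snp_names = sprintf("snp%04d", seq_len(m_snps)))
  })
}

#' Simulate phenotypes under the model's variance architectures
#'
#' Generates `y = X beta + u + c + e` on one row per individual: `u` is the
#' polygenic effect drawn with covariance `h2 * A` (via [factor_relmat()],
#' so rank-deficient twin matrices are handled), `c` a household-shared
#' normal effect with variance `c2_household`, and `e` i.i.d. residuals
#' with variance `1 - h2 - c2`. With `cfg$sex_specific`, `u` is drawn with
#' covariance `A` masked by the sex-pair kernel (sg1, sg2, rho_g) and `e`
#' has sex-specific sds. Age is simulated uniformly by generation; sex
#' comes from the pedigree. An optional causal SNP adds
#' `causal_beta * dosage` to `y`.
#'
#' @param ped a [pedigree()] (from [simulate_pedigree()]).
#' @param A optional precomputed [rel_matrix()]; computed from `ped` when
#'   `NULL`.
#' @param cfg a [sim_config()].
#' @param causal_geno,causal_beta optional dosage vector (named by id) and
#'   its effect size.
#' @return data frame with columns id, family_id, hhid, sex, age, y.
#' @export
simulate_phenotype <- function(ped, A = NULL, cfg, causal_geno = NULL,
                               causal_beta = 0) {
  if (is.null(A)) A <- additive_relationship(ped)
  A <- as_rel_matrix(A)
  n <- nrow(ped)
  stopifnot(identical(A$ids, ped$id))
  gen <- attr(ped, "generation") %||% ifelse(is.na(ped$father_id), 0L, 1L)
  hhid <- household_of(ped)
  with_seed(sub_seed(cfg$seed, 2L), {
    age <- stats::runif(n, 0, 10) + c(55, 35, 15)[gen + 1L]
    female <- as.numeric(ped$sex == "female")
    Xb <- cfg$beta[["intercept"]] + cfg$beta[["age"]] * age +
      cfg$beta[["female"]] * female
    Fz <- factor_relmat(A)
    if (is.null(cfg$sex_specific)) {
      u <- sqrt(cfg$h2) * as.vector(Fz$L %*% stats::rnorm(Fz$rank))
      hh_eff <- stats::setNames(stats::rnorm(length(unique(hhid)),
                                             0, sqrt(cfg$c2_household)),
                                unique(hhid))
      cc <- as.numeric(hh_eff[hhid])
      e <- stats::rnorm(n, 0, sqrt(1 - cfg$h2 - cfg$c2_household))
    } else {
      ss <- cfg$sex_specific
      sds <- ifelse(ped$sex == "female", ss$sg2, ss$sg1)
      Kpair <- outer(sds, sds)
      cross <- outer(ped$sex, ped$sex, FUN = function(a, b) a != b)
      Kpair[cross] <- Kpair[cross] * ss$rho_g
      V <- as.matrix(A$values) * Kpair
      Fv <- factor_relmat(rel_matrix(V, ped$id))
      u <- as.vector(Fv$L %*% stats::rnorm(Fv$rank))
      cc <- 0
      e <- stats::rnorm(n, 0, ifelse(ped$sex == "female", ss$sde_f, ss$sde_m))
    }
    y <- as.numeric(Xb + u + cc + e)
    if (!is.null(causal_geno)) {
      y <- y + causal_beta * as.numeric(causal_geno[ped$id])
    }
    data.frame(id = ped$id, family_id = ped$family_id, hhid = hhid,
               sex = ped$sex, age = age, y = y, stringsAsFactors = FALSE)
  })
}

# Households: each child-rearing couple and its children share a household;
# founders without offspring-partners keep their own.
household_of <- function(ped) {
  couple <- ifelse(is.na(ped$father_id), NA_character_,
                   paste(ped$father_id, ped$mother_id, sep = "+"))
  hh <- ifelse(is.na(couple), NA_character_, couple)
  # parents join the household keyed by their own couple id
  for (i in seq_len(nrow(ped))) {
    if (!is.na(hh[i])) next
    own <- which(!is.na(couple) &
                   (ped$father_id == ped$id[i] | ped$mother_id == ped$id[i]))
    hh[i] <- if (length(own)) couple[own[1]] else paste0("solo_", ped$id[i])
  }
  paste0("hh_", hh)
}

#' Simulate a full synthetic study
#'
#' Convenience wrapper: pedigree, relationship matrix, phenotypes, and
#' (optionally) genotypes.
#'
#' @param cfg a [sim_config()].
#' @return list with `ped`, `A`, `pheno`, and `geno` (when
#'   `cfg$m_snps > 0`).
#' @export
simulate_study <- function(cfg) {
  ped <- simulate_pedigree(cfg)
  A <- additive_relationship(ped)
  pheno <- simulate_phenotype(ped, A, cfg)
  geno <- if (cfg$m_snps > 0) {
    simulate_genotypes(ped, cfg$m_snps, cfg$maf, seed = sub_seed(cfg$seed, 3L))
  }
  list(ped = ped, A = A, pheno = pheno, geno = geno)
}
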