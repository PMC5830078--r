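# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive, dense, from-scratch implementations that share no code
# with the package internals they check.

# -2 log (restricted) likelihood from an explicitly assembled dense Sigma.
oracle_m2ll <- function(y, X, Sigma, criterion = "REML") {
  n <- length(y)
  p <- ncol(X)
  Si <- solve(Sigma)
  XtSiX <- t(X) %*% Si %*% X
  beta <- solve(XtSiX, t(X) %*% Si %*% y)
  r <- y - X %*% beta
  quad <- as.numeric(t(r) %*% Si %*% r)
  ldet <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  if (criterion == "ML") {
    n * log(2 * pi) + ldet + quad
  } else {
    (n - p) * log(2 * pi) + ldet +
      as.numeric(determinant(XtSiX, logarithm = TRUE)$modulus) + quad
  }
}

# Dense covariance assembled by explicit elementwise loops:
#   terms: list of list(A = dense matrix over ids, g = per-row id,
#                       sd = scalar  [intercept term]
#                  or   sds = named by level, cors = matrix of correlations,
#                       f = per-row level  [group-specific term])
#   resid: list(sd = scalar) or list(sds = named by level, f = per-row level)
oracle_sigma <- function(n, terms, resid) {
  S <- matrix(0, n, n)
  for (tm in terms) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        a <- tm$A[tm$g[i], tm$g[j]]
        S[i, j] <- S[i, j] + if (!is.null(tm[["sd"]])) {
          tm[["sd"]]^2 * a
        } else {
          si <- tm$sds[[tm$f[i]]]
          sj <- tm$sds[[tm$f[j]]]
          rho <- if (tm$f[i] == tm$f[j]) 1 else tm$cors[tm$f[i], tm$f[j]]
          a * rho * si * sj
        }
      }
    }
  }
  for (i in seq_len(n)) {
    S[i, i] <- S[i, i] + if (!is.null(resid[["sd"]])) resid[["sd"]]^2 else resid$sds[[resid$f[i]]]^2
  }
  S
}

# Monte-Carlo gene-dropping estimate of A = 2 * kinship, with per-entry
# standard errors. Two alleles per founder, Mendelian transmission, IBD
# sharing counted over `reps` replicates.
oracle_gene_drop_A <- function(ped, reps = 10000, seed = 1) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- ifelse(is.na(ped$father_id), NA_integer_, idx[ped$father_id])
  mo <- ifelse(is.na(ped$mother_id), NA_integer_, idx[ped$mother_id])
  # parents-before-children order by repeated sweeps (independent of the
  # package's topological sort)
  ord <- integer(0)
  left <- seq_len(n)
  while (length(left)) {
    ready <- left[vapply(left, function(i) {
      (is.na(fa[i]) || fa[i] %in% ord) && (is.na(mo[i]) || mo[i] %in% ord)
    }, TRUE)]
    stopifnot(length(ready) > 0)
    ord <- c(ord, ready)
    left <- setdiff(left, ready)
  }
  withr::local_seed(seed)
  a1 <- matrix(0L, n, reps)
  a2 <- matrix(0L, n, reps)
  next_allele <- 1L
  mz_seen <- list()
  for (i in ord) {
    g <- ped$mz_group[i]
    if (!is.na(g) && !is.null(mz_seen[[g]])) {
      r <- mz_seen[[g]]
      a1[i, ] <- a1[r, ]
      a2[i, ] <- a2[r, ]
      next
    }
    if (is.na(fa[i])) {
      a1[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(reps) < 0.5
      a1[i, ] <- ifelse(pick, a1[fa[i], ], a2[fa[i], ])
    }
    if (is.na(mo[i])) {
      a2[i, ] <- next_allele; next_allele <- next_allele + 1L
    } else {
      pick <- stats::runif(reps) < 0.5
      a2[i, ] <- ifelse(pick, a1[mo[i], ], a2[mo[i], ])
    }
    if (!is.na(g)) mz_seen[[g]] <- i
  }
  Ahat <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  Ase <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      share <- (a1[i, ] == a1[j, ]) + (a1[i, ] == a2[j, ]) +
        (a2[i, ] == a1[j, ]) + (a2[i, ] == a2[j, ])
      x <- share / 2   # per-replicate estimate of A_ij
      Ahat[i, j] <- Ahat[j, i] <- mean(x)
      Ase[i, j] <- Ase[j, i] <- stats::sd(x) / sqrt(reps)
    }
  }
  list(A = Ahat, se = Ase)
}

# Closed-form REML estimates for a balanced one-way random-intercept design.
oracle_anova_oneway <- function(y, group) {
  g <- factor(group)
  k <- nlevels(g)
  r <- length(y) / k
  gm <- tapply(y, g, mean)
  msa <- r * sum((gm - mean(y))^2) / (k - 1)
  mse <- sum((y - gm[g])^2) / (k * (r - 1))
  c(var_group = (msa - mse) / r, var_resid = mse)
}

# Random PSD matrix with ids; rank-deficient when rank < dim.
random_psd <- function(dim, rank = dim, seed = 1) {
  withr::local_seed(seed)
  B <- matrix(rnorm(dim * rank), dim, rank)
  M <- B %*% t(B) + diag(1e-6, dim)  # near-PSD, PD when rank = dim
  if (rank < dim) M <- B %*% t(B)    # exactly rank-deficient
  rownames(M) <- colnames(M) <- paste0("id", seq_len(dim))
  M
}

# Small fixed pedigree fixture: two founders, two full sibs, one grandchild
# via a founder spouse.
fixture_pedigree <- function() {
  pedigree(data.frame(
    family_id = "f1",
    id = c("p1", "p2", "s1", "s2", "sp", "gc"),
    father_id = c(NA, NA, "p1", "p1", NA, "s1"),
    mother_id = c(NA, NA, "p2", "p2", NA, "sp"),
    sex = c("male", "female", "male", "female", "female", "male")
  ))
}
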