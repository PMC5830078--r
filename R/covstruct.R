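#' Factor a relationship matrix for the Z* = Z L substitution
#'
#' A structured random effect u ~ N(0, sigma^2 Z A Z') can be rewritten with
#' an unstructured effect by replacing the incidence matrix Z with
#' Z* = Z L where L L' = A. For positive-definite A, L is the lower
#' Cholesky triangle; for positive semi-definite A (e.g. pedigrees with
#' monozygotic twins) L = V diag(sqrt(lambda)) from the eigendecomposition,
#' keeping only eigenvalues above tolerance, so L has `rank` columns.
#'
#' @param A a [rel_matrix()] or symmetric matrix.
#' @param psd_tol tolerance for treating eigenvalues as zero, relative to the
#'   largest eigenvalue.
#' @return object of class `kin_factorization` with elements `L` (rows named
#'   by the relmat ids), `rank`, and `method` (`"cholesky"` or `"eigen"`).
#' @export
factor_relmat <- function(A, psd_tol = 1e-8) {
  A <- as_rel_matrix(A)
  M <- as.matrix(A$values)
  n <- nrow(M)
  e <- eigen(M, symmetric = TRUE)
  scale <- max(abs(e$values[1]), 1)
  tol <- psd_tol * scale
  if (min(e$values) < -tol) {
    stopf("matrix is not positive semi-definite: eigenvalue %.6g below -%.3g",
          min(e$values), tol)
  }
  L <- NULL
  method <- "cholesky"
  if (min(e$values) > tol) {
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (!is.null(ch)) L <- t(ch)
  }
  if (is.null(L)) {  # semi-definite (or chol failed despite PD): eigen path
    keep <- which(e$values > tol)
    L <- e$vectors[, keep, drop = FALSE] %*% diag(sqrt(e$values[keep]), length(keep))
    method <- "eigen"
  }
  dimnames(L) <- list(A$ids, NULL)
  err <- max(abs(L %*% t(L) - M))
  if (err > 1e-8 * max(1, max(abs(M)))) {
    stopf("factorization failed to reconstruct the matrix (error %.3g)", err)
  }
  structure(list(L = L, rank = ncol(L), method = method),
            class = "kin_factorization")
}

#' @exportS3Method base::print
print.kin_factorization <- function(x, ...) {
  cat(sprintf("<kin_factorization> %s, %d x %d, rank %d\n",
              x$method, nrow(x$L), ncol(x$L), x$rank))
  invisible(x)
}

#' Substituted random-effect design Z* = Z L
#'
#' @param Z incidence matrix (rows = observations, columns = relmat ids).
#' @param F a [factor_relmat()] result aligned with Z's columns.
#' @return Z* such that `Z* t(Z*) = Z A t(Z)`.
#' @export
substituted_design <- function(Z, F) {
  if (!inherits(F, "kin_factorization")) stopf("'F' must come from factor_relmat()")
  if (ncol(Z) != nrow(F$L)) {
    stopf("dimension mismatch: Z is %d x %d but L is %d x %d",
          nrow(Z), ncol(Z), nrow(F$L), ncol(F$L))
  }
  as.matrix(Z %*% F$L)
}

#' Random-effect term of a mixed model
#'
#' @param grouping name of the data column holding the grouping factor
#'   (e.g. individual id, household id).
#' @param relmat optional [rel_matrix()] giving the covariance between
#'   grouping levels; `NULL` means identity (i.i.d. levels).
#' @param within `"intercept"` for a single variance, or
#'   [group_slopes()] for group-specific variances with cross-group genetic
#'   correlations (the sex-specific model).
#' @param sds,cors optional known parameter values (standard deviations and
#'   correlations); left `NA` when the parameters are to be estimated.
#' @param label name used in parameter paths; defaults to `grouping`.
#' @return a `kin_random_term`.
#' @export
random_term <- function(grouping, relmat = NULL, within = "intercept",
                        sds = NULL, cors = NULL, label = grouping) {
  if (!is.null(relmat)) relmat <- as_rel_matrix(relmat)
  if (is.character(within)) {
    stopifnot(identical(within, "intercept"))
    within <- list(type = "intercept")
  }
  stopifnot(within$type %in% c("intercept", "group_slopes"))
  structure(
    list(grouping = grouping, relmat = relmat, within = within,
         sds = sds, cors = cors, label = label),
    class = "kin_random_term"
  )
}

#' @rdname random_term
#' @param factor name of the data column whose levels index the
#'   group-specific standard deviations.
#' @export
group_slopes <- function(factor) list(type = "group_slopes", factor = factor)

#' Residual structure of a mixed model
#'
#' @param type `"homoscedastic"` (one residual variance) or `"by_group"`
#'   (one residual variance per level of `factor`, modelling residual
#'   heteroscedasticity between e.g. males and females).
#' @param factor grouping column for `"by_group"`.
#' @param sds optional known residual standard deviation(s).
#' @return a `kin_residual_spec`.
#' @export
residual_spec <- function(type = c("homoscedastic", "by_group"),
                          factor = NULL, sds = NULL) {
  type <- match.arg(type)
  if (type == "by_group" && is.null(factor)) stopf("by_group residual needs 'factor'")
  structure(list(type = type, factor = factor, sds = sds),
            class = "kin_residual_spec")
}

term_levels <- function(term, data) {
  g <- as.character(data[[term$grouping]])
  if (!is.null(term$relmat)) {
    ids <- term$relmat$ids
    missing <- setdiff(unique(g), ids)
    if (length(missing)) {
      stopf("grouping levels absent from the relationship matrix: %s",
            paste(utils::head(missing, 5), collapse = ", "))
    }
    ids[ids %in% g]
  } else {
    sort(unique(g))
  }
}

# Observation-level covariance base Z A Z' for a term (sparse symmetric).
term_zazt <- function(term, data) {
  levels <- term_levels(term, data)
  Z <- sparse_incidence(data[[term$grouping]], levels)
  if (!is.null(term$relmat)) {
    A <- term$relmat$values[levels, levels, drop = FALSE]
    as(Matrix::forceSymmetric(Z %*% A %*% Matrix::t(Z)), "CsparseMatrix")
  } else {
    as(Matrix::forceSymmetric(Matrix::tcrossprod(Z)), "CsparseMatrix")
  }
}

# Hadamard masks per factor-level pair for a group_slopes term, applied to
# the observation-level base Z A Z'. Returns list(comps, labels, kinds).
group_slope_components <- function(base, fvals, flevels) {
  k <- length(flevels)
  comps <- list()
  for (a in seq_len(k)) {
    ua <- as.numeric(fvals == flevels[a])
    comps[[length(comps) + 1L]] <-
      as(Matrix::forceSymmetric(base * Matrix::tcrossprod(Matrix::Matrix(ua, ncol = 1))),
         "CsparseMatrix")
  }
  if (k >= 2) {
    for (a in seq_len(k - 1)) {
      for (b in seq((a + 1), k)) {
        ua <- as.numeric(fvals == flevels[a])
        ub <- as.numeric(fvals == flevels[b])
        M <- Matrix::Matrix(ua, ncol = 1) %*% Matrix::t(Matrix::Matrix(ub, ncol = 1))
        M <- M + Matrix::t(M)
        comps[[length(comps) + 1L]] <-
          as(Matrix::forceSymmetric(base * M), "CsparseMatrix")
      }
    }
  }
  comps
}

slope_pairs <- function(k) {
  if (k < 2) return(matrix(integer(0), ncol = 2))
  t(utils::combn(k, 2))
}

# Coefficients multiplying the term's covariance components given parameters.
term_coefs <- function(nlev, sds, cors) {
  if (nlev == 1) return(sds[1]^2)
  prs <- slope_pairs(nlev)
  c(sds^2, cors * sds[prs[, 1]] * sds[prs[, 2]])
}

#' Observation-level covariance contributed by one random term
#'
#' For an intercept term the contribution is `sd^2 * Z A Z'`. For a
#' [group_slopes()] term with levels l1..lk the contribution at observations
#' i, j is `A_g(i)g(j) * K_l(i)l(j)` where K has `sds[a]^2` on the diagonal
#' and `cors_ab * sds[a] * sds[b]` off it — the sex-specific genetic model
#' with variances sg1^2, sg2^2 and cross-sex covariance rho_g sg1 sg2.
#'
#' @param term a [random_term()] with `sds` (and `cors` if needed) set.
#' @param data data frame holding the grouping (and factor) columns.
#' @return dense symmetric covariance matrix, one row per data row.
#' @export
term_covariance <- function(term, data) {
  base <- term_zazt(term, data)
  if (term$within$type == "intercept") {
    if (is.null(term$sds) || length(term$sds) != 1 || is.na(term$sds[1])) {
      stopf("term '%s': one sd value is required", term$label)
    }
    return(as.matrix(term$sds[1]^2 * base))
  }
  f <- as.character(data[[term$within$factor]])
  flev <- sort(unique(f))
  k <- length(flev)
  if (is.null(term$sds) || length(term$sds) != k) {
    stopf("term '%s': factor '%s' has %d levels but %d sds supplied",
          term$label, term$within$factor, k, length(term$sds %||% numeric(0)))
  }
  ncor <- k * (k - 1) / 2
  if (ncor > 0 && (is.null(term$cors) || length(term$cors) != ncor)) {
    stopf("term '%s': %d correlations required", term$label, ncor)
  }
  comps <- group_slope_components(base, f, flev)
  coefs <- term_coefs(k, term$sds, term$cors %||% numeric(0))
  as.matrix(Reduce(`+`, Map(`*`, coefs, comps)))
}

#' Residual covariance matrix
#'
#' @param spec a [residual_spec()] with `sds` set.
#' @param data data frame (supplies the grouping factor and row count).
#' @return diagonal covariance matrix: `sd^2 I` when homoscedastic, the
#'   level-specific variance per row when `by_group`.
#' @export
residual_covariance <- function(spec, data) {
  n <- nrow(data)
  if (spec$type == "homoscedastic") {
    if (length(spec$sds) != 1) stopf("homoscedastic residual needs one sd")
    return(diag(spec$sds[1]^2, n))
  }
  f <- as.character(data[[spec$factor]])
  flev <- sort(unique(f))
  if (length(spec$sds) != length(flev)) {
    stopf("residual factor '%s' has levels %s but %d sds supplied",
          spec$factor, paste(flev, collapse = ", "), length(spec$sds))
  }
  v <- stats::setNames(spec$sds^2, flev)
  diag(v[f], n)
}
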