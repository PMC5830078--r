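# Internal model context: cleaned data, fixed design, per-term sparse
# covariance components, residual indicators, parameter table and the
# constraint mapping. Everything downstream (likelihood, fitting, profile,
# bootstrap refits) works off this object; only `y` changes across
# simulation refits.

build_context <- function(spec, data, quiet = FALSE, extra_cols = character(0)) {
  stopifnot(inherits(spec, "kin_model_spec"))
  used <- unique(c(
    spec$response, spec$fixed,
    unlist(lapply(spec$random, function(t) {
      c(t$grouping, if (t$within$type == "group_slopes") t$within$factor)
    })),
    if (spec$residual$type == "by_group") spec$residual$factor,
    extra_cols
  ))
  miss <- setdiff(used, names(data))
  if (length(miss)) stopf("data is missing columns: %s", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(data[used])
  n_dropped <- sum(!keep)
  if (n_dropped > 0 && !quiet) {
    kin_log("data", "dropped %d of %d rows with missing values in used columns",
            n_dropped, nrow(data))
  }
  data <- data[keep, used, drop = FALSE]
  n <- nrow(data)
  if (n < 1) stopf("no complete observations")
  y <- as.numeric(data[[spec$response]])

  X <- stats::model.matrix(
    if (length(spec$fixed)) stats::reformulate(spec$fixed) else ~1, data
  )
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stopf("fixed-effect design is rank deficient; collinear column(s): %s",
          paste(bad, collapse = ", "))
  }

  par_names <- character(0)
  par_kind <- character(0)
  terms <- list()
  for (t in spec$random) {
    base <- term_zazt(t, data)
    if (t$within$type == "intercept") {
      terms[[length(terms) + 1L]] <- list(
        label = t$label, nlev = 1L, comps = list(base),
        par_idx = length(par_names) + 1L, n_par = 1L
      )
      par_names <- c(par_names, paste0(t$label, ".sd"))
      par_kind <- c(par_kind, "sd")
    } else {
      f <- as.character(data[[t$within$factor]])
      flev <- sort(unique(f))
      k <- length(flev)
      if (k < 2) stopf("group_slopes factor '%s' has fewer than 2 levels", t$within$factor)
      comps <- group_slope_components(base, f, flev)
      prs <- slope_pairs(k)
      nm <- c(paste0(t$label, ".sd.", flev),
              paste0(t$label, ".cor.", flev[prs[, 1]], ".", flev[prs[, 2]]))
      terms[[length(terms) + 1L]] <- list(
        label = t$label, nlev = k, comps = comps,
        par_idx = length(par_names) + 1L, n_par = length(nm)
      )
      par_names <- c(par_names, nm)
      par_kind <- c(par_kind, rep(c("sd", "cor"), c(k, nrow(prs))))
    }
  }
  if (spec$residual$type == "homoscedastic") {
    res_groups <- list(rep(TRUE, n))
    res_names <- "residual.sd"
  } else {
    f <- as.character(data[[spec$residual$factor]])
    flev <- sort(unique(f))
    res_groups <- lapply(flev, function(l) f == l)
    res_names <- paste0("residual.sd.", flev)
  }
  res_idx <- length(par_names) + seq_along(res_names)
  par_names <- c(par_names, res_names)
  par_kind <- c(par_kind, rep("sd", length(res_names)))

  par_table <- data.frame(name = par_names, kind = par_kind,
                          stringsAsFactors = FALSE)
  # dense evaluation wins for small n or genuinely dense covariance
  # patterns; block-sparse family structures use the sparse path
  pat_nnz <- n + sum(vapply(terms, function(t) {
    sum(vapply(t$comps, function(m) length(m@x), 0))
  }, 0))
  dense <- n <= 150L || (n <= DENSE_N_MAX && pat_nnz / n^2 >= 0.05)
  sparse_cache <- NULL
  if (dense) {
    for (i in seq_along(terms)) {
      terms[[i]]$comps <- lapply(terms[[i]]$comps, as.matrix)
    }
  } else {
    # union sparsity pattern over all components + the diagonal; each
    # component's entries are mapped into the union so Sigma(theta) is
    # assembled by pure numeric accumulation, and the Cholesky symbolic
    # analysis is done once and reused by numeric updates
    comps_all <- c(unlist(lapply(terms, `[[`, "comps"), recursive = FALSE))
    U <- Matrix::Diagonal(n, 1)
    for (cm in comps_all) U <- U + abs(cm)
    U <- as(Matrix::forceSymmetric(U), "CsparseMatrix")
    ukey <- sparse_entry_keys(U, n)
    maps <- lapply(comps_all, function(cm) {
      match(sparse_entry_keys(as(Matrix::forceSymmetric(cm), "CsparseMatrix"), n), ukey)
    })
    diag_map <- match((seq_len(n) - 1) * n + seq_len(n), ukey)
    ch_sym <- Matrix::Cholesky(U, LDL = FALSE, perm = TRUE)
    sparse_cache <- list(U = U, maps = maps, diag_map = diag_map,
                         ch_sym = ch_sym,
                         comp_x = lapply(comps_all, function(cm) {
                           as(Matrix::forceSymmetric(cm), "CsparseMatrix")@x
                         }))
  }
  ctx <- list(
    spec = spec, data = data, y = y, X = X, n = n, p = ncol(X),
    terms = terms, res_groups = res_groups, res_idx = res_idx,
    par_table = par_table, n_dropped = n_dropped, dense = dense,
    sparse_cache = sparse_cache,
    ids = if ("id" %in% names(data)) as.character(data$id) else rownames(data)
  )
  ctx$cmap <- resolve_constraints(spec$constraints, par_table)
  ctx
}

# Map the constraint set onto the parameter table. Returns a list with
#   full_of_free(theta_free) -> full natural-scale vector
#   free_names, free_kind, n_free, fixed mask/values
resolve_constraints <- function(cons, par_table) {
  nm <- par_table$name
  npar <- length(nm)
  unknown <- setdiff(c(names(cons$fixes), unlist(cons$equalities)), nm)
  if (length(unknown)) {
    stopf("constraint refers to unknown parameter(s): %s (known: %s)",
          paste(unknown, collapse = ", "), paste(nm, collapse = ", "))
  }
  group <- seq_len(npar)          # union-find over parameter indices
  findr <- function(i) { while (group[i] != i) i <- group[i]; i }
  for (eq in cons$equalities) {
    idx <- match(eq, nm)
    if (length(unique(par_table$kind[idx])) > 1) {
      stopf("equality constraint mixes sd and cor parameters: %s",
            paste(eq, collapse = ", "))
    }
    r <- findr(idx[1])
    for (j in idx[-1]) group[findr(j)] <- r
  }
  root <- vapply(seq_len(npar), findr, 1L)

  fixed_val <- rep(NA_real_, npar)
  for (fnm in names(cons$fixes)) {
    i <- match(fnm, nm)
    v <- as.numeric(cons$fixes[[fnm]])
    if (par_table$kind[i] == "cor" && abs(v) > 1) stopf("fixed correlation |%s| > 1", fnm)
    if (par_table$kind[i] == "sd" && v < 0) stopf("fixed sd %s < 0", fnm)
    r <- root[i]
    if (!is.na(fixed_val[r]) && fixed_val[r] != v) {
      stopf("conflicting fixed values within an equality group (%s)", fnm)
    }
    fixed_val[r] <- v
  }
  roots <- unique(root)
  free_roots <- roots[is.na(fixed_val[roots])]
  free_names <- nm[free_roots]
  free_kind <- par_table$kind[free_roots]
  full_of_free <- function(theta_free) {
    vals <- fixed_val
    vals[free_roots] <- theta_free
    vals[root]
  }
  list(full_of_free = full_of_free, free_names = free_names,
       free_kind = free_kind, n_free = length(free_roots),
       free_roots = free_roots, root = root, fixed_val = fixed_val)
}

# Assemble Sigma(theta_full): dense base matrix at desk scale, sparse
# symmetric Matrix for large sparse-kinship problems.
assemble_sigma <- function(ctx, par_full) {
  rv <- numeric(ctx$n)
  res_sds <- par_full[ctx$res_idx]
  for (i in seq_along(ctx$res_groups)) rv[ctx$res_groups[[i]]] <- res_sds[i]^2
  if (ctx$dense) {
    S <- diag(rv, ctx$n)
    for (t in ctx$terms) {
      pars <- par_full[t$par_idx + seq_len(t$n_par) - 1L]
      coefs <- term_coefs(t$nlev, pars[seq_len(t$nlev)],
                          if (t$n_par > t$nlev) pars[(t$nlev + 1):t$n_par] else numeric(0))
      for (i in seq_along(coefs)) {
        if (coefs[i] != 0) S <- S + coefs[i] * t$comps[[i]]
      }
    }
    return(S)
  }
  cache <- ctx$sparse_cache
  x <- numeric(length(cache$U@x))
  k <- 0L
  for (t in ctx$terms) {
    pars <- par_full[t$par_idx + seq_len(t$n_par) - 1L]
    coefs <- term_coefs(t$nlev, pars[seq_len(t$nlev)],
                        if (t$n_par > t$nlev) pars[(t$nlev + 1):t$n_par] else numeric(0))
    for (i in seq_along(coefs)) {
      k <- k + 1L
      if (coefs[i] == 0) next
      idx <- cache$maps[[k]]
      x[idx] <- x[idx] + coefs[i] * cache$comp_x[[k]]
    }
  }
  x[cache$diag_map] <- x[cache$diag_map] + rv
  S <- cache$U
  S@x <- x
  S
}

# 0-based-column keys identifying (i, j) slots of a CsparseMatrix.
sparse_entry_keys <- function(m, n) {
  j0 <- rep(seq_len(n) - 1L, diff(m@p))
  as.numeric(j0) * n + m@i + 1
}

BIG_PENALTY <- 1e10

# Below this size a dense Cholesky beats sparse analysis + factorization;
# the sparse path is what makes large sparse-kinship fits scale.
DENSE_N_MAX <- 400L

# Core evaluation: -2 log (restricted) likelihood with beta profiled out by
# GLS. Returns the penalty value when Sigma(theta) is not positive definite.
m2ll_ctx <- function(ctx, par_full, criterion = "REML", y = NULL, details = FALSE) {
  y <- y %||% ctx$y
  S <- assemble_sigma(ctx, par_full)
  X <- ctx$X
  if (ctx$dense) {
    R <- tryCatch(chol(as.matrix(S)), error = function(e) NULL)
    if (is.null(R)) {
      if (details) stopf("covariance matrix is singular at the supplied parameters")
      return(BIG_PENALTY)
    }
    ldet <- 2 * sum(log(diag(R)))
    if (!is.finite(ldet)) {
      return(if (details) stopf("singular covariance") else BIG_PENALTY)
    }
    # whitened solves through the triangular factor
    Xw <- backsolve(R, X, transpose = TRUE)
    yw <- backsolve(R, y, transpose = TRUE)
    XtSiX <- crossprod(Xw)
    XtSiy <- crossprod(Xw, yw)
    beta <- tryCatch(solve(XtSiX, XtSiy), error = function(e) NULL)
    if (is.null(beta)) return(if (details) stopf("singular GLS system") else BIG_PENALTY)
    rw <- yw - as.vector(Xw %*% beta)
    quad <- sum(rw^2)
  } else {
    ch <- tryCatch(Matrix::update(ctx$sparse_cache$ch_sym, S),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(ch)) {
      if (details) stopf("covariance matrix is singular at the supplied parameters")
      return(BIG_PENALTY)
    }
    ldet <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
    if (!is.finite(ldet)) return(if (details) stopf("singular covariance") else BIG_PENALTY)
    SiX <- as.matrix(Matrix::solve(ch, X, system = "A"))
    XtSiX <- crossprod(X, SiX)
    XtSiy <- crossprod(SiX, y)
    beta <- tryCatch(solve(XtSiX, XtSiy), error = function(e) NULL)
    if (is.null(beta)) return(if (details) stopf("singular GLS system") else BIG_PENALTY)
    r <- y - as.vector(X %*% beta)
    Sir <- as.vector(Matrix::solve(ch, r, system = "A"))
    quad <- sum(r * Sir)
  }
  n <- ctx$n; p <- ctx$p
  val <- if (criterion == "ML") {
    n * log(2 * pi) + ldet + quad
  } else {
    ldx <- determinant(XtSiX, logarithm = TRUE)
    (n - p) * log(2 * pi) + ldet + as.numeric(ldx$modulus) + quad
  }
  if (!is.finite(val)) return(if (details) stopf("non-finite likelihood") else BIG_PENALTY)
  if (!details) return(val)
  vcov_beta <- solve(XtSiX)
  dimnames(vcov_beta) <- list(colnames(X), colnames(X))
  list(m2ll = val, beta = stats::setNames(as.vector(beta), colnames(X)),
       vcov_beta = vcov_beta, sigma = S)
}

#' Minus twice the (restricted) log-likelihood of a mixed model
#'
#' Evaluates -2 log L at a full variance-parameter vector (order and names
#' as given by [spec_params()]), with fixed effects profiled out by
#' generalized least squares. The REML criterion adds the
#' `log det(X' Sigma^-1 X)` term of the restricted likelihood.
#'
#' @param spec a [model_spec()].
#' @param theta numeric vector of variance parameters on the natural scale
#'   (standard deviations and correlations), optionally named.
#' @param data data frame.
#' @param criterion `"REML"` or `"ML"`.
#' @return the -2 log-likelihood value.
#' @export
neg2_loglik <- function(spec, theta, data, criterion = c("REML", "ML")) {
  criterion <- match.arg(criterion)
  ctx <- build_context(spec, data, quiet = TRUE)
  npar <- nrow(ctx$par_table)
  if (!is.null(names(theta)) && all(names(theta) != "")) {
    miss <- setdiff(ctx$par_table$name, names(theta))
    if (length(miss)) stopf("theta is missing parameter(s): %s", paste(miss, collapse = ", "))
    theta <- theta[ctx$par_table$name]
  }
  if (length(theta) != npar) {
    stopf("theta has %d values; %d parameters expected (%s)",
          length(theta), npar, paste(ctx$par_table$name, collapse = ", "))
  }
  m2ll_ctx(ctx, as.numeric(theta), criterion, details = TRUE)$m2ll
}
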