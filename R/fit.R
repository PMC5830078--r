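# Optimizer space: standard deviations on [0, sd_cap], correlations directly
# on [-1, 1]. The direct correlation scale keeps the rho = 1 boundary (the
# no-interaction null, often the free MLE in small samples) attainable in a
# finite number of steps; a tanh-type transform puts it at infinity and
# stalls derivative-free optimizers on the flat ridge.
BOUNDARY_TOL <- 1e-4

free_to_natural <- function(x, kind) x
natural_to_free <- function(v, kind) {
  ifelse(kind == "cor", pmin(pmax(v, -1), 1), v)
}

default_starts <- function(ctx, cmap, sd_y) {
  v <- sd_y^2
  n_blocks <- length(ctx$terms) + 1L
  mk <- function(term_share, resid_share) {
    full <- numeric(nrow(ctx$par_table))
    for (t in ctx$terms) {
      idx <- t$par_idx + seq_len(t$n_par) - 1L
      sds <- sqrt(term_share * v / max(1, length(ctx$terms)))
      full[idx[seq_len(t$nlev)]] <- sds
      # correlations start at 0
    }
    full[ctx$res_idx] <- sqrt(resid_share * v)
    full
  }
  starts <- list(
    mk(1 - 1 / n_blocks, 1 / n_blocks),  # equal split across blocks
    mk(0.1, 0.9),                        # residual-dominant
    mk(0.9, 0.1)                         # structured-dominant
  )
  lapply(starts, function(full) full[cmap$free_roots])
}

#' Fit a structured linear mixed model
#'
#' Minimizes [neg2_loglik()] over the free variance parameters after
#' applying the model's [constraint_set()] (fixed parameters are removed
#' from the search, equalities collapse to one free value). Standard
#' deviations are box-constrained at 0, correlations at +/-1; optimization
#' uses a bounded derivative-free local search from three deterministic
#' starting points (equal-split, residual-dominant, structured-dominant),
#' keeping the best optimum. Rows with missing values in any used column
#' are dropped with a logged count.
#'
#' @param spec a [model_spec()].
#' @param data data frame.
#' @param criterion `"REML"` (default; use for variance estimation) or
#'   `"ML"` (required when a likelihood ratio test compares models that
#'   differ in fixed effects).
#' @param optimizer_config list with any of `n_starts` (default 3),
#'   `maxfun` (default 2000), `rhoend` (final trust-region radius, default
#'   1e-8), `start` (named numeric vector of natural-scale starting values).
#' @param quiet suppress the dropped-rows log line.
#' @return a `kin_fit` with elements `beta`, `params` (named natural-scale
#'   estimates), `m2ll`, `loglik`, `criterion`, `converged`, `n_obs`,
#'   `n_params` (free parameter count), `boundary_flags`, `vcov_beta`.
#' @export
fit <- function(spec, data, criterion = c("REML", "ML"),
                optimizer_config = list(), quiet = FALSE) {
  criterion <- match.arg(criterion)
  ctx <- build_context(spec, data, quiet = quiet)
  fit_ctx(ctx, criterion, optimizer_config)
}

fit_ctx <- function(ctx, criterion, optimizer_config = list(), y = NULL) {
  cfg <- utils::modifyList(
    list(n_starts = 3L, maxfun = 2000L, rhoend = 1e-8, start = NULL),
    optimizer_config
  )
  y <- y %||% ctx$y
  if (ctx$n < 2) stopf("fewer than 2 complete observations")
  if (stats::var(y) == 0) {
    stopf("degenerate data: response '%s' has zero variance", ctx$spec$response)
  }
  cmap <- ctx$cmap
  kind <- cmap$free_kind
  sd_cap <- 25 * max(stats::sd(y), 1e-6)
  lower <- ifelse(kind == "cor", -1, 0)
  upper <- ifelse(kind == "cor", 1, sd_cap)

  objective <- function(x) {
    m2ll_ctx(ctx, cmap$full_of_free(free_to_natural(x, kind)), criterion, y = y)
  }

  starts <- default_starts(ctx, cmap, stats::sd(y))
  if (!is.null(cfg$start)) {
    s <- cfg$start
    if (!is.null(names(s))) {
      full <- numeric(nrow(ctx$par_table))
      full[match(names(s), ctx$par_table$name)] <- as.numeric(s)
      s <- full[cmap$free_roots]
    }
    starts <- c(list(natural_to_free(s, kind)), starts)
  }
  starts <- starts[seq_len(min(length(starts), max(1L, cfg$n_starts)))]

  best <- NULL
  n_free <- cmap$n_free
  for (s in starts) {
    s <- pmin(pmax(s, lower), upper)
    res <- if (n_free == 0L) {
      list(par = numeric(0), fval = objective(numeric(0)), ierr = 0L)
    } else if (n_free == 1L) {
      o <- stats::optimize(function(x) objective(x), lower = lower, upper = upper,
                           tol = 1e-10)
      list(par = o$minimum, fval = o$objective, ierr = 0L)
    } else {
      b <- tryCatch(
        minqa::bobyqa(s, objective, lower = lower, upper = upper,
                      control = list(maxfun = cfg$maxfun, rhoend = cfg$rhoend,
                                     iprint = 0)),
        error = function(e) NULL
      )
      if (is.null(b)) NULL else list(par = b$par, fval = b$fval, ierr = b$ierr)
    }
    if (is.null(res) || !is.finite(res$fval)) next
    if (is.null(best) || res$fval < best$fval) best <- res
  }

  # polish: restart the search at the incumbent with a small trust region,
  # which also recovers runs stopped at the evaluation cap
  if (!is.null(best) && n_free >= 2L) {
    b2 <- tryCatch(
      minqa::bobyqa(pmin(pmax(best$par, lower), upper), objective,
                    lower = lower, upper = upper,
                    control = list(maxfun = cfg$maxfun,
                                   rhobeg = 0.02, rhoend = cfg$rhoend,
                                   iprint = 0)),
      error = function(e) NULL
    )
    if (!is.null(b2) && is.finite(b2$fval) && b2$fval <= best$fval) {
      best <- list(par = b2$par, fval = b2$fval,
                   ierr = min(best$ierr, b2$ierr))
    }
  }

  converged <- !is.null(best) && best$ierr == 0L && best$fval < BIG_PENALTY / 2
  if (is.null(best)) {
    best <- list(par = starts[[1]], fval = objective(starts[[1]]), ierr = 1L)
  }
  if (!converged) {
    warning("model fit did not converge after ", length(starts),
            " optimizer starts; estimates are flagged", call. = FALSE)
  }

  par_full <- cmap$full_of_free(free_to_natural(best$par, kind))
  names(par_full) <- ctx$par_table$name
  det <- m2ll_ctx(ctx, par_full, criterion, y = y, details = TRUE)

  bflags <- vapply(seq_along(par_full), function(i) {
    if (ctx$par_table$kind[i] == "sd") {
      par_full[i] <= BOUNDARY_TOL || par_full[i] >= sd_cap - BOUNDARY_TOL
    } else {
      abs(par_full[i]) >= 1 - BOUNDARY_TOL
    }
  }, TRUE)
  names(bflags) <- names(par_full)

  structure(
    list(
      beta = det$beta, params = par_full, m2ll = det$m2ll,
      loglik = -det$m2ll / 2, criterion = criterion, converged = converged,
      n_obs = ctx$n, n_dropped = ctx$n_dropped, n_params = cmap$n_free,
      boundary_flags = bflags, vcov_beta = det$vcov_beta,
      spec = ctx$spec, ctx = ctx, y = y
    ),
    class = "kin_fit"
  )
}

# Refit the same model (same rows, same design) to a new response vector;
# used by simulation-based tests. Warm-started from the original estimates.
refit_response <- function(fit, ynew, n_starts = 2L, maxfun = 600L) {
  fit_ctx(fit$ctx, fit$criterion,
          list(start = fit$params, n_starts = n_starts, maxfun = maxfun,
               rhoend = 1e-7),
          y = ynew)
}

#' @exportS3Method base::print
print.kin_fit <- function(x, ...) {
  cat(sprintf("<kin_fit> %s, -2 logLik = %.4f, n = %d%s\n",
              x$criterion, x$m2ll, x$n_obs,
              if (x$converged) "" else " (NOT CONVERGED)"))
  cat("Fixed effects:\n")
  print(round(x$beta, 4))
  cat("Variance parameters (sd scale):\n")
  est <- round(x$params, 4)
  flag <- ifelse(x$boundary_flags, " [boundary]", "")
  for (i in seq_along(est)) cat(sprintf("  %s = %s%s\n", names(est)[i], est[i], flag[i]))
  invisible(x)
}

#' Variance parameters of a fit as variances
#' @param fit a `kin_fit`.
#' @return named vector of variance-scale estimates (correlations as-is).
#' @export
varcomp <- function(fit) {
  kind <- fit$ctx$par_table$kind
  out <- ifelse(kind == "sd", fit$params^2, fit$params)
  names(out) <- sub("\\.sd", ".var", names(fit$params))
  out
}

#' Narrow-sense heritability from a polygenic fit
#'
#' The proportion of phenotypic variance attributed to the genetic random
#' effect: `sigma_g^2 / (sigma_g^2 + other term variances + sigma_e^2)`.
#' Requires a homoscedastic model (a single residual variance and
#' intercept-only random terms); for sex-specific models report the
#' group-specific variance fractions instead.
#'
#' @param fit a converged `kin_fit`.
#' @param term label of the genetic term; defaults to the first term that
#'   carries a relationship matrix.
#' @return heritability in [0, 1].
#' @export
heritability <- function(fit, term = NULL) {
  spec <- fit$spec
  if (spec$residual$type != "homoscedastic") {
    stopf(paste("heritability is defined for homoscedastic models;",
                "use the group-specific variance summaries for",
                "heteroscedastic fits"))
  }
  if (any(vapply(spec$random, function(t) t$within$type, "") != "intercept")) {
    stopf("heritability requires intercept-only random terms")
  }
  if (is.null(term)) {
    has_rm <- vapply(spec$random, function(t) !is.null(t$relmat), TRUE)
    if (!any(has_rm)) stopf("no random term carries a relationship matrix")
    term <- spec$random[[which(has_rm)[1]]]$label
  }
  vg <- unname(fit$params[paste0(term, ".sd")]^2)
  total <- sum(fit$params[fit$ctx$par_table$kind == "sd"]^2)
  if (total == 0) return(0)
  vg / total
}

#' Fit the gene-environment trio: free, rho_g = 1, equal variances
#'
#' Fits the sex-specific model (free sg1, sg2, rho_g and group-specific
#' residual variances) and its two null restrictions: the cross-group
#' genetic correlation fixed at 1, and the group variances constrained
#' equal. All three use ML so likelihood ratio tests are comparable.
#'
#' @param spec a [gxe_spec()]-style model: one [group_slopes()] genetic
#'   term and a `by_group` residual.
#' @param data data frame.
#' @param optimizer_config passed to [fit()].
#' @return list with elements `m_free`, `m_rho1`, `m_eqvar` (class
#'   `kin_gxe_fits`).
#' @export
fit_gxe <- function(spec, data, optimizer_config = list()) {
  gs <- which(vapply(spec$random, function(t) t$within$type, "") == "group_slopes")
  if (length(gs) == 0) stopf("fit_gxe needs a group_slopes random term")
  if (spec$residual$type != "by_group") stopf("fit_gxe needs a by_group residual")
  t1 <- spec$random[[gs[1]]]
  pars <- spec_params(spec, data)
  cor_names <- grep(paste0("^", t1$label, "\\.cor\\."), pars$name, value = TRUE)
  sd_names <- grep(paste0("^", t1$label, "\\.sd\\."), pars$name, value = TRUE)

  add_constraints <- function(spec, fixes = list(), equalities = list()) {
    cs <- spec$constraints
    spec$constraints <- constraint_set(
      fixes = c(as.list(cs$fixes), fixes),
      equalities = c(cs$equalities, equalities)
    )
    spec
  }
  m_free <- fit(spec, data, criterion = "ML", optimizer_config = optimizer_config)
  m_rho1 <- fit(add_constraints(spec, fixes = stats::setNames(as.list(rep(1, length(cor_names))), cor_names)),
                data, criterion = "ML", optimizer_config = optimizer_config, quiet = TRUE)
  m_eqvar <- fit(add_constraints(spec, equalities = list(sd_names)),
                 data, criterion = "ML", optimizer_config = optimizer_config, quiet = TRUE)
  # the free optimum can never exceed a constrained one; if a null fit beats
  # the free fit (free MLE on the rho = 1 boundary), restart the free search
  # from that solution
  for (m0 in list(m_rho1, m_eqvar)) {
    if (m_free$m2ll > m0$m2ll - 1e-10) {
      cand <- fit(spec, data, criterion = "ML",
                  optimizer_config = utils::modifyList(
                    optimizer_config, list(start = m0$params, n_starts = 1L)),
                  quiet = TRUE)
      if (cand$m2ll < m_free$m2ll) m_free <- cand
    }
  }
  structure(list(m_free = m_free, m_rho1 = m_rho1, m_eqvar = m_eqvar),
            class = "kin_gxe_fits")
}

#' Serialize a fit to JSON
#'
#' @param fit a `kin_fit`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
fit_to_json <- function(fit, path = NULL) {
  obj <- list(
    criterion = fit$criterion,
    converged = fit$converged,
    n_obs = fit$n_obs,
    n_dropped = fit$n_dropped,
    n_free_params = fit$n_params,
    minus2_loglik = fit$m2ll,
    beta = as.list(fit$beta),
    params = as.list(fit$params),
    boundary = as.list(fit$boundary_flags),
    constraints = list(
      fixes = as.list(fit$spec$constraints$fixes),
      equalities = fit$spec$constraints$equalities
    )
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
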