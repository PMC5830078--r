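new_test_result <- function(statistic, df, p_value, method, details = list()) {
  structure(
    list(statistic = max(0, statistic), df = df,
         p_value = min(max(p_value, 0), 1), method = method, details = details),
    class = "kin_test"
  )
}

#' @exportS3Method base::print
print.kin_test <- function(x, ...) {
  dfs <- if (length(x$df) > 1) paste0("mixture(", paste(x$df, collapse = ","), ")") else x$df
  cat(sprintf("<kin_test> %s: stat = %.4f, df = %s, p = %.4g\n",
              x$method, x$statistic, dfs, x$p_value))
  invisible(x)
}

#' Likelihood ratio test between nested fits
#'
#' The statistic is `max(0, -2ll_null + 2ll_alt)`. With a regular null the
#' reference distribution is chi-square with df = difference in free
#' parameter counts. When the null pins a parameter at the boundary of its
#' space (a variance at 0, or a correlation at 1), the reference is the
#' equal mixture of chi-square(df-1) and chi-square(df).
#'
#' @param fit_null,fit_alt `kin_fit`s of nested models on the same data and
#'   criterion.
#' @param null_on_boundary use the boundary chi-square mixture.
#' @return a `kin_test`.
#' @export
lrt <- function(fit_null, fit_alt, null_on_boundary = FALSE) {
  if (!identical(fit_null$criterion, fit_alt$criterion)) {
    stopf("criterion mismatch: null is %s, alternative is %s",
          fit_null$criterion, fit_alt$criterion)
  }
  if (fit_null$n_obs != fit_alt$n_obs) {
    stopf("sample size mismatch: null n = %d, alternative n = %d",
          fit_null$n_obs, fit_alt$n_obs)
  }
  df <- fit_alt$n_params - fit_null$n_params
  if (df < 0) stopf("null model has more free parameters than the alternative")
  stat <- max(0, fit_null$m2ll - fit_alt$m2ll)
  p <- lrt_pvalue(stat, df, null_on_boundary)
  new_test_result(stat, if (null_on_boundary) c(max(df - 1, 0), df) else df,
                  p, if (null_on_boundary) "lrt_mixture" else "lrt_chisq")
}

lrt_pvalue <- function(stat, df, boundary = FALSE) {
  if (stat <= 0) return(1)
  if (!boundary) {
    if (df == 0) return(as.numeric(stat <= 0))
    return(stats::pchisq(stat, df, lower.tail = FALSE))
  }
  df_lo <- max(df - 1, 0)
  p_lo <- if (df_lo == 0) 0 else stats::pchisq(stat, df_lo, lower.tail = FALSE)
  0.5 * p_lo + 0.5 * stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Simulation-based restricted likelihood ratio test for a variance component
#'
#' Tests whether the variance of one random term is zero. The observed REML
#' likelihood-ratio statistic is compared against its null distribution
#' obtained by parametric simulation: the null model (without the term) is
#' fitted, `n_sim` response vectors are drawn from it, and both models are
#' refitted to each draw. This generalizes to models with multiple
#' structured random terms, where the spectral fast algorithms for
#' single-random-effect models do not apply. The p-value uses the
#' `(1 + #{sim >= obs}) / (1 + n_sim)` estimator, so it is never exactly 0.
#'
#' @param spec the alternative model ([model_spec()]).
#' @param term_index index (in `spec$random`) of the term under test.
#' @param data data frame.
#' @param n_sim number of null simulations; values below 100 are flagged as
#'   low-resolution in the result.
#' @param seed integer seed; the same seed reproduces the same p-value.
#' @return a `kin_test` with `details$n_sim`, `details$obs`,
#'   `details$low_n_sim`.
#' @export
rlrt_sim <- function(spec, term_index, data, n_sim = 200L, seed = 1L) {
  stopifnot(term_index >= 1, term_index <= length(spec$random))
  ctx_alt <- build_context(spec, data)
  null_spec <- drop_term(spec, term_index, ctx_alt$par_table$name)
  # same rows for both models
  ctx_null <- build_context(null_spec, ctx_alt$data, quiet = TRUE)

  fit_alt <- fit_ctx(ctx_alt, "REML")
  fit_null <- fit_ctx(ctx_null, "REML")
  obs <- max(0, fit_null$m2ll - fit_alt$m2ll)

  mu <- as.vector(ctx_null$X %*% fit_null$beta)
  S0 <- as.matrix(assemble_sigma(ctx_null, fit_null$params))
  R <- chol(S0)
  n <- ctx_null$n
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(b) {
      ystar <- mu + as.vector(crossprod(R, stats::rnorm(n)))
      f0 <- refit_response(fit_null, ystar)
      f1 <- refit_response(fit_alt, ystar)
      max(0, f0$m2ll - f1$m2ll)
    }, 0)
  })
  p <- (1 + sum(sims >= obs)) / (1 + n_sim)
  new_test_result(obs, df = 1L, p, "rlrt_sim",
                  details = list(n_sim = n_sim, obs = obs, sims = sims,
                                 low_n_sim = n_sim < 100,
                                 fit_null = fit_null, fit_alt = fit_alt))
}

# Remove one random term from a spec, discarding constraints that refer to
# parameters that no longer exist.
drop_term <- function(spec, term_index, old_par_names) {
  lab <- spec$random[[term_index]]$label
  spec$random <- spec$random[-term_index]
  gone <- grepl(paste0("^", lab, "\\."), old_par_names)
  gone_names <- old_par_names[gone]
  cs <- spec$constraints
  fixes <- cs$fixes[!(names(cs$fixes) %in% gone_names)]
  eqs <- Filter(function(eq) !any(eq %in% gone_names), cs$equalities)
  spec$constraints <- constraint_set(as.list(fixes), eqs)
  spec
}

#' Profile-deviance confidence interval
#'
#' Endpoints are where the profiled -2 log-likelihood rises by the
#' chi-square(1) quantile of `level` above its minimum. The target is
#' either `"h2"` — heritability profiled directly, with the genetic
#' variance reparameterized as `h2/(1-h2)` times the sum of the remaining
#' variance components and all other parameters re-optimized — or a
#' parameter path (see [spec_params()]), profiled by fixing it and
#' refitting. Endpoints are located by monotone bisection to 1e-4 on the
#' target scale. If the profile never crosses the threshold before a
#' parameter bound, the interval is one-sided and the bound is flagged.
#'
#' @param spec,data the fitted model and its data.
#' @param fit the `kin_fit` to profile around.
#' @param target `"h2"` or a parameter path.
#' @param level confidence level (default 0.95).
#' @return a `kin_interval`: list with `lower`, `upper`, `estimate`,
#'   `level`, `target`, `lower_at_bound`, `upper_at_bound`.
#' @export
profile_ci <- function(spec, data, fit, target = "h2", level = 0.95) {
  if (!fit$converged) stopf("profile_ci needs a converged fit")
  q <- stats::qchisq(level, 1)
  dev_min <- fit$m2ll
  ctx <- fit$ctx

  if (identical(target, "h2")) {
    est <- heritability(fit)
    prof <- make_h2_profiler(fit)
    lo_bound <- 0
    hi_bound <- 0.999
  } else {
    if (!target %in% ctx$par_table$name) {
      stopf("unknown profile target '%s'", target)
    }
    est <- unname(fit$params[target])
    kind <- ctx$par_table$kind[ctx$par_table$name == target]
    prof <- make_param_profiler(fit, target)
    lo_bound <- if (kind == "cor") -0.9999 else 0
    hi_bound <- if (kind == "cor") 0.9999 else max(4 * est, 4 * stats::sd(fit$y))
  }

  # allow for profile minima slightly below the reported optimum
  dev_at_est <- prof(est)
  dev_min <- min(dev_min, dev_at_est)
  threshold <- dev_min + q
  g <- function(x) prof(x) - threshold

  lower_at_bound <- FALSE
  g_lo <- g(lo_bound)
  lower <- if (g_lo <= 0) { lower_at_bound <- TRUE; lo_bound } else {
    bisect_root(g, lo_bound, est, g_lo, dev_at_est - threshold)
  }
  upper_at_bound <- FALSE
  g_hi <- g(hi_bound)
  upper <- if (g_hi <= 0) { upper_at_bound <- TRUE; hi_bound } else {
    bisect_root(g, hi_bound, est, g_hi, dev_at_est - threshold)
  }
  structure(
    list(lower = min(lower, est), upper = max(upper, est), estimate = est,
         level = level, target = target,
         lower_at_bound = lower_at_bound, upper_at_bound = upper_at_bound),
    class = "kin_interval"
  )
}

#' @exportS3Method base::print
print.kin_interval <- function(x, ...) {
  cat(sprintf("<kin_interval> %s = %.4f, %g%% CI [%.4f, %.4f]%s\n",
              x$target, x$estimate, 100 * x$level, x$lower, x$upper,
              if (x$lower_at_bound || x$upper_at_bound) " (at bound)" else ""))
  invisible(x)
}

# Bisection between an exterior point (g > 0) and the estimate (g < 0).
bisect_root <- function(g, x_out, x_in, g_out, g_in, tol = 1e-4) {
  if (g_in > 0) return(x_in)  # degenerate: profile already above threshold
  while (abs(x_out - x_in) > tol) {
    mid <- (x_out + x_in) / 2
    if (g(mid) > 0) x_out <- mid else x_in <- mid
  }
  (x_out + x_in) / 2
}

# Profiled deviance in h2: the genetic sd is a deterministic function of the
# remaining variance components; the rest are re-optimized.
make_h2_profiler <- function(fit) {
  ctx <- fit$ctx
  spec <- fit$spec
  if (spec$residual$type != "homoscedastic" ||
      any(vapply(spec$random, function(t) t$within$type, "") != "intercept")) {
    stopf("h2 profiling needs a homoscedastic intercept-terms model")
  }
  has_rm <- vapply(spec$random, function(t) !is.null(t$relmat), TRUE)
  glab <- spec$random[[which(has_rm)[1]]]$label
  g_all <- which(ctx$par_table$name == paste0(glab, ".sd"))
  cmap <- ctx$cmap
  root_g <- cmap$root[g_all]
  if (!is.na(cmap$fixed_val[root_g]) || sum(cmap$root == root_g) > 1) {
    stopf("the genetic sd must be a free, unaliased parameter to profile h2")
  }
  g_free_pos <- match(root_g, cmap$free_roots)
  kind <- cmap$free_kind
  sd_mask <- ctx$par_table$kind == "sd"
  warm <- new.env()
  warm$x <- natural_to_free(fit$params[cmap$free_roots], kind)[-g_free_pos]

  function(h2) {
    h2 <- min(max(h2, 0), 0.999)
    obj <- function(x_rest) {
      x_full_free <- append(x_rest, 0, after = g_free_pos - 1)
      full <- cmap$full_of_free(free_to_natural(x_full_free, kind))
      v_other <- sum(full[sd_mask]^2) - full[g_all[1]]^2
      full[cmap$root == root_g] <- sqrt(h2 / (1 - h2) * v_other)
      m2ll_ctx(ctx, full, fit$criterion)
    }
    n_rest <- cmap$n_free - 1L
    sd_cap <- 25 * max(stats::sd(ctx$y), 1e-6)
    lower <- ifelse(kind[-g_free_pos] == "cor", -1, 0)
    upper <- ifelse(kind[-g_free_pos] == "cor", 1, sd_cap)
    res <- if (n_rest == 0L) {
      list(par = numeric(0), fval = obj(numeric(0)))
    } else if (n_rest == 1L) {
      o <- stats::optimize(obj, lower = lower, upper = upper, tol = 1e-9)
      list(par = o$minimum, fval = o$objective)
    } else {
      b <- minqa::bobyqa(pmin(pmax(warm$x, lower), upper), obj,
                         lower = lower, upper = upper,
                         control = list(maxfun = 500, rhoend = 1e-7, iprint = 0))
      list(par = b$par, fval = b$fval)
    }
    if (length(res$par)) warm$x <- res$par
    res$fval
  }
}

make_param_profiler <- function(fitted, target) {
  spec <- fitted$spec
  function(v) {
    spec2 <- spec
    spec2$constraints <- constraint_set(
      fixes = c(as.list(spec$constraints$fixes), stats::setNames(list(v), target)),
      equalities = spec$constraints$equalities
    )
    f <- fit(spec2, fitted$ctx$data, criterion = fitted$criterion,
             optimizer_config = list(start = fitted$params, n_starts = 2L,
                                     maxfun = 500L, rhoend = 1e-7),
             quiet = TRUE)
    f$m2ll
  }
}

#' The two gene-environment interaction tests
#'
#' Compares the free sex-specific model against its two null restrictions:
#' cross-group genetic correlation equal to 1 (a boundary null, tested with
#' the chi-square mixture) and equal group variances (tested with
#' chi-square(1)).
#'
#' @param fits a [fit_gxe()] result (or its three fits as separate
#'   arguments `m_free`, `m_rho1`, `m_eqvar`).
#' @param m_rho1,m_eqvar optional, when `fits` is the free fit.
#' @return list with `rho_test` and `var_test`, both `kin_test`.
#' @export
gxe_test_pair <- function(fits, m_rho1 = NULL, m_eqvar = NULL) {
  if (inherits(fits, "kin_gxe_fits")) {
    m_free <- fits$m_free; m_rho1 <- fits$m_rho1; m_eqvar <- fits$m_eqvar
  } else {
    m_free <- fits
  }
  list(
    rho_test = lrt(m_rho1, m_free, null_on_boundary = TRUE),
    var_test = lrt(m_eqvar, m_free, null_on_boundary = FALSE)
  )
}
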