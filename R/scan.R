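#' Genotype dosage table
#'
#' @param dosages numeric matrix, individuals x SNPs, values in [0, 2],
#'   `NA` allowed; row names are individual ids, column names SNP names.
#' @param ids,snp_names optional overrides for the dimnames.
#' @return a `kin_geno` (the matrix with validated dimnames and range).
#' @export
genotype_table <- function(dosages, ids = NULL, snp_names = NULL) {
  dosages <- as.matrix(dosages)
  if (!is.null(ids)) rownames(dosages) <- as.character(ids)
  if (!is.null(snp_names)) colnames(dosages) <- as.character(snp_names)
  if (is.null(rownames(dosages))) stopf("genotype table needs individual ids as row names")
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- paste0("snp", seq_len(ncol(dosages)))
  }
  if (anyDuplicated(rownames(dosages))) stopf("duplicated individual ids in genotypes")
  rng <- range(dosages, na.rm = TRUE)
  if (ncol(dosages) > 0 && (rng[1] < 0 || rng[2] > 2)) {
    stopf("dosages must lie in [0, 2]; observed range [%g, %g]", rng[1], rng[2])
  }
  class(dosages) <- c("kin_geno", class(dosages))
  dosages
}

#' Minor allele frequency of a dosage vector
#'
#' @param dosages numeric vector of allele dosages in [0, 2]; `NA` allowed.
#' @return `min(p, 1 - p)` with `p = mean(dosage) / 2` over non-missing
#'   entries.
#' @export
maf <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (!length(d)) stopf("cannot compute MAF: all dosages are missing")
  p <- mean(d) / 2
  min(p, 1 - p)
}

#' Filter SNPs by minor allele frequency
#'
#' SNPs with MAF strictly below `maf_min` are removed (a SNP exactly at the
#' threshold is kept). Kept/removed counts are logged and attached as
#' attributes.
#'
#' @param g a [genotype_table()].
#' @param maf_min minimum allele frequency (e.g. 0.01).
#' @return the filtered genotype table with attributes `n_kept`,
#'   `n_removed`.
#' @export
filter_snps <- function(g, maf_min) {
  mafs <- apply(g, 2, maf)
  keep <- mafs >= maf_min
  kin_log("maf_filter", "kept %d of %d SNPs (removed %d with MAF < %g)",
          sum(keep), length(keep), sum(!keep), maf_min)
  out <- genotype_table(g[, keep, drop = FALSE])
  attr(out, "n_kept") <- sum(keep)
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Per-SNP association scan against a structured mixed-model null
#'
#' Tests each SNP for association with the response while accounting for
#' the null model's random-effect structure. Three tests are available:
#' \describe{
#'   \item{`lrt`}{per SNP, ML fits of the null and the SNP model on the
#'     rows with non-missing dosage; chi-square(1) likelihood ratio test.}
#'   \item{`wald`}{ML fit of the SNP model; `(beta/se)^2` against
#'     chi-square(1).}
#'   \item{`score2step`}{the fast two-step mode: variance components are
#'     frozen at the null REML fit and each SNP is tested by generalized
#'     least squares with the fixed covariance, so no mixed model is
#'     refitted per SNP. Labelled approximate in the output.}
#' }
#' Rows with missing dosage are dropped per SNP (`n_used` records the rows
#' used). Results are identical for any `workers` value; parallel slices
#' are reassembled in SNP order.
#'
#' @param null_spec the null [model_spec()] (no SNP term).
#' @param data data frame; must contain an `id_col` column matching the
#'   genotype row names.
#' @param g a [genotype_table()].
#' @param test `"lrt"`, `"wald"` or `"score2step"`.
#' @param workers number of parallel worker processes.
#' @param seed accepted for interface uniformity; the scan is
#'   deterministic.
#' @param id_col name of the id column in `data`.
#' @return a `kin_assoc` data frame: snp, n_used, maf, beta, se, stat, p,
#'   test.
#' @export
assoc_scan <- function(null_spec, data, g, test = c("lrt", "wald", "score2step"),
                 workers = 1L, seed = 1L, id_col = "id") {
  test <- match.arg(test)
  if (!id_col %in% names(data)) stopf("data lacks id column '%s'", id_col)
  ctx <- build_context(null_spec, data, quiet = FALSE, extra_cols = id_col)
  ids <- as.character(ctx$data[[id_col]])
  unmatched <- setdiff(ids, rownames(g))
  if (length(unmatched)) {
    stopf("ids missing from the genotype table: %s",
          paste(utils::head(unmatched, 10), collapse = ", "))
  }
  G <- g[ids, , drop = FALSE]
  m <- ncol(G)
  if (m == 0L) return(empty_assoc(test))

  crit <- if (test == "score2step") "REML" else "ML"
  null_fit <- fit_ctx(ctx, crit)

  snp_fun <- make_snp_tester(ctx, null_fit, test)
  idx <- seq_len(m)
  run_slice <- function(jj) lapply(jj, function(j) snp_fun(G[, j], colnames(G)[j]))
  rows <- if (workers > 1L) {
    chunk <- ceiling(length(idx) / workers)
    slices <- split(idx, ceiling(seq_along(idx) / chunk))  # contiguous, ordered
    unlist(parallel::mclapply(slices, run_slice, mc.cores = workers),
           recursive = FALSE)
  } else {
    run_slice(idx)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("kin_assoc", "data.frame")
  out
}

empty_assoc <- function(test) {
  out <- data.frame(snp = character(0), n_used = integer(0), maf = numeric(0),
                    beta = numeric(0), se = numeric(0), stat = numeric(0),
                    p = numeric(0), test = character(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("kin_assoc", "data.frame")
  out
}

make_snp_tester <- function(ctx, null_fit, test) {
  y <- ctx$y
  X <- ctx$X
  n <- ctx$n

  if (test == "score2step") {
    # freeze Sigma at the null REML estimates
    S <- as.matrix(assemble_sigma(ctx, null_fit$params))
    R_full <- chol(S)
    function(dos, name) {
      ok <- !is.na(dos)
      n_used <- sum(ok)
      mf <- maf(dos)
      R <- if (all(ok)) R_full else chol(S[ok, ok, drop = FALSE])
      Xs <- forwardsolve(t(R), cbind(X[ok, , drop = FALSE], snp = dos[ok]))
      ys <- forwardsolve(t(R), y[ok])
      f <- stats::lm.fit(Xs, ys)
      cf <- f$coefficients
      XtX_inv <- chol2inv(chol(crossprod(Xs)))
      j <- ncol(Xs)
      beta <- unname(cf[j])
      se <- sqrt(XtX_inv[j, j])
      stat <- (beta / se)^2
      data.frame(snp = name, n_used = n_used, maf = mf, beta = beta, se = se,
                 stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
                 test = "score2step", stringsAsFactors = FALSE)
    }
  } else {
    null_m2ll_full <- null_fit$m2ll
    function(dos, name) {
      ok <- !is.na(dos)
      n_used <- sum(ok)
      mf <- maf(dos)
      d2 <- ctx$data
      d2$.snp <- dos
      d2 <- d2[ok, , drop = FALSE]
      spec_alt <- ctx$spec
      spec_alt$fixed <- c(spec_alt$fixed, ".snp")
      alt <- fit(spec_alt, d2, criterion = "ML",
                 optimizer_config = list(start = null_fit$params, n_starts = 2L,
                                         maxfun = 600L, rhoend = 1e-7),
                 quiet = TRUE)
      beta <- unname(alt$beta[".snp"])
      se <- sqrt(alt$vcov_beta[".snp", ".snp"])
      if (test == "wald") {
        stat <- (beta / se)^2
      } else {
        null_m2ll <- if (all(ok)) null_m2ll_full else {
          fit(ctx$spec, d2, criterion = "ML",
              optimizer_config = list(start = null_fit$params, n_starts = 2L,
                                      maxfun = 600L, rhoend = 1e-7),
              quiet = TRUE)$m2ll
        }
        stat <- max(0, null_m2ll - alt$m2ll)
      }
      data.frame(snp = name, n_used = n_used, maf = mf, beta = beta, se = se,
                 stat = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
                 test = test, stringsAsFactors = FALSE)
    }
  }
}

#' Add a Bonferroni genome-wide significance column
#'
#' @param assoc a `kin_assoc`.
#' @param alpha family-wise error rate.
#' @return the table with an added logical `significant_bonferroni` column.
#' @export
bonferroni_flag <- function(assoc, alpha = 0.05) {
  assoc$significant_bonferroni <- assoc$p < alpha / max(1L, nrow(assoc))
  assoc
}
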