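#' Read a relationship matrix from a text file
#'
#' Two formats are accepted: a square TSV whose first row and first column
#' carry the ids, and a sparse triplet TSV with header `id1  id2  value`
#' (unlisted cells are zero; either triangle suffices). Matrices with
#' asymmetry below 1e-8 are symmetrized; larger asymmetry is an error.
#'
#' @param path input path.
#' @return a [rel_matrix()].
#' @export
read_matrix <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (identical(tolower(header), c("id1", "id2", "value"))) {
    tr <- utils::read.table(path, header = TRUE, sep = "\t",
                            colClasses = c("character", "character", "numeric"))
    ids <- unique(c(tr$id1, tr$id2))
    M <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    M[cbind(tr$id1, tr$id2)] <- tr$value
    M[cbind(tr$id2, tr$id1)] <- tr$value
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                             check.names = FALSE)
    M <- as.matrix(tab)
    if (nrow(M) != ncol(M)) stopf("matrix in '%s' is not square", path)
    if (!identical(rownames(M), colnames(M))) {
      stopf("row and column ids differ in '%s'", path)
    }
  }
  asym <- max(abs(M - t(M)))
  if (asym > 1e-8) {
    stopf("matrix in '%s' is asymmetric (max |M - t(M)| = %.3g > 1e-8)", path, asym)
  }
  rel_matrix((M + t(M)) / 2)
}

#' Write a relationship matrix
#'
#' @param m a [rel_matrix()].
#' @param path output path.
#' @param format `"square"` (id-headed TSV) or `"triplet"` (`id1 id2
#'   value`, upper triangle of non-zero cells).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("square", "triplet")) {
  format <- match.arg(format)
  m <- as_rel_matrix(m)
  M <- as.matrix(m$values)
  if (format == "square") {
    df <- data.frame(id = m$ids, M, check.names = FALSE)
    colnames(df) <- c("id", m$ids)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    up <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
    df <- data.frame(id1 = m$ids[up[, 1]], id2 = m$ids[up[, 2]],
                     value = M[up])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write a phenotype-covariate table
#'
#' TSV with a header, one row per individual (or observation).
#'
#' @param path file path.
#' @return data frame.
#' @export
read_phenotype <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_phenotype
#' @param df data frame to write.
#' @export
write_phenotype <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a genotype dosage table
#'
#' TSV: first column `id`, remaining columns SNP dosages in [0, 2] with
#' `NA` for missing.
#'
#' @param path file path.
#' @return a [genotype_table()].
#' @export
read_genotypes <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                           check.names = FALSE)
  genotype_table(as.matrix(tab))
}

#' @rdname read_genotypes
#' @param g a [genotype_table()].
#' @export
write_genotypes <- function(g, path) {
  df <- data.frame(id = rownames(g), unclass(g), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an association table
#'
#' Stable column order: snp, n_used, maf, beta, se, stat, p, test.
#'
#' @param assoc a `kin_assoc` from [scan()].
#' @param path output path.
#' @export
write_assoc <- function(assoc, path) {
  utils::write.table(assoc[, c("snp", "n_used", "maf", "beta", "se",
                               "stat", "p", "test")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

SPEC_KEYS <- c("response", "fixed", "random", "residual", "constraints", "criterion")
RANDOM_KEYS <- c("grouping", "relmat", "within", "label")
RESIDUAL_KEYS <- c("type", "factor")
CONSTRAINT_KEYS <- c("fixes", "equalities")

#' Read a model specification from JSON
#'
#' Schema:
#' \preformatted{
#' {
#'   "response": "y",
#'   "fixed": ["age", "sex"],
#'   "random": [
#'     {"grouping": "id", "relmat": "kinship.tsv", "within": "intercept"},
#'     {"grouping": "id", "relmat": "kinship.tsv",
#'      "within": {"group_slopes": "sex"}, "label": "gxe"}
#'   ],
#'   "residual": {"type": "by_group", "factor": "sex"},
#'   "constraints": {"fixes": {"gxe.cor.female.male": 1},
#'                   "equalities": [["gxe.sd.female", "gxe.sd.male"]]},
#'   "criterion": "REML"
#' }
#' }
#' `"relmat": "identity"` (or omitting it) gives an unstructured term.
#' Relative relmat paths resolve against the spec file's directory.
#' Unknown keys are rejected, with the JSON path in the error.
#'
#' @param path path to the JSON file.
#' @return list with `spec` (a [model_spec()]) and `criterion`.
#' @export
read_spec <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  check_keys(doc, SPEC_KEYS, "/")
  if (is.null(doc$response)) stopf("spec /response is required")
  terms <- lapply(seq_along(doc$random %||% list()), function(i) {
    r <- doc$random[[i]]
    check_keys(r, RANDOM_KEYS, sprintf("/random/%d", i))
    relmat <- NULL
    if (!is.null(r$relmat) && !identical(r$relmat, "identity")) {
      rp <- r$relmat
      if (!file.exists(rp)) rp <- file.path(dirname(path), rp)
      relmat <- read_matrix(rp)
    }
    within <- r$within %||% "intercept"
    if (is.list(within)) {
      if (!identical(names(within), "group_slopes")) {
        stopf("spec /random/%d/within: expected \"intercept\" or {\"group_slopes\": <factor>}", i)
      }
      within <- group_slopes(within$group_slopes)
    }
    random_term(r$grouping, relmat = relmat, within = within,
                label = r$label %||% r$grouping)
  })
  res <- doc$residual %||% list(type = "homoscedastic")
  check_keys(res, RESIDUAL_KEYS, "/residual")
  cons <- doc$constraints %||% list()
  check_keys(cons, CONSTRAINT_KEYS, "/constraints")
  spec <- model_spec(
    response = doc$response,
    fixed = as.character(unlist(doc$fixed %||% list())),
    random = terms,
    residual = residual_spec(res$type %||% "homoscedastic", factor = res$factor),
    constraints = constraint_set(
      fixes = cons$fixes %||% list(),
      equalities = lapply(cons$equalities %||% list(), function(e) as.character(unlist(e)))
    )
  )
  criterion <- doc$criterion %||% "REML"
  if (!criterion %in% c("REML", "ML")) stopf("spec /criterion must be REML or ML")
  list(spec = spec, criterion = criterion)
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stopf("unknown key(s) at %s: %s (allowed: %s)", where,
          paste(extra, collapse = ", "), paste(allowed, collapse = ", "))
  }
}
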