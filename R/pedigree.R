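#' Pedigree objects
#'
#' A pedigree is a data frame with one row per individual and columns
#' `family_id`, `id`, `father_id`, `mother_id`, `sex` and `mz_group`.
#' Missing parents and missing `mz_group` are `NA`. `sex` is one of
#' `"male"`, `"female"`, `"unknown"`. Members of one `mz_group` are
#' monozygotic twins: they must share both parents and sex, and are treated
#' as genetically identical when the additive relationship matrix is built.
#'
#' @param df data frame with the columns above (`sex` may also be coded
#'   1/2/0 as in LINKAGE files).
#' @return a validated `kin_pedigree` data frame, row order preserved.
#' @export
pedigree <- function(df) {
  need <- c("family_id", "id", "father_id", "mother_id", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("pedigree is missing columns: %s", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!"mz_group" %in% names(df)) df$mz_group <- NA_character_
  for (col in c("family_id", "id", "father_id", "mother_id", "mz_group")) {
    df[[col]] <- trimws(as.character(df[[col]]))
    df[[col]][df[[col]] %in% c("", "0", "NA")] <- NA_character_
  }
  if (any(is.na(df$id))) stopf("pedigree has missing individual ids")
  sx <- as.character(df$sex)
  sx[sx %in% c("1", "m", "M")] <- "male"
  sx[sx %in% c("2", "f", "F")] <- "female"
  sx[sx %in% c("0", "NA", "", NA)] <- "unknown"
  bad <- setdiff(unique(sx), c("male", "female", "unknown"))
  if (length(bad)) stopf("unrecognized sex codes: %s", paste(bad, collapse = ", "))
  df$sex <- sx
  validate_pedigree(df)
  class(df) <- c("kin_pedigree", "data.frame")
  df
}

validate_pedigree <- function(df) {
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stopf("duplicated individual ids: %s", paste(unique(dup), collapse = ", "))
  for (pcol in c("father_id", "mother_id")) {
    p <- df[[pcol]]
    unknown <- setdiff(p[!is.na(p)], df$id)
    if (length(unknown)) {
      stopf("structural error: %s '%s' is not defined in the pedigree",
            sub("_id", "", pcol), unknown[[1]])
    }
  }
  ord <- pedigree_order(df)   # errors on cycles
  # MZ groups: same parents and same sex
  grp <- df$mz_group
  for (g in unique(grp[!is.na(grp)])) {
    rows <- df[which(grp == g), , drop = FALSE]
    if (nrow(rows) < 2) next
    same <- function(x) length(unique(ifelse(is.na(x), "<none>", x))) == 1L
    if (!same(rows$father_id) || !same(rows$mother_id)) {
      stopf("mz_group '%s': members do not share both parents", g)
    }
    if (!same(rows$sex)) stopf("mz_group '%s': members differ in sex", g)
  }
  invisible(ord)
}

# Topological order (parents before children). Errors with one explicit cycle.
pedigree_order <- function(df) {
  n <- nrow(df)
  idx <- stats::setNames(seq_len(n), df$id)
  fa <- ifelse(is.na(df$father_id), NA_integer_, idx[df$father_id])
  mo <- ifelse(is.na(df$mother_id), NA_integer_, idx[df$mother_id])
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    rem <- setdiff(seq_len(n), ord)
    cyc <- find_cycle(rem[[1]], fa, mo, df$id)
    stopf("structural error: pedigree contains a cycle: %s", paste(cyc, collapse = " -> "))
  }
  ord
}

find_cycle <- function(start, fa, mo, ids) {
  seen <- integer(0)
  v <- start
  repeat {
    if (v %in% seen) {
      path <- seen[which(seen == v)[1]:length(seen)]
      return(c(ids[path], ids[v]))
    }
    seen <- c(seen, v)
    nxt <- c(fa[v], mo[v])
    nxt <- nxt[!is.na(nxt)]
    # walk into an ancestor that is itself stuck in the cycle
    v <- if (length(nxt)) nxt[[1]] else return(ids[seen])
  }
}

#' Read a LINKAGE-style pedigree file
#'
#' Whitespace- or tab-delimited, one row per individual, columns
#' family, id, father, mother, sex (1=male, 2=female, 0=unknown).
#' `"0"` codes a missing parent. A 6th column (phenotype placeholder) is
#' ignored if present; an optional 7th column gives the monozygotic-twin
#' group (`0` = none).
#'
#' @param path path to the ped file.
#' @return a [pedigree()] object; row order preserved.
#' @export
read_pedigree <- function(path) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           comment.char = "#", blank.lines.skip = TRUE)
  if (ncol(raw) < 5) stopf("ped file '%s' has %d columns; at least 5 required", path, ncol(raw))
  df <- data.frame(
    family_id = raw[[1]], id = raw[[2]], father_id = raw[[3]],
    mother_id = raw[[4]], sex = raw[[5]],
    mz_group = if (ncol(raw) >= 7) raw[[7]] else NA_character_,
    stringsAsFactors = FALSE
  )
  # a child listing itself as a parent is a (self-)cycle
  self <- df$id == df$father_id | df$id == df$mother_id
  if (any(self, na.rm = TRUE)) {
    stopf("structural error: pedigree contains a cycle: %s -> %s",
          df$id[which(self)[1]], df$id[which(self)[1]])
  }
  pedigree(df)
}

#' Write a pedigree to a LINKAGE-style file
#'
#' @param ped a [pedigree()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path) {
  sexcode <- c(male = "1", female = "2", unknown = "0")
  out <- data.frame(
    ped$family_id, ped$id,
    ifelse(is.na(ped$father_id), "0", ped$father_id),
    ifelse(is.na(ped$mother_id), "0", ped$mother_id),
    sexcode[ped$sex], "0",
    ifelse(is.na(ped$mz_group), "0", ped$mz_group)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Relationship matrix objects
#'
#' An identifier-indexed symmetric positive semi-definite matrix, the
#' container for the additive genetic relationship matrix A (twice the
#' kinship matrix) and any user-supplied covariance between grouping levels.
#'
#' @param values square symmetric matrix (base or Matrix).
#' @param ids character ids, one per row/column; defaults to dimnames.
#' @return a `kin_relmat` object with elements `ids`, `values` (sparse
#'   symmetric `Matrix`), `storage` (`"sparse"` or `"dense"`) and `sparsity`
#'   (fraction of exactly-zero cells).
#' @export
rel_matrix <- function(values, ids = NULL) {
  if (is.null(ids)) ids <- rownames(values)
  if (is.null(ids)) stopf("rel_matrix needs ids (or row names on 'values')")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stopf("rel_matrix ids must be unique")
  values <- as(as(Matrix::Matrix(values), "generalMatrix"), "CsparseMatrix")
  if (nrow(values) != ncol(values) || nrow(values) != length(ids)) {
    stopf("rel_matrix: %d ids but a %d x %d matrix", length(ids), nrow(values), ncol(values))
  }
  asym <- max(abs(values - Matrix::t(values)))
  if (asym > 1e-12) stopf("rel_matrix: matrix is asymmetric (max |M - t(M)| = %.3g)", asym)
  values <- Matrix::forceSymmetric(values)
  dimnames(values) <- list(ids, ids)
  sp <- sparsity_fraction(values)
  structure(
    list(ids = ids, values = values,
         storage = if (sp >= 0.5) "sparse" else "dense", sparsity = sp),
    class = "kin_relmat"
  )
}

sparsity_fraction <- function(m) {
  m <- as(as(m, "generalMatrix"), "CsparseMatrix")
  nz <- sum(m@x != 0)
  1 - nz / (nrow(m) * ncol(m))
}

#' @exportS3Method base::print
print.kin_relmat <- function(x, ...) {
  cat(sprintf("<kin_relmat> %d ids, %s storage, sparsity %.3f\n",
              length(x$ids), x$storage, x$sparsity))
  invisible(x)
}

#' @export
dim.kin_relmat <- function(x) dim(x$values)

as_rel_matrix <- function(x) {
  if (inherits(x, "kin_relmat")) x else rel_matrix(x)
}

#' Additive genetic relationship matrix from a pedigree
#'
#' Builds A by the tabular recursion: founders have `A_ii = 1`;
#' `A_ii = 1 + A_fm / 2` for an individual with parents f and m;
#' `A_ij = (A_jf + A_jm) / 2` for previously processed j (terms with a
#' missing parent drop out). Monozygotic twins are genetically identical:
#' later members of an `mz_group` receive copies of the first member's rows
#' and columns, so A can be rank-deficient (positive semi-definite).
#' Inbreeding is handled implicitly by the recursion.
#'
#' @param ped a [pedigree()] object.
#' @return a [rel_matrix()] over all pedigree ids, in pedigree id order.
#' @export
additive_relationship <- function(ped) {
  ped <- if (inherits(ped, "kin_pedigree")) ped else pedigree(ped)
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  fa <- ifelse(is.na(ped$father_id), NA_integer_, idx[ped$father_id])
  mo <- ifelse(is.na(ped$mother_id), NA_integer_, idx[ped$mother_id])
  ord <- pedigree_order(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  mz_first <- list()  # mz_group -> index of first processed member
  done <- integer(0)
  for (i in ord) {
    g <- ped$mz_group[i]
    if (!is.na(g) && !is.null(mz_first[[g]])) {
      r <- mz_first[[g]]
      A[i, done] <- A[r, done]
      A[done, i] <- A[done, r]
      A[i, i] <- A[r, r]
      A[i, r] <- A[r, i] <- A[r, r]
      done <- c(done, i)
      next
    }
    f <- fa[i]; m <- mo[i]
    if (length(done)) {
      row <- numeric(length(done))
      if (!is.na(f)) row <- row + A[f, done] / 2
      if (!is.na(m)) row <- row + A[m, done] / 2
      A[i, done] <- row
      A[done, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(f) && !is.na(m)) A[f, m] / 2 else 0
    if (!is.na(g)) mz_first[[g]] <- i
    done <- c(done, i)
  }
  rel_matrix(A, ped$id)
}

#' Incidence matrix of a grouping factor
#'
#' @param values character vector of per-row group memberships.
#' @param levels ordered character vector of group levels (matrix columns).
#' @return 0/1 matrix with one 1 per row.
#' @export
incidence_from_factor <- function(values, levels) {
  values <- as.character(values)
  levels <- as.character(levels)
  unknown <- setdiff(values, levels)
  if (length(unknown)) {
    stopf("unknown grouping level(s): %s", paste(unique(unknown), collapse = ", "))
  }
  Z <- matrix(0, length(values), length(levels), dimnames = list(NULL, levels))
  Z[cbind(seq_along(values), match(values, levels))] <- 1
  Z
}

sparse_incidence <- function(values, levels) {
  Matrix::sparseMatrix(
    i = seq_along(values), j = match(as.character(values), levels), x = 1,
    dims = c(length(values), length(levels)), dimnames = list(NULL, levels)
  )
}

#' Fraction of exactly-zero cells of a relationship matrix
#'
#' @param m a [rel_matrix()] or plain matrix.
#' @return fraction of cells (diagonal included) that are exactly zero.
#' @export
matrix_sparsity <- function(m) {
  if (inherits(m, "kin_relmat")) m$sparsity else sparsity_fraction(Matrix::Matrix(m))
}

#' Fill zero cells of a relationship matrix to reach a target sparsity
#'
#' Randomly selected zero cells (symmetric pairs off the diagonal) are set
#' to `fill_value`, reducing the proportion of exact zeros to
#' `target_sparsity`; `fill_value * I` is then added to the diagonal so the
#' perturbed matrix stays positive semi-definite for small fills. Used to
#' study how fitting cost grows as a sparse kinship matrix densifies.
#'
#' @param m a [rel_matrix()].
#' @param target_sparsity requested fraction of zero cells, at most the
#'   current sparsity.
#' @param fill_value small positive value written into filled cells.
#' @param seed integer seed controlling which cells are filled.
#' @return a [rel_matrix()] with sparsity within 0.01 of the target.
#' @export
densify <- function(m, target_sparsity, fill_value = 0.01, seed = 1L) {
  m <- as_rel_matrix(m)
  cur <- m$sparsity
  if (target_sparsity > cur + 1e-12) {
    stopf("target sparsity %.3f exceeds current sparsity %.3f", target_sparsity, cur)
  }
  n <- length(m$ids)
  dense <- as.matrix(m$values)
  if (abs(target_sparsity - cur) <= 1e-12) return(m)
  n_fill_cells <- round((cur - target_sparsity) * n * n)
  zero_off <- which(dense == 0 & upper.tri(dense), arr.ind = TRUE)
  zero_diag <- which(diag(dense) == 0)
  with_seed(seed, {
    # fill symmetric off-diagonal pairs first (2 cells each), then diagonal
    n_pairs <- min(nrow(zero_off), floor(n_fill_cells / 2))
    if (n_pairs > 0) {
      pick <- zero_off[sample.int(nrow(zero_off), n_pairs), , drop = FALSE]
      dense[pick] <- fill_value
      dense[pick[, c(2, 1), drop = FALSE]] <- fill_value
    }
    left <- n_fill_cells - 2 * n_pairs
    if (left > 0 && length(zero_diag)) {
      d <- zero_diag[sample.int(length(zero_diag), min(left, length(zero_diag)))]
      dense[cbind(d, d)] <- fill_value
    }
  })
  diag(dense) <- diag(dense) + fill_value
  out <- rel_matrix(dense, m$ids)
  if (abs(out$sparsity - target_sparsity) > 0.01) {
    stopf("densify could not reach target sparsity %.3f (achieved %.3f)",
          target_sparsity, out$sparsity)
  }
  out
}
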