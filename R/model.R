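#' Constraints on variance-component parameters
#'
#' Restrictions used by advanced variance-component models: `fixes` pins a
#' parameter at a value (e.g. the cross-sex genetic correlation at 1) and
#' `equalities` forces parameters to share one value (e.g. equal male and
#' female genetic standard deviations). Parameters are addressed by path,
#' e.g. `"id.sd"`, `"id.sd.male"`, `"id.cor.female.male"`, `"residual.sd"`,
#' `"residual.sd.female"` (see [spec_params()]).
#'
#' @param fixes named numeric vector or list: parameter path -> fixed value.
#' @param equalities list of character vectors; the parameters in each
#'   vector are constrained equal (one free value per group).
#' @return a `kin_constraints` object.
#' @export
constraint_set <- function(fixes = list(), equalities = list()) {
  fixes <- unlist(fixes)
  if (length(fixes) && is.null(names(fixes))) stopf("fixes must be named by parameter path")
  structure(list(fixes = fixes, equalities = equalities), class = "kin_constraints")
}

#' Mixed-model specification
#'
#' Declarative analogue of a mixed-model formula: a response, fixed-effect
#' covariates (intercept implicit), structured random terms, a residual
#' structure and a constraint set.
#'
#' @param response name of the response column.
#' @param fixed character vector of covariate columns (may be empty).
#' @param random list of [random_term()]s (may be empty).
#' @param residual a [residual_spec()].
#' @param constraints a [constraint_set()].
#' @return a `kin_model_spec`.
#' @export
model_spec <- function(response, fixed = character(0), random = list(),
                       residual = residual_spec("homoscedastic"),
                       constraints = constraint_set()) {
  if (inherits(random, "kin_random_term")) random <- list(random)
  stopifnot(all(vapply(random, inherits, TRUE, "kin_random_term")))
  labels <- vapply(random, function(t) t$label, "")
  if (anyDuplicated(labels)) {
    labels <- make.unique(labels, sep = ".")
    for (i in seq_along(random)) random[[i]]$label <- labels[i]
  }
  structure(
    list(response = response, fixed = fixed, random = random,
         residual = residual, constraints = constraints),
    class = "kin_model_spec"
  )
}

#' Convenience constructor: polygenic model
#'
#' The classical family-study model: a genetic random effect with covariance
#' `sigma_g^2 A` over individuals, an optional shared-household effect, and
#' i.i.d. residuals.
#'
#' @param response,fixed as in [model_spec()].
#' @param kinship a [rel_matrix()] (the additive relationship matrix A).
#' @param id name of the individual-id column.
#' @param household optional name of the household column.
#' @return a `kin_model_spec`.
#' @export
polygenic_spec <- function(response, fixed = character(0), kinship, id = "id",
                           household = NULL) {
  terms <- list(random_term(id, relmat = kinship))
  if (!is.null(household)) terms <- c(terms, list(random_term(household)))
  model_spec(response, fixed, terms)
}

#' Convenience constructor: sex-specific (gene-environment) model
#'
#' Genetic variance split by a two-level environment factor (typically sex):
#' parameters sg1, sg2 and rho_g for the genetic block, plus group-specific
#' residual variances.
#'
#' @param response,fixed as in [model_spec()].
#' @param kinship the additive relationship [rel_matrix()].
#' @param id individual-id column.
#' @param environment name of the grouping factor (e.g. `"sex"`).
#' @return a `kin_model_spec`.
#' @export
gxe_spec <- function(response, fixed = character(0), kinship, id = "id",
                     environment = "sex") {
  model_spec(
    response, fixed,
    list(random_term(id, relmat = kinship, within = group_slopes(environment))),
    residual = residual_spec("by_group", factor = environment)
  )
}

#' @exportS3Method base::print
print.kin_model_spec <- function(x, ...) {
  rt <- vapply(x$random, function(t) {
    w <- if (t$within$type == "intercept") "1" else paste0("0+", t$within$factor)
    sprintf("(%s | %s%s)", w, t$grouping, if (is.null(t$relmat)) "" else ", relmat")
  }, "")
  cat(sprintf("<kin_model_spec> %s ~ %s%s; residual: %s\n",
              x$response,
              paste(c("1", x$fixed), collapse = " + "),
              if (length(rt)) paste0(" + ", paste(rt, collapse = " + ")) else "",
              x$residual$type))
  invisible(x)
}

#' Parameter paths of a model specification
#'
#' Lists the variance-parameter names in the order used by [neg2_loglik()]
#' and reported by [fit()]: for each random term its sd(s) then its
#' correlation(s), then the residual sd(s).
#'
#' @param spec a [kin_model_spec].
#' @param data the data frame the model will be fitted to (supplies factor
#'   levels for group-specific terms).
#' @return data frame with columns `name` and `kind` (`"sd"` or `"cor"`).
#' @export
spec_params <- function(spec, data) {
  ctx <- build_context(spec, data, quiet = TRUE)
  ctx$par_table[, c("name", "kind")]
}
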