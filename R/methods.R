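#' Normalized expression matrix
#'
#' @param object a [ZIExpDataSet-class].
#' @return genes x samples numeric matrix (the `"normcounts"` assay).
#' @rdname normCounts
#' @export
setMethod("normCounts", "ZIExpDataSet", function(object) {
  assay(object, "normcounts")
})

#' Group factor of a dataset
#'
#' @param object a [ZIExpDataSet-class].
#' @return the per-sample group factor.
#' @rdname groupFactor
#' @export
setMethod("groupFactor", "ZIExpDataSet", function(object) {
  droplevels(colData(object)[[object@groupVar]])
})

#' Covariate matrix of a dataset
#'
#' @param object a [ZIExpDataSet-class].
#' @return samples x M numeric matrix (0 columns when no covariates).
#' @rdname covariateMatrix
#' @export
setMethod("covariateMatrix", "ZIExpDataSet", function(object) {
  vars <- object@covariateVars
  m <- matrix(numeric(0), ncol(object), 0L,
              dimnames = list(colnames(object), NULL))
  if (length(vars)) {
    m <- do.call(cbind, lapply(vars, function(v) colData(object)[[v]]))
    dimnames(m) <- list(colnames(object), vars)
  }
  m
})

setMethod("show", "ZIExpDataSet", function(object) {
  callNextMethod()
  g <- groupFactor(object)
  cat(sprintf("group '%s': %s\n", object@groupVar,
              paste(sprintf("%s(%d)", levels(g), table(g)), collapse = " ")))
  if (length(object@covariateVars))
    cat("covariates:", paste(object@covariateVars, collapse = ", "), "\n")
})

#' Accessors for ZIExpFit objects
#'
#' `piEstimates()` returns the per-gene nonzero-probability estimates
#' (`n+/N`); `groupMeans()` the natural-scale group mean estimates (genes x
#' groups; for covariate models, the group means at covariate value zero);
#' `isConverged()` the per-gene optimizer status; `logLiks()` the per-gene
#' maximized zero-inflated log-likelihoods.
#'
#' @param object a [ZIExpFit-class].
#' @return numeric vector / matrix / logical vector, one entry per gene.
#' @name ZIExpFit-accessors
NULL

#' @rdname ZIExpFit-accessors
#' @export
setMethod("piEstimates", "ZIExpFit", function(object) {
  stats::setNames(object@pi, object@geneIds)
})

#' @rdname ZIExpFit-accessors
#' @export
setMethod("groupMeans", "ZIExpFit", function(object) {
  if (object@link == "log") exp(object@coef) else object@coef
})

#' @rdname ZIExpFit-accessors
#' @export
setMethod("isConverged", "ZIExpFit", function(object) {
  stats::setNames(object@converged, object@geneIds)
})

#' @rdname ZIExpFit-accessors
#' @export
setMethod("logLiks", "ZIExpFit", function(object) {
  stats::setNames(object@logLik, object@geneIds)
})

setMethod("show", "ZIExpFit", function(object) {
  cat(sprintf(
    "ZIExpFit: %d genes, %d samples, %d group(s), %d covariate(s), %s link\n",
    length(object@geneIds), length(object@design$group),
    length(object@groupLabels), ncol(object@covCoef), object@link))
  conv <- object@converged
  cat(sprintf("converged: %d; failed: %d; unfittable (all-zero): %d\n",
              sum(conv, na.rm = TRUE), sum(!conv, na.rm = TRUE),
              sum(is.na(conv))))
})

setMethod("show", "ZIExpResults", function(object) {
  md <- metadata(object)
  cat(sprintf("ZIExpResults: %d genes (%s link, df = %s)\n",
              nrow(object), md$link %||% "?", md$df %||% "?"))
  if (!is.null(md$alpha)) {
    n_sig <- sum(object$padj < md$alpha, na.rm = TRUE)
    cat(sprintf("padj < %g: %d genes\n", md$alpha, n_sig))
  }
  callNextMethod()
})

setMethod("show", "ZIExpScenario", function(object) {
  disp <- switch(object@family,
    exponential = "",
    nb = sprintf(", phi = %g", object@disp),
    lognormal = sprintf(", sigma2 = %g", object@disp))
  cat(sprintf(
    "ZIExpScenario: %d genes (%d DE), %s family%s, pi = %g, N = %d/group\n",
    length(object@baselines), sum(object@truth), object@family, disp,
    object@pi, object@nPerGroup))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
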