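#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames colData rowData colData<- rowData<-
#' @importFrom stats setNames quantile sd median rexp rbinom rpois rnbinom
#'   rlnorm rnorm pchisq
NULL

#' ZIExpDataSet: container for normalized expression and sample design
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a single assay
#' `"normcounts"` holding a genes x samples matrix of non-negative,
#' library-size normalized expression values (RPKM/FPKM/TMM/UQ or any
#' continuous or integer normalized counts), plus the names of the grouping
#' factor and optional numeric covariates in `colData`.
#'
#' @slot groupVar name of the `colData` column holding the group factor.
#' @slot covariateVars names of numeric `colData` columns used as covariates
#'   (possibly none).
#'
#' @seealso [ZIExpDataSet()] the constructor, [ziExpFit()], [ziExpLRT()]
#' @export
setClass("ZIExpDataSet",
  contains = "SummarizedExperiment",
  slots = c(groupVar = "character", covariateVars = "character")
)

.validZIExpDataSet <- function(object) {
  msg <- NULL
  if (!("normcounts" %in% SummarizedExperiment::assayNames(object)))
    msg <- c(msg, "assay 'normcounts' is required")
  else {
    m <- assay(object, "normcounts")
    if (!is.numeric(m))
      msg <- c(msg, "assay 'normcounts' must be numeric")
    else if (any(!is.finite(m)))
      msg <- c(msg, "assay 'normcounts' contains non-finite values")
    else if (any(m < 0))
      msg <- c(msg, "assay 'normcounts' contains negative values")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
      msg <- c(msg, "gene identifiers (rownames) must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
      msg <- c(msg, "sample identifiers (colnames) must be present and unique")
  }
  if (length(object@groupVar) != 1L)
    msg <- c(msg, "'groupVar' must name exactly one colData column")
  else if (!(object@groupVar %in% colnames(colData(object))))
    msg <- c(msg, sprintf("colData lacks group column '%s'", object@groupVar))
  else {
    g <- colData(object)[[object@groupVar]]
    if (!is.factor(g))
      msg <- c(msg, "group column must be a factor")
    else if (nlevels(droplevels(g)) < 1L || any(table(g)[levels(g)] == 0L))
      msg <- c(msg, "every group level must contain at least one sample")
  }
  for (v in object@covariateVars) {
    if (!(v %in% colnames(colData(object))))
      msg <- c(msg, sprintf("colData lacks covariate column '%s'", v))
    else if (!is.numeric(colData(object)[[v]]))
      msg <- c(msg, sprintf("covariate column '%s' must be numeric", v))
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("ZIExpDataSet", .validZIExpDataSet)

#' Construct a ZIExpDataSet
#'
#' @param counts genes x samples matrix of non-negative normalized expression
#'   values. Rownames are gene identifiers, colnames sample identifiers;
#'   defaults are generated when missing.
#' @param colData `data.frame` (or DataFrame) of per-sample annotation, one
#'   row per column of `counts`. Alternatively pass `group` directly as a
#'   vector and omit `colData`.
#' @param group either the name of a `colData` column holding the group
#'   factor, or (when `colData` is missing) a vector of group labels, one per
#'   sample. Coerced to a factor with levels in order of first appearance.
#' @param covariates character vector naming numeric `colData` columns to be
#'   used as model covariates. Default none.
#'
#' @return A [ZIExpDataSet-class] object.
#'
#' @examples
#' m <- matrix(rexp(40, 1 / 2), nrow = 4,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' zds <- ZIExpDataSet(m, group = rep(c("A", "B"), each = 5))
#' zds
#' @export
ZIExpDataSet <- function(counts, colData = NULL, group = "group",
                         covariates = character(0)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(rownames(counts)))
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  if (is.null(colData)) {
    if (length(group) != ncol(counts))
      stop("when 'colData' is missing, 'group' must give one label per sample")
    colData <- S4Vectors::DataFrame(
      group = factor(group, levels = unique(as.character(group))),
      row.names = colnames(counts)
    )
    group <- "group"
  } else {
    colData <- as(colData, "DataFrame")
    if (nrow(colData) != ncol(counts))
      stop("'colData' must have one row per sample")
    if (!(is.character(group) && length(group) == 1L))
      stop("with 'colData' supplied, 'group' must name a colData column")
    if (!(group %in% colnames(colData)))
      stop(sprintf("colData lacks group column '%s'", group))
    g <- colData[[group]]
    if (!is.factor(g))
      colData[[group]] <- factor(g, levels = unique(as.character(g)))
    else
      colData[[group]] <- droplevels(g)
  }
  se <- SummarizedExperiment(assays = SimpleList(normcounts = counts),
                             colData = colData)
  new("ZIExpDataSet", se, groupVar = group,
      covariateVars = as.character(covariates))
}

#' Per-gene zero-inflated Exponential GLM fits
#'
#' One fit per gene of the zero-inflated Exponential quasi-likelihood GLM.
#' Coefficients are stored on the link scale of `link`; `groupMeans()`
#' returns natural-scale group means regardless of link.
#'
#' @slot pi per-gene nonzero-probability estimates (pi-hat = n+/N).
#' @slot coef genes x K group coefficient matrix on the link scale.
#' @slot covCoef genes x M covariate coefficient matrix (0 columns if none).
#' @slot logLik per-gene maximized zero-inflated log-likelihood.
#' @slot converged per-gene optimizer status (`NA` for unfittable genes).
#' @slot link `"log"` or `"identity"`.
#' @slot groupLabels the K group labels, in design-column order.
#' @slot design list with elements `group` (factor) and `covariates`
#'   (samples x M numeric matrix) used for the fit.
#' @slot nZero,nNonzero per-gene zero / nonzero sample counts.
#' @slot geneIds gene identifiers, in input order.
#' @export
setClass("ZIExpFit",
  slots = c(
    pi = "numeric", coef = "matrix", covCoef = "matrix",
    logLik = "numeric", converged = "logical", link = "character",
    groupLabels = "character", design = "list",
    nZero = "integer", nNonzero = "integer", geneIds = "character"
  )
)

setValidity("ZIExpFit", function(object) {
  n <- length(object@geneIds)
  msg <- NULL
  if (length(object@pi) != n || nrow(object@coef) != n ||
      length(object@logLik) != n || length(object@converged) != n)
    msg <- c(msg, "per-gene slots must all have one entry per gene")
  if (!(object@link %in% c("log", "identity")))
    msg <- c(msg, "link must be 'log' or 'identity'")
  if (any(object@pi < 0 | object@pi > 1, na.rm = TRUE))
    msg <- c(msg, "pi estimates must lie in [0, 1]")
  if (any(object@nZero + object@nNonzero !=
          length(object@design$group), na.rm = TRUE))
    msg <- c(msg, "nZero + nNonzero must equal the sample count")
  if (is.null(msg)) TRUE else msg
})

#' Differential expression results
#'
#' A [S4Vectors::DataFrame] subclass with one row per gene: natural-scale
#' group means, `log2FoldChange` (two-group designs), the LRT statistic
#' `stat`, `df`, `pvalue`, BH-adjusted `padj`, optional `empiricalP` /
#' `empiricalPadj`, and a `status` column (`"ok"`, `"not_converged"`,
#' `"filtered"`). Test metadata (link, alpha, permutations, seed) is kept in
#' `metadata()`.
#' @export
setClass("ZIExpResults", contains = "DFrame")

#' Simulation scenario for the zero-inflated expression generator
#'
#' A fixed two-group simulation configuration: per-gene baseline means for
#' group 1, multiplicative group-2 shifts (null genes forced to shift 1),
#' truth labels, the sampling family and its nuisance parameters. Replicate
#' matrices are drawn from a scenario with [simulateCounts()].
#'
#' @slot family `"exponential"`, `"nb"` or `"lognormal"`.
#' @slot pi nonzero proportion of the Bernoulli mask, in (0, 1].
#' @slot disp NB dispersion phi or LN log-variance sigma^2 (ignored for
#'   `"exponential"`).
#' @slot nPerGroup samples per group.
#' @slot baselines per-gene group-1 mean expression (positive).
#' @slot shifts per-gene multiplicative group-2 fold change (1 for nulls).
#' @slot truth per-gene DE indicator, `shifts != 1`.
#' @slot geneIds gene identifiers.
#' @slot seed integer seed the scenario was built from.
#' @export
setClass("ZIExpScenario",
  slots = c(
    family = "character", pi = "numeric", disp = "numeric",
    nPerGroup = "integer", baselines = "numeric", shifts = "numeric",
    truth = "logical", geneIds = "character", seed = "integer"
  )
)

setValidity("ZIExpScenario", function(object) {
  msg <- NULL
  if (!(object@family %in% c("exponential", "nb", "lognormal")))
    msg <- c(msg, "family must be exponential, nb or lognormal")
  if (object@pi <= 0 || object@pi > 1)
    msg <- c(msg, "pi must lie in (0, 1]")
  if (any(object@baselines <= 0))
    msg <- c(msg, "baselines must be positive")
  if (any(object@shifts != 1 & abs(log2(object@shifts)) < 0.5))
    msg <- c(msg, "shifts with |log2| < 0.5 must have been forced to 1")
  if (!identical(object@truth, object@shifts != 1))
    msg <- c(msg, "truth labels must equal (shift != 1)")
  if (length(object@shifts) != length(object@baselines) ||
      length(object@truth) != length(object@baselines))
    msg <- c(msg, "baselines, shifts and truth must be aligned")
  if (is.null(msg)) TRUE else msg
})
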