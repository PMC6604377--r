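## Likelihood ratio testing between nested zero-inflated Exponential GLMs.
## D = 2 (L*_full - L*_null) ~ chi^2 with df = (distinct full coefficients)
## - (distinct null coefficients); for the default test of any group effect,
## df = K - 1. Because pi-hat = n+/N under both the full and the null mean
## structure, the nuisance pi cancels from D exactly.

## run an expression under a temporary RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## LRT statistic for one gene; closed form for groups-only designs. The
## zero-inflation nuisance is saturated in the FULL groups for both models,
## so it cancels from the difference.
.lrtStatOne <- function(y, group, covariates = NULL, link = "log",
                        reduced = NULL) {
  group <- droplevels(as.factor(group))
  if (is.null(reduced))
    reduced <- factor(rep("all", length(y)))
  if (is.null(covariates)) {
    Y <- rbind(y)
    nzmat <- Y > 0
    if (!any(nzmat)) return(NA_real_)
    llf <- .fitGroupsOnly(Y, nzmat, group, group)$logLik
    lln <- .fitGroupsOnly(Y, nzmat, reduced, group)$logLik
    max(0, 2 * (llf - lln))
  } else {
    f1 <- .fitCovariates(y, group, covariates, link, piGroup = group)
    f0 <- .fitCovariates(y, reduced, covariates, link, piGroup = group)
    if (!f1$converged || !f0$converged) return(NA_real_)
    max(0, 2 * (f1$logLik - f0$logLik))
  }
}

#' Likelihood ratio test between two nested fits
#'
#' Compares a full [ZIExpFit-class] with a fit under a null design whose
#' groups are a coarsening of the full groups (some group contrasts
#' constrained to zero). The statistic is `D = 2 (L*_full - L*_null)`,
#' clipped at zero, with an asymptotic upper-tail chi-square p-value on
#' `df = K_full - K_null` degrees of freedom.
#'
#' @param full,null [ZIExpFit-class] objects fitted to the same genes and
#'   covariates; `null`'s groups must be a merging of `full`'s groups, and
#'   both fits must share the same zero-inflation grouping (fit the null
#'   with `piGroup` set to the full design's groups, as [ziExpLRT()] does).
#' @return A `data.frame` with columns `gene_id`, `stat`, `df`, `pvalue`.
#'   Genes where either fit failed get `NA` statistics.
#'
#' @examples
#' m <- matrix(rexp(60, 1 / 2), nrow = 6)
#' g <- rep(c("A", "B"), each = 5)
#' full <- ziExpFit(m, group = g)
#' null <- ziExpFit(m, group = rep("all", 10), piGroup = g)
#' lrtStatistics(full, null)
#' @export
lrtStatistics <- function(full, null) {
  stopifnot(is(full, "ZIExpFit"), is(null, "ZIExpFit"))
  if (!identical(full@geneIds, null@geneIds))
    stop("'full' and 'null' must be fitted to the same genes")
  gf <- full@design$group
  gn <- null@design$group
  if (length(gf) != length(gn))
    stop("'full' and 'null' must be fitted to the same samples")
  merged <- tapply(as.integer(gn), gf, function(x) length(unique(x)))
  if (any(merged != 1L))
    stop("null design is not nested in the full design")
  if (ncol(full@covCoef) != ncol(null@covCoef))
    stop("'full' and 'null' must share the same covariates")
  if (!identical(as.integer(full@design$piGroup),
                 as.integer(null@design$piGroup)))
    stop("'full' and 'null' must share the same zero-inflation grouping ",
         "(fit the null with piGroup = the full design's groups)")
  df <- nlevels(gf) - nlevels(gn)
  if (df < 1L) stop("null design must constrain at least one coefficient")
  D <- 2 * (full@logLik - null@logLik)
  bad <- is.na(D) | !full@converged | !null@converged
  bad[is.na(bad)] <- TRUE
  # a materially negative D means the optimizer failed on one side
  bad <- bad | (D < -1e-8)
  D <- pmax(0, D)
  D[bad] <- NA_real_
  data.frame(
    gene_id = full@geneIds,
    stat = D,
    df = df,
    pvalue = stats::pchisq(D, df = df, lower.tail = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up false discovery rate adjustment: for order statistics
#' `p_(1) <= ... <= p_(m)`, the adjusted value of `p_(i)` is
#' `min_{j >= i} min(1, m * p_(j) / j)`. `NA` entries are propagated and
#' excluded from `m`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return vector of adjusted values, same length and order as `p`.
#'
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  idx <- which(!is.na(p))
  m <- length(idx)
  if (m == 0L) return(out)
  pp <- p[idx]
  o <- order(pp, decreasing = TRUE)
  adj <- pmin(1, cummin(pp[o] * m / seq(m, 1)))
  out[idx[o]] <- adj
  out
}

#' Permutation-based empirical p-value for the group-effect LRT
#'
#' Shuffles the per-sample group labels (covariate rows stay attached to
#' their samples), recomputes the LRT statistic `D_p` for each permutation,
#' and returns the fraction of permutation statistics strictly exceeding the
#' observed `D_0`: `sum I(D_p > D_0) / P`. With `smoothed = TRUE` the
#' estimator `(1 + sum I) / (1 + P)`, which cannot return exactly zero, is
#' used instead. With `exhaustive = TRUE` (two-group designs) every distinct
#' relabeling with the observed group sizes is enumerated instead of
#' sampling.
#'
#' @param y non-negative expression values for one gene.
#' @param group per-sample group factor (K groups).
#' @param covariates optional samples x M numeric matrix.
#' @param link `"log"` or `"identity"`.
#' @param permutations number of random permutations P (default 100).
#' @param seed integer seed for reproducible shuffling.
#' @param exhaustive enumerate all relabelings (two groups only).
#' @param smoothed use the `(1 + sum)/(1 + P)` estimator.
#'
#' @return empirical p-value in `[0, 1]` (`NA` if the gene is all-zero).
#'
#' @examples
#' y <- c(0, 1, 2, 0.5, 4, 6, 5, 8)
#' g <- rep(c("A", "B"), each = 4)
#' empiricalPValue(y, g, exhaustive = TRUE)
#' empiricalPValue(y, g, permutations = 200, seed = 7)
#' @export
empiricalPValue <- function(y, group, covariates = NULL,
                            link = c("log", "identity"),
                            permutations = 100, seed = NULL,
                            exhaustive = FALSE, smoothed = FALSE) {
  link <- match.arg(link)
  group <- droplevels(as.factor(group))
  if (!exhaustive && permutations < 1)
    stop("'permutations' must be at least 1")
  D0 <- .lrtStatOne(y, group, covariates, link)
  if (is.na(D0)) return(NA_real_)
  if (exhaustive) {
    if (nlevels(group) != 2L)
      stop("exhaustive enumeration is implemented for two groups only")
    n <- length(y)
    n1 <- sum(group == levels(group)[1L])
    sets <- utils::combn(n, n1)
    Dp <- apply(sets, 2L, function(ix) {
      gp <- factor(ifelse(seq_len(n) %in% ix, levels(group)[1L],
                          levels(group)[2L]), levels = levels(group))
      .lrtStatOne(y, gp, covariates, link)
    })
    return(mean(Dp > D0))
  }
  Dp <- .withSeed(seed, {
    vapply(seq_len(permutations), function(p) {
      .lrtStatOne(y, sample(group), covariates, link)
    }, numeric(1))
  })
  if (smoothed) (1 + sum(Dp > D0, na.rm = TRUE)) / (1 + permutations)
  else mean(Dp > D0, na.rm = TRUE)
}

.runLRT <- function(Y, group, covariates, link, reduced, empirical,
                    permutations, seed, alpha, smoothed = FALSE) {
  group <- droplevels(as.factor(group))
  K <- nlevels(group)
  if (K < 2L && is.null(reduced))
    stop("testing a group effect needs at least two groups (df would be 0)")
  if (is.null(reduced)) reduced <- factor(rep("all", ncol(Y)))
  reduced <- droplevels(as.factor(reduced))
  full <- .fitMatrix(Y, group, covariates, link)
  null <- .fitMatrix(Y, reduced, covariates, link, piGroup = group)
  lrt <- lrtStatistics(full, null)

  status <- rep("ok", nrow(Y))
  status[is.na(full@converged)] <- "filtered"       # all-zero genes
  status[!is.na(full@converged) & is.na(lrt$stat)] <- "not_converged"
  pvalue <- lrt$pvalue
  pvalue[status != "ok"] <- NA_real_
  padj <- bhAdjust(pvalue)

  gm <- groupMeans(full)
  res <- DataFrame(row.names = full@geneIds)
  for (k in seq_len(K))
    res[[paste0("groupMean.", full@groupLabels[k])]] <- gm[, k]
  res$log2FoldChange <- if (K == 2L) log2(gm[, 2L] / gm[, 1L]) else NA_real_
  res$pi <- full@pi
  res$stat <- lrt$stat
  res$df <- lrt$df
  res$pvalue <- pvalue
  res$padj <- padj

  if (empirical) {
    set.seed(seed %||% 1L)
    geneSeeds <- sample.int(.Machine$integer.max - 1L, nrow(Y))
    emp <- rep(NA_real_, nrow(Y))
    for (i in which(status == "ok")) {
      emp[i] <- empiricalPValue(Y[i, ], group, covariates, link,
                                permutations = permutations,
                                seed = geneSeeds[i], smoothed = smoothed)
    }
    res$empiricalP <- emp
    res$empiricalPadj <- bhAdjust(emp)
  }
  res$status <- status

  out <- new("ZIExpResults", res)
  metadata(out) <- list(link = link, alpha = alpha, df = unique(lrt$df),
                        empirical = empirical,
                        permutations = if (empirical) permutations else NULL,
                        seed = seed)
  out
}

#' Differential expression by zero-inflated Exponential LRT
#'
#' Fits the zero-inflated Exponential quasi-likelihood GLM per gene under the
#' full design (group + covariates) and the null design (groups merged,
#' covariates kept), computes the likelihood ratio statistic with its
#' asymptotic chi-square p-value (`df = K - 1` for the default null),
#' adjusts for multiple testing by Benjamini-Hochberg, and optionally adds
#' permutation-based empirical p-values. Genes that cannot be fitted
#' (all-zero) are flagged `"filtered"` and excluded from the BH family.
#'
#' @param object a [ZIExpDataSet-class] or a genes x samples matrix.
#' @param link `"log"` (default) or `"identity"`.
#' @param reduced optional factor giving the null-model group membership
#'   (a coarsening of the groups); default: all groups merged.
#' @param empirical also compute permutation empirical p-values.
#' @param permutations number of permutations P when `empirical` (default
#'   100).
#' @param seed integer seed controlling the permutations.
#' @param alpha significance threshold recorded in the result metadata
#'   (default 0.05).
#' @param group,covariates for the matrix method: per-sample group labels
#'   and optional covariate matrix.
#' @param ... unused.
#'
#' @return A [ZIExpResults-class] with one row per input gene, in input
#'   order.
#'
#' @examples
#' set.seed(1)
#' m <- rbind(matrix(rexp(200, 1 / 2), 10),       # null genes
#'            cbind(matrix(rexp(50, 1 / 2), 5),   # DE genes, fold change 4
#'                  matrix(rexp(50, 1 / 8), 5)))
#' rownames(m) <- paste0("g", 1:15)
#' res <- ziExpLRT(m, group = rep(c("A", "B"), each = 10))
#' res[res$padj < 0.05, ]
#' @rdname ziExpLRT
#' @export
setMethod("ziExpLRT", "ZIExpDataSet",
  function(object, link = c("log", "identity"), reduced = NULL,
           empirical = FALSE, permutations = 100, seed = NULL,
           alpha = 0.05, ...) {
    link <- match.arg(link)
    V <- covariateMatrix(object)
    .runLRT(assay(object, "normcounts"), groupFactor(object),
            if (ncol(V) > 0L) V else NULL, link, reduced, empirical,
            permutations, seed, alpha)
  })

#' @rdname ziExpLRT
#' @export
setMethod("ziExpLRT", "matrix",
  function(object, group, covariates = NULL, link = c("log", "identity"),
           reduced = NULL, empirical = FALSE, permutations = 100,
           seed = NULL, alpha = 0.05, ...) {
    link <- match.arg(link)
    if (any(!is.finite(object)) || any(object < 0))
      stop("expression values must be non-negative and finite")
    if (nrow(object) == 0L) stop("empty expression matrix")
    if (is.null(rownames(object)))
      rownames(object) <- paste0("gene", seq_len(nrow(object)))
    if (!is.null(covariates)) covariates <- as.matrix(covariates)
    .runLRT(object, group, covariates, link, reduced, empirical,
            permutations, seed, alpha)
  })
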