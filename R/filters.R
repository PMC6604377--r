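## Gene filtering rules applied before DE analysis, and the gene-wise
## CV-mean diagnostics that motivate the Exponential working model (an
## Exponential distribution has CV = 1 at every mean, so low-abundance genes
## clustering at CV = 1 across mean deciles support the assumption).

.filterMatrix <- function(m, keep) m[keep, , drop = FALSE]

#' Remove low-information genes
#'
#' Keeps genes with mean expression `>= meanMin` and zero fraction
#' `<= maxZeroProp` (defaults: mean >= 0.3 and zeros in at most half the
#' samples, the usual pre-analysis rule for low-abundance normalized
#' counts). Gene order is preserved; the filter is idempotent.
#'
#' @param object a genes x samples matrix or [ZIExpDataSet-class].
#' @param meanMin minimum gene-wise mean (default 0.3).
#' @param maxZeroProp maximum allowed fraction of zero values (default 0.5).
#' @param ... unused.
#' @return the filtered object, same class as the input.
#'
#' @examples
#' m <- rbind(low = c(0, 0, 0, 1), ok = rep(0.3, 4))
#' colnames(m) <- paste0("s", 1:4)
#' rownames(filterLowInfo(m))  # "ok"
#' @rdname filterLowInfo
#' @export
setMethod("filterLowInfo", "matrix",
  function(object, meanMin = 0.3, maxZeroProp = 0.5, ...) {
    if (!is.finite(meanMin) || meanMin < 0)
      stop("'meanMin' must be a non-negative number")
    if (!is.finite(maxZeroProp) || maxZeroProp < 0 || maxZeroProp > 1)
      stop("'maxZeroProp' must lie in [0, 1]")
    keep <- rowMeans(object) >= meanMin &
      rowMeans(object == 0) <= maxZeroProp
    .filterMatrix(object, keep)
  })

#' @rdname filterLowInfo
#' @export
setMethod("filterLowInfo", "ZIExpDataSet",
  function(object, meanMin = 0.3, maxZeroProp = 0.5, ...) {
    m <- assay(object, "normcounts")
    keep <- rowMeans(m) >= meanMin & rowMeans(m == 0) <= maxZeroProp
    object[keep, ]
  })

.yanKeep <- function(m, strictAsPrinted) {
  med <- apply(m, 1L, stats::quantile, probs = 0.5, names = FALSE)
  q90 <- apply(m, 1L, stats::quantile, probs = 0.9, names = FALSE)
  if (strictAsPrinted) med > 0 & q90 < 0.1 else med > 0 & q90 >= 0.1
}

#' Two-step detection filter for lncRNA matrices
#'
#' Step 1 removes genes whose per-gene median (50th percentile) equals zero.
#' Step 2, by default, keeps genes whose 90th percentile is at least 0.1 —
#' the reading under which the filter removes genes with negligible
#' detectable expression. `strictAsPrinted = TRUE` instead keeps genes with
#' 90th percentile strictly below 0.1, the literal published wording, which
#' retains only near-undetected genes and is provided for comparability.
#' Sample quantiles use the default linear-interpolation definition.
#'
#' @param object a genes x samples matrix or [ZIExpDataSet-class].
#' @param strictAsPrinted use the literal `< 0.1` direction in step 2.
#' @param ... unused.
#' @return the filtered object, same class as the input.
#' @rdname yanTwoStepFilter
#' @export
setMethod("yanTwoStepFilter", "matrix",
  function(object, strictAsPrinted = FALSE, ...) {
    .filterMatrix(object, .yanKeep(object, strictAsPrinted))
  })

#' @rdname yanTwoStepFilter
#' @export
setMethod("yanTwoStepFilter", "ZIExpDataSet",
  function(object, strictAsPrinted = FALSE, ...) {
    object[.yanKeep(assay(object, "normcounts"), strictAsPrinted), ]
  })

.cvProfile <- function(m, nBins) {
  if (nBins < 1L) stop("'nBins' must be a positive integer")
  mu <- rowMeans(m)
  if (any(mu == 0)) {
    message(sum(mu == 0), " gene(s) with zero mean excluded from CV profile")
    m <- m[mu > 0, , drop = FALSE]
    mu <- mu[mu > 0]
  }
  if (nrow(m) < nBins)
    stop("need at least 'nBins' genes with positive mean")
  cv <- apply(m, 1L, stats::sd) / mu
  r <- rank(mu, ties.method = "first")
  bin <- as.integer(ceiling(r * nBins / length(mu)))
  data.frame(gene_id = rownames(m), mean = unname(mu), cv = unname(cv),
             bin = bin, stringsAsFactors = FALSE)
}

#' Gene-wise CV-mean profile
#'
#' Computes, per gene, the mean (zeros included), the coefficient of
#' variation (sample SD over mean, zeros included), and an equal-count bin
#' by mean percentile (`nBins = 10` gives deciles). Genes with zero mean are
#' excluded with a message. For Exponential-like low-abundance genes the CV
#' is close to 1 in every bin.
#'
#' @param object a genes x samples matrix or [ZIExpDataSet-class].
#' @param nBins number of mean-percentile bins (default 10).
#' @param ... unused.
#' @return `data.frame` with columns `gene_id`, `mean`, `cv`, `bin`.
#' @rdname cvProfile
#' @export
setMethod("cvProfile", "matrix",
  function(object, nBins = 10, ...) .cvProfile(object, nBins))

#' @rdname cvProfile
#' @export
setMethod("cvProfile", "ZIExpDataSet",
  function(object, nBins = 10, ...)
    .cvProfile(assay(object, "normcounts"), nBins))

#' Split genes into high- and low-abundance sets
#'
#' Splits a matrix at a quantile of the gene-wise means (default the 85th
#' percentile, the conventional high/low-abundance mRNA cutoff).
#'
#' @param object genes x samples matrix.
#' @param cutoff quantile of gene-wise means in (0, 1), default 0.85.
#' @return list with elements `high` and `low`, each a sub-matrix.
#' @export
splitByAbundance <- function(object, cutoff = 0.85) {
  if (cutoff <= 0 || cutoff >= 1) stop("'cutoff' must lie in (0, 1)")
  mu <- rowMeans(object)
  q <- stats::quantile(mu, cutoff, names = FALSE)
  list(high = object[mu > q, , drop = FALSE],
       low = object[mu <= q, , drop = FALSE])
}

#' Theoretical squared CV of a Negative Binomial gene
#'
#' Under the NB mean-variance relation `Var = mu + phi * mu^2`, the squared
#' coefficient of variation is `phi + 1/mu`: it falls toward `phi` as the
#' mean grows, so NB genes show a negative CV-mean trend.
#'
#' @param mu positive mean.
#' @param phi non-negative dispersion.
#' @return `phi + 1 / mu`.
#' @examples
#' nbCV2(mu = 1, phi = 0)   # Poisson limit, 1
#' nbCV2(mu = 2, phi = 0.5) # 1
#' @export
nbCV2 <- function(mu, phi) {
  if (any(mu <= 0)) stop("'mu' must be positive")
  if (any(phi < 0)) stop("'phi' must be non-negative")
  phi + 1 / mu
}

#' Theoretical squared CV of a Log-Normal gene
#'
#' For a Log-Normal with log-variance `sigma2`, the squared coefficient of
#' variation is `exp(sigma2) - 1`, independent of the mean: LN genes show a
#' flat CV-mean profile.
#'
#' @param sigma2 non-negative log-scale variance.
#' @return `exp(sigma2) - 1`.
#' @examples
#' lnCV2(log(2))  # 1
#' @export
lnCV2 <- function(sigma2) {
  if (any(sigma2 < 0)) stop("'sigma2' must be non-negative")
  exp(sigma2) - 1
}
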