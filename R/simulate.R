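## Zero-inflated expression generator and benchmarking utilities.
##
## Sampling is Bernoulli-then-positive: a Bernoulli(pi) mask decides which
## samples express the gene, and expressing samples receive a draw with
## conditional mean `mean / pi` from the chosen family, so the overall
## expectation is exactly `mean`:
##   exponential: Exp(mean = mean/pi)
##   nb:          NB(mu = mean/pi, Var = mu + phi mu^2), integer draws
##   lognormal:   LN(meanlog = log(mean/pi) - sigma2/2, sdlog = sqrt(sigma2))
## NB draws can themselves be zero, adding to the Bernoulli zeros; the
## unconditional mean is still `mean`.

#' Draw zero-inflated expression values
#'
#' @param n number of samples.
#' @param mean overall (unconditional) positive mean of the draws.
#' @param pi nonzero proportion of the Bernoulli mask, in (0, 1].
#' @param family `"exponential"`, `"nb"` or `"lognormal"`.
#' @param disp NB dispersion `phi` (`Var = mu + phi mu^2`) or LN
#'   log-variance `sigma2`; ignored for `"exponential"`.
#' @param seed optional integer seed (the caller's RNG state is preserved).
#'
#' @return numeric vector of `n` non-negative values with expectation
#'   `mean`.
#'
#' @examples
#' y <- sampleZI(1e4, mean = 2, pi = 0.5, family = "exponential", seed = 1)
#' mean(y)        # close to 2
#' mean(y == 0)   # close to 0.5
#' @export
sampleZI <- function(n, mean, pi = 1,
                     family = c("exponential", "nb", "lognormal"),
                     disp = NULL, seed = NULL) {
  family <- match.arg(family)
  if (mean <= 0) stop("'mean' must be positive")
  if (pi <= 0 || pi > 1) stop("'pi' must lie in (0, 1]")
  if (family != "exponential" && (is.null(disp) || disp < 0))
    stop(sprintf("'disp' (%s) must be non-negative for family '%s'",
                 if (family == "nb") "phi" else "sigma2", family))
  muc <- mean / pi
  .withSeed(seed, {
    mask <- if (pi < 1) stats::rbinom(n, 1L, pi) else rep(1L, n)
    draw <- switch(family,
      exponential = stats::rexp(n, rate = 1 / muc),
      nb = if (disp == 0) stats::rpois(n, muc)
           else stats::rnbinom(n, mu = muc, size = 1 / disp),
      lognormal = stats::rlnorm(n, meanlog = log(muc) - disp / 2,
                                sdlog = sqrt(disp)))
    mask * draw
  })
}

## synthetic per-gene baselines standing in for post-filter normalized-count
## means: right-skewed log-normal, rejection-sampled to >= 0.3 (the filter
## floor)
.syntheticBaselines <- function(nGenes) {
  out <- numeric(0)
  while (length(out) < nGenes) {
    cand <- stats::rlnorm(2L * nGenes, meanlog = 0, sdlog = 1)
    out <- c(out, cand[cand >= 0.3])
  }
  out[seq_len(nGenes)]
}

## candidate group-2 fold changes resembling tumor/normal contrasts
.syntheticShifts <- function(nGenes) {
  2^stats::rnorm(nGenes, mean = 0, sd = 1.5)
}

#' Build a two-group simulation scenario
#'
#' Fixes per-gene group-1 baseline means and group-2 multiplicative shifts
#' for a two-group experiment. Candidate shifts with `|log2(shift)| < 0.5`
#' are forced to exactly 1; those genes are the nulls (`truth = FALSE`), the
#' rest are DE. Baselines and shifts can be supplied; by default they are
#' drawn from a synthetic generator (log-normal baselines >= 0.3, log2
#' fold changes from N(0, 1.5^2)).
#'
#' @param nGenes number of genes.
#' @param nPerGroup samples per group N.
#' @param family sampling family, `"exponential"`, `"nb"` or `"lognormal"`.
#' @param pi nonzero proportion (default 0.7).
#' @param disp NB dispersion phi or LN sigma2 (ignored for exponential).
#' @param baselines optional positive per-gene group-1 means.
#' @param shifts optional candidate per-gene fold changes (the null-forcing
#'   rule is still applied).
#' @param seed integer seed; the same seed reproduces the scenario exactly.
#'
#' @return A [ZIExpScenario-class].
#'
#' @examples
#' sc <- buildScenario(nGenes = 50, nPerGroup = 20, seed = 1)
#' sc
#' @export
buildScenario <- function(nGenes = 200, nPerGroup = 100,
                          family = c("exponential", "nb", "lognormal"),
                          pi = 0.7, disp = 1, baselines = NULL,
                          shifts = NULL, seed = 1) {
  family <- match.arg(family)
  if (nGenes < 1L) stop("'nGenes' must be positive")
  .withSeed(seed, {
    if (is.null(baselines)) baselines <- .syntheticBaselines(nGenes)
    if (is.null(shifts)) shifts <- .syntheticShifts(nGenes)
  })
  if (length(baselines) != nGenes || length(shifts) != nGenes)
    stop("'baselines' and 'shifts' must have one entry per gene")
  if (any(baselines <= 0)) stop("baselines must be positive")
  shifts[abs(log2(shifts)) < 0.5] <- 1
  new("ZIExpScenario",
      family = family, pi = pi,
      disp = if (family == "exponential") NA_real_ else disp,
      nPerGroup = as.integer(nPerGroup),
      baselines = as.numeric(baselines), shifts = as.numeric(shifts),
      truth = shifts != 1,
      geneIds = sprintf("gene%04d", seq_len(nGenes)),
      seed = as.integer(seed))
}

#' Draw one replicate expression matrix from a scenario
#'
#' Group 1 samples are drawn at the per-gene baseline mean, group 2 samples
#' at baseline times shift, using the scenario's family, `pi` and
#' dispersion. Truth labels are stored in `rowData(...)$trueDE`.
#'
#' @param object a [ZIExpScenario-class].
#' @param seed integer seed for this replicate.
#' @param ... unused.
#' @return A [ZIExpDataSet-class] with groups `"A"` and `"B"`.
#' @rdname simulateCounts
#' @export
setMethod("simulateCounts", "ZIExpScenario", function(object, seed = 1, ...) {
  n <- object@nPerGroup
  nG <- length(object@baselines)
  disp <- if (object@family == "exponential") 0 else object@disp
  Y <- .withSeed(seed, {
    m <- matrix(0, nG, 2L * n)
    for (i in seq_len(nG)) {
      m[i, seq_len(n)] <- sampleZI(n, object@baselines[i], object@pi,
                                   object@family, disp)
      m[i, n + seq_len(n)] <- sampleZI(
        n, object@baselines[i] * object@shifts[i], object@pi,
        object@family, disp)
    }
    m
  })
  dimnames(Y) <- list(object@geneIds, sprintf("s%04d", seq_len(2L * n)))
  zds <- ZIExpDataSet(Y, group = rep(c("A", "B"), each = n))
  rowData(zds)$trueDE <- object@truth
  rowData(zds)$baseline <- object@baselines
  rowData(zds)$shift <- object@shifts
  metadata(zds) <- list(family = object@family, pi = object@pi,
                        disp = object@disp, seed = seed,
                        scenarioSeed = object@seed)
  zds
})

#' Confusion metrics and AUC for a benchmark replicate
#'
#' At the adjusted-p threshold: realized false discovery proportion
#' `FDR = FP / max(1, FP + TP)` and `TPR = TP / (TP + FN)` (zero rejections
#' give FDR 0 and, if there are true DE genes, TPR 0). The AUC is
#' threshold-free: the rank-based (Mann-Whitney) area under the ROC of
#' `1 - pvalue` scores against the truth labels. Genes with `NA` p-values
#' are excluded from all three metrics.
#'
#' @param results a [ZIExpResults-class] (or data.frame with `pvalue` and
#'   `padj` columns), one row per gene.
#' @param truth logical vector of true DE labels, aligned with `results`.
#' @param threshold adjusted-p significance threshold (default 0.05).
#' @return one-row `data.frame` with columns `fdr`, `tpr`, `auc`,
#'   `threshold`, `nGenes`.
#' @export
evaluatePerformance <- function(results, truth, threshold = 0.05) {
  if (nrow(results) != length(truth))
    stop("'results' and 'truth' must be aligned")
  p <- results$pvalue
  padj <- results$padj
  ok <- !is.na(p)
  p <- p[ok]; padj <- padj[ok]; truth <- truth[ok]
  call_pos <- !is.na(padj) & padj < threshold
  TP <- sum(call_pos & truth)
  FP <- sum(call_pos & !truth)
  FN <- sum(!call_pos & truth)
  fdr <- FP / max(1, FP + TP)
  tpr <- if (TP + FN > 0) TP / (TP + FN) else 0
  auc <- if (any(truth) && any(!truth)) {
    score <- 1 - p
    r <- rank(score)
    n1 <- sum(truth)
    (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * sum(!truth))
  } else NA_real_
  data.frame(fdr = fdr, tpr = tpr, auc = auc, threshold = threshold,
             nGenes = length(p))
}

#' Group-mean recovery experiment
#'
#' Simulates one gene in three biological groups (A, B, C) with true mean
#' expression `means`, repeatedly, under each requested sampling family;
#' fits the three-group zero-inflated Exponential model to every replicate
#' and summarizes the natural-scale group-mean estimates. Because the
#' estimator is quasi-likelihood, the NB and LN families recover the same
#' means as the Exponential family.
#'
#' @param nReplicates Monte Carlo replicates per family (default 1000).
#' @param nPerGroup samples per group (default 100).
#' @param means true group means (default `c(A = 2, B = 3, C = 8)`).
#' @param pi nonzero proportion (default 0.8).
#' @param phi NB dispersion (default 1).
#' @param sigma2 LN log-variance (default 0.25).
#' @param families families to run (default all three).
#' @param seed integer seed.
#'
#' @return `data.frame` with one row per family x group: the true mean and
#'   the mean, median and Monte Carlo standard error of the estimates.
#'
#' @examples
#' groupMeanRecovery(nReplicates = 50, nPerGroup = 50, seed = 1)
#' @export
groupMeanRecovery <- function(nReplicates = 1000, nPerGroup = 100,
                              means = c(A = 2, B = 3, C = 8), pi = 0.8,
                              phi = 1, sigma2 = 0.25,
                              families = c("exponential", "nb", "lognormal"),
                              seed = 1) {
  if (nReplicates < 2) stop("'nReplicates' must be at least 2")
  K <- length(means)
  if (is.null(names(means))) names(means) <- LETTERS[seq_len(K)]
  group <- factor(rep(names(means), each = nPerGroup),
                  levels = names(means))
  out <- list()
  for (fam in families) {
    disp <- switch(fam, exponential = 0, nb = phi, lognormal = sigma2)
    # replicates as rows of one matrix: the vectorized closed-form fit
    # estimates all replicates at once
    Y <- .withSeed(seed + match(fam, c("exponential", "nb", "lognormal")), {
      m <- matrix(0, nReplicates, K * nPerGroup)
      for (k in seq_len(K)) {
        cols <- (k - 1L) * nPerGroup + seq_len(nPerGroup)
        m[, cols] <- sampleZI(nReplicates * nPerGroup, means[k], pi, fam,
                              disp)
      }
      m
    })
    rownames(Y) <- sprintf("rep%04d", seq_len(nReplicates))
    colnames(Y) <- sprintf("s%04d", seq_len(K * nPerGroup))
    fit <- ziExpFit(Y, group = group, link = "log")
    gm <- groupMeans(fit)
    out[[fam]] <- data.frame(
      family = fam, group = names(means), trueMean = unname(means),
      estMean = colMeans(gm, na.rm = TRUE),
      estMedian = apply(gm, 2L, stats::median, na.rm = TRUE),
      mcse = apply(gm, 2L, stats::sd, na.rm = TRUE) /
        sqrt(colSums(!is.na(gm))),
      nReplicates = nReplicates, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' The full simulation grid of study conditions
#'
#' The benchmark grid: nonzero proportion `pi` in \{0.5, 0.7, 0.9\},
#' NB dispersion `phi` in \{1, 2, 10, 20\} and LN log-variance `sigma2` in
#' \{0.01, 0.25, 1, 2.25\}, sample size `N` in \{100, 200, 300\} per group.
#'
#' @return `data.frame` with columns `family`, `pi`, `disp`, `nPerGroup`.
#' @export
defaultScenarioGrid <- function() {
  g <- rbind(
    expand.grid(family = "nb", disp = c(1, 2, 10, 20),
                pi = c(0.5, 0.7, 0.9), nPerGroup = c(100, 200, 300),
                stringsAsFactors = FALSE),
    expand.grid(family = "lognormal", disp = c(0.01, 0.25, 1, 2.25),
                pi = c(0.5, 0.7, 0.9), nPerGroup = c(100, 200, 300),
                stringsAsFactors = FALSE))
  g[, c("family", "pi", "disp", "nPerGroup")]
}

#' Run the DE benchmark over a scenario grid
#'
#' For every row of `grid`, builds one fixed scenario (baselines and shifts
#' drawn once per scenario; only sampling noise varies across replicates),
#' draws `nReplicates` replicate matrices, runs the LRT, and averages the
#' per-replicate FDR and TPR at `threshold` and the AUC.
#'
#' @param grid `data.frame` with columns `family`, `pi`, `disp`,
#'   `nPerGroup` (see [defaultScenarioGrid()]); reduced grids are fine.
#' @param nGenes genes per scenario (default 200).
#' @param nReplicates replicates per scenario (default 100).
#' @param threshold adjusted-p threshold (default 0.05).
#' @param link link function passed to the LRT.
#' @param seed integer seed.
#'
#' @return `data.frame`: the grid columns plus mean `fdr`, `tpr`, `auc` and
#'   `nReplicates`.
#'
#' @examples
#' g <- data.frame(family = "exponential", pi = 0.7, disp = 0,
#'                 nPerGroup = 50)
#' runBenchmark(g, nGenes = 40, nReplicates = 3, seed = 1)
#' @export
runBenchmark <- function(grid, nGenes = 200, nReplicates = 100,
                         threshold = 0.05, link = "log", seed = 1) {
  stopifnot(all(c("family", "pi", "disp", "nPerGroup") %in% colnames(grid)))
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    sc <- buildScenario(nGenes = nGenes, nPerGroup = grid$nPerGroup[r],
                        family = grid$family[r], pi = grid$pi[r],
                        disp = grid$disp[r], seed = seed + r)
    reps <- vapply(seq_len(nReplicates), function(b) {
      zds <- simulateCounts(sc, seed = seed + r * 100000L + b)
      res <- ziExpLRT(zds, link = link, alpha = threshold)
      perf <- evaluatePerformance(res, rowData(zds)$trueDE, threshold)
      c(perf$fdr, perf$tpr, perf$auc)
    }, numeric(3))
    data.frame(grid[r, , drop = FALSE],
               fdr = mean(reps[1, ], na.rm = TRUE),
               tpr = mean(reps[2, ], na.rm = TRUE),
               auc = mean(reps[3, ], na.rm = TRUE),
               nReplicates = nReplicates, row.names = NULL)
  })
  do.call(rbind, rows)
}
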