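## Zero-inflated Exponential working model.
##
## Y_ij >= 0 are library-size normalized counts for gene i, sample j. The
## working density puts point mass 1 - pi at zero and an Exponential-type
## positive part:
##   f(y) = (1 - pi)^{I(y=0)} * ((pi^2 / lambda) exp(-pi y / lambda))^{I(y>0)}
## whose mean is lambda for every pi (the positive part has conditional mean
## lambda / pi and total mass pi). Group and covariate structure enters
## through lambda on the identity or log link.
##
## The zero-inflation is a nuisance saturated in the design groups: each
## level l of `piGroup` (by default the mean-model groups) carries its own
## nonzero probability pi_l, and (pi, beta, gamma) are maximized jointly.
## Given the mean structure, each pi_l has a closed-form profile (a
## quadratic root), and given pi the mean coefficients solve a weighted
## Exponential GLM, so fitting alternates two closed-form/standard steps.
## For a groups-only model with piGroup == group the joint maximum is fully
## closed form: pi_k = n_k+ / n_k and lambda_k = S_k / n_k, the group grand
## mean (zeros included) — which is what keeps the mean estimator unbiased
## when the sampling family (e.g. NB) itself contributes group-dependent
## zeros. The LRT fits the null with piGroup = the full design's groups, so
## the nuisance has the same structure under both hypotheses and
## D ~ chi^2(K_full - K_null).

#' Zero-inflated Exponential density
#'
#' Density/mass function of the zero-inflated Exponential working model:
#' mass `1 - pi` at zero and density `(pi^2 / lambda) * exp(-pi * y / lambda)`
#' for `y > 0`. The distribution has mean `lambda` for every `pi`, and its
#' positive part integrates to `pi`.
#'
#' @param y non-negative value(s) at which to evaluate.
#' @param lambda positive mean parameter(s).
#' @param pi nonzero-probability in `[0, 1]`.
#'
#' @return Numeric vector of density/mass values (recycled to the common
#'   length of the arguments).
#'
#' @examples
#' ziExpDensity(0, lambda = 5, pi = 0.5)    # 0.5, the zero mass
#' ziExpDensity(1, lambda = 1, pi = 1)      # plain Exponential: exp(-1)
#' integrate(ziExpDensity, 0, Inf, lambda = 2, pi = 0.5)$value  # = pi
#' @export
ziExpDensity <- function(y, lambda, pi) {
  if (any(!is.finite(lambda)) || any(lambda <= 0))
    stop("'lambda' must be positive and finite")
  if (any(!is.finite(pi)) || any(pi < 0) || any(pi > 1))
    stop("'pi' must lie in [0, 1]")
  if (any(!is.finite(y)) || any(y < 0))
    stop("'y' must be non-negative and finite")
  n <- max(length(y), length(lambda), length(pi))
  y <- rep_len(y, n); lambda <- rep_len(lambda, n); pi <- rep_len(pi, n)
  ifelse(y == 0, 1 - pi, pi^2 / lambda * exp(-pi * y / lambda))
}

## log-likelihood given per-sample means `lambda` and a common nonzero
## probability `pi`; -Inf when a zero observation coexists with pi == 1 or
## when the mean of a nonzero observation is nonpositive (identity-link
## barrier).
.ziLogLikCore <- function(y, lambda, pi) {
  nz <- y > 0
  n0 <- sum(!nz)
  if (any(!is.finite(lambda[nz])) || any(lambda[nz] <= 0)) return(-Inf)
  if (n0 > 0L && pi >= 1) return(-Inf)
  zero_part <- if (n0 > 0L) n0 * log1p(-pi) else 0
  zero_part +
    sum(2 * log(pi) - pi * y[nz] / lambda[nz] - log(lambda[nz]))
}

.groupIndicator <- function(group) {
  lev <- levels(group)
  G <- matrix(0, length(group), length(lev),
              dimnames = list(NULL, lev))
  G[cbind(seq_along(group), as.integer(group))] <- 1
  G
}

.linearPredictor <- function(group, covariates, beta, gamma) {
  eta <- beta[as.integer(group)]
  if (!is.null(covariates) && ncol(covariates) > 0L)
    eta <- eta + drop(covariates %*% gamma)
  eta
}

#' Zero-inflated Exponential log-likelihood
#'
#' Evaluates the zero-inflated Exponential GLM log-likelihood
#' `L* = sum_j l_j*` for one gene at given parameters. Zero observations
#' contribute `log(1 - pi)`; nonzero observations contribute
#' `2 log(pi) - pi * y / lambda_j - log(lambda_j)` with
#' `lambda_j = sum_k beta_k w_jk + sum_m gamma_m v_jm` (identity link) or
#' `log(lambda_j)` equal to that linear predictor (log link). The same
#' `lambda_j` appears in the ratio and the log term under both links. With
#' no zeros and `pi = 1` this is the plain Exponential GLM log-likelihood.
#'
#' @param y non-negative expression values, one per sample.
#' @param group factor of group membership, one per sample.
#' @param pi nonzero probability in `[0, 1]`.
#' @param beta group coefficients on the link scale, one per group level.
#' @param gamma covariate coefficients (`NULL` if no covariates).
#' @param covariates samples x M numeric matrix, or `NULL`.
#' @param link `"identity"` or `"log"`.
#'
#' @return The log-likelihood; `-Inf` when a zero observation coexists with
#'   `pi = 1`, or when the identity-link linear predictor is nonpositive
#'   for a nonzero observation (the documented barrier sentinel).
#'
#' @examples
#' ziExpLogLik(1, factor("A"), pi = 1, beta = 1, link = "identity")  # -1
#' ziExpLogLik(rep(0, 4), factor(rep("A", 4)), pi = 0.5, beta = 3,
#'             link = "identity")  # 4 * log(0.5)
#' @export
ziExpLogLik <- function(y, group, pi, beta, gamma = NULL, covariates = NULL,
                        link = c("log", "identity")) {
  link <- match.arg(link)
  group <- as.factor(group)
  if (length(y) != length(group))
    stop("'y' and 'group' must have the same length")
  if (any(!is.finite(y)) || any(y < 0))
    stop("'y' must be non-negative and finite")
  if (pi < 0 || pi > 1) stop("'pi' must lie in [0, 1]")
  if (length(beta) != nlevels(group))
    stop("'beta' must have one coefficient per group level")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != length(y))
      stop("'covariates' must have one row per sample")
    if (is.null(gamma) || length(gamma) != ncol(covariates))
      stop("'gamma' must have one coefficient per covariate column")
  }
  eta <- .linearPredictor(group, covariates, beta, gamma)
  lambda <- if (link == "log") exp(eta) else eta
  .ziLogLikCore(y, lambda, pi)
}

## Profile MLE of a nonzero probability given its mean structure: with
## a = (sum of y in the pi-group) / lambda, n0 zeros and npos nonzeros,
## d/dpi of [n0 log(1-pi) + 2 npos log(pi) - pi a] = 0 is the quadratic
## a pi^2 - (a + n0 + 2 npos) pi + 2 npos = 0; the root in (0, 1] is the
## maximizer. Vectorized over genes x pi-groups.
.profilePi <- function(a, n0, npos) {
  b <- a + n0 + 2 * npos
  out <- ifelse(a > 1e-12,
                (b - sqrt(pmax(b^2 - 8 * a * npos, 0))) / (2 * a),
                2 * npos / pmax(b, 1))
  out[npos == 0] <- 0
  pmin(out, 1)
}

## zero + "2 log(pi)" part of the log-likelihood; all args genes x L
.zeroPosPart <- function(pi, nl0, nlpos) {
  zp <- nl0 * log1p(-pi)
  zp[nl0 == 0] <- 0
  pp <- 2 * nlpos * log(pi)
  pp[nlpos == 0] <- 0
  rowSums(zp) + rowSums(pp)
}

## map from piGroup levels to mean-group levels; errors unless piGroup is
## nested inside group (each pi level lies within one mean group)
.piToGroupMap <- function(group, piGroup) {
  tab <- table(piGroup, group)
  if (any(rowSums(tab > 0) != 1L))
    stop("'piGroup' must be nested within the mean-model groups")
  apply(tab > 0, 1L, which)[levels(piGroup)]
}

## Joint fit of the groups-only model for all genes of Y at once, with the
## zero-inflation saturated in piGroup. Alternates the closed-form pi
## profile with the weighted-mean update of lambda; when piGroup == group
## the grand-mean initialization is already the fixed point.
.fitGroupsOnly <- function(Y, nzmat, group, piGroup) {
  G <- .groupIndicator(group)
  P <- .groupIndicator(piGroup)
  ml <- .piToGroupMap(group, piGroup)
  nl <- colSums(P)
  Sl <- Y %*% P
  nlpos <- nzmat %*% P
  nl0 <- sweep(-nlpos, 2L, nl, `+`)
  nkpos <- nzmat %*% G
  npos <- rowSums(nlpos)
  Ml <- matrix(0, ncol(P), ncol(G))
  Ml[cbind(seq_along(ml), ml)] <- 1

  lam <- (Y %*% G) / matrix(colSums(G), nrow(Y), ncol(G), byrow = TRUE)
  lam[lam <= 0 | !is.finite(lam)] <- 1      # placeholders, masked at end
  pi <- nlpos / matrix(nl, nrow(Y), ncol(P), byrow = TRUE)
  for (it in seq_len(100L)) {
    a <- Sl / lam[, ml, drop = FALSE]
    pi <- .profilePi(a, nl0, nlpos)
    lamNew <- ((pi * Sl) %*% Ml) / nkpos
    lamNew[nkpos == 0 | !is.finite(lamNew) | lamNew <= 0] <- 1
    delta <- max(abs(lamNew - lam) / pmax(lam, 1e-12))
    lam <- lamNew
    if (is.na(delta) || delta < 1e-12) break
  }
  meanPart <- -rowSums((pi * Sl) / lam[, ml, drop = FALSE])
  logLam <- log(lam)
  term <- nkpos * logLam
  term[nkpos == 0] <- 0
  ll <- .zeroPosPart(pi, nl0, nlpos) + meanPart - rowSums(term)
  lam[nkpos == 0] <- NA_real_
  ll[npos == 0] <- NA_real_
  list(lambda = lam, pi = pi, logLik = ll)
}

## One-gene fit with covariates: alternate the pi profile with a weighted
## Exponential GLM for the mean coefficients. Log link uses a Gamma(log)
## GLM on the nonzero observations with response w_j * y_j (its score
## equations are the stationarity conditions of the mean part and do not
## involve the Gamma shape); identity link uses Nelder-Mead with a -Inf
## barrier at nonpositive means.
.fitCovariates <- function(y, group, covariates, link, piGroup = group) {
  nz <- y > 0
  npos <- sum(nz)
  P <- .groupIndicator(piGroup)
  nl <- colSums(P)
  nlpos <- drop(crossprod(P, as.numeric(nz)))
  nl0 <- nl - nlpos
  G <- .groupIndicator(group)
  X <- cbind(G, covariates)
  K <- ncol(G)
  M <- ncol(covariates)

  pi <- nlpos / nl
  fitMean <- function(w) {
    if (link == "log") {
      fit <- suppressWarnings(stats::glm.fit(
        x = X[nz, , drop = FALSE], y = (w * y)[nz],
        family = stats::Gamma(link = "log"),
        control = stats::glm.control(epsilon = 1e-10, maxit = 200)))
      theta <- fit$coefficients
      eta <- .linearPredictor(group, covariates, theta[seq_len(K)],
                              theta[K + seq_len(M)])
      list(theta = unname(theta), lambda = exp(eta),
           converged = isTRUE(fit$converged))
    } else {
      start <- pmax(drop(crossprod(G, y)) / colSums(G), min(y[nz]) / 2)
      negll <- function(par) {
        lam <- .linearPredictor(group, covariates, par[seq_len(K)],
                                par[K + seq_len(M)])
        if (any(!is.finite(lam[nz])) || any(lam[nz] <= 0)) return(1e10)
        sum((w * y)[nz] / lam[nz] + log(lam[nz]))
      }
      opt <- stats::optim(c(start, rep(0, M)), negll,
                          method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      opt <- stats::optim(opt$par, negll, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-12))
      lam <- .linearPredictor(group, covariates,
                              opt$par[seq_len(K)], opt$par[K + seq_len(M)])
      list(theta = opt$par, lambda = lam,
           converged = opt$convergence == 0L && opt$value < 1e10)
    }
  }
  ll <- -Inf
  fit <- NULL
  for (it in seq_len(50L)) {
    w <- pi[as.integer(piGroup)]
    fit <- fitMean(w)
    a <- drop(crossprod(P, ifelse(nz, y / fit$lambda, 0)))
    pi <- .profilePi(a, nl0, nlpos)
    llNew <- .zeroPosPart(rbind(pi), rbind(nl0), rbind(nlpos)) -
      sum((pi[as.integer(piGroup)] * y / fit$lambda)[nz]) -
      sum(log(fit$lambda[nz]))
    if (is.finite(llNew) && abs(llNew - ll) < 1e-10 * (abs(ll) + 1)) {
      ll <- llNew
      break
    }
    ll <- llNew
  }
  list(pi = npos / length(y), piByGroup = pi,
       beta = fit$theta[seq_len(K)], gamma = fit$theta[K + seq_len(M)],
       logLik = ll, converged = fit$converged)
}

## Fit every gene of Y (genes x samples). Returns a ZIExpFit. Groups-only
## designs use the vectorized closed-form/alternating fit; covariate
## designs loop genes.
.fitMatrix <- function(Y, group, covariates, link, piGroup = NULL) {
  N <- ncol(Y)
  stopifnot(length(group) == N)
  group <- droplevels(as.factor(group))
  if (is.null(piGroup)) piGroup <- group
  piGroup <- droplevels(as.factor(piGroup))
  K <- nlevels(group)
  M <- if (is.null(covariates)) 0L else ncol(covariates)
  nzmat <- Y > 0
  npos <- rowSums(nzmat)
  n0 <- N - npos
  pihat <- npos / N
  geneIds <- rownames(Y)
  fittable <- npos > 0L

  if (M == 0L) {
    fit <- .fitGroupsOnly(Y, nzmat, group, piGroup)
    lambda <- fit$lambda
    ll <- fit$logLik
    coef <- if (link == "log") log(lambda) else lambda
    converged <- rep(TRUE, nrow(Y))
  } else {
    coef <- matrix(NA_real_, nrow(Y), K)
    gammaMat <- matrix(NA_real_, nrow(Y), M)
    ll <- rep(NA_real_, nrow(Y))
    converged <- rep(NA, nrow(Y))
    for (i in which(fittable)) {
      f <- .fitCovariates(Y[i, ], group, covariates, link, piGroup)
      coef[i, ] <- f$beta
      gammaMat[i, ] <- f$gamma
      ll[i] <- f$logLik
      converged[i] <- f$converged
    }
  }

  coef[!fittable, ] <- NA_real_
  ll[!fittable] <- NA_real_
  converged[!fittable] <- NA
  pihat[!fittable] <- NA_real_

  new("ZIExpFit",
      pi = unname(pihat),
      coef = matrix(unname(as.vector(coef)), nrow(Y), K,
                    dimnames = list(geneIds, levels(group))),
      covCoef = if (M == 0L)
        matrix(numeric(0), nrow(Y), 0L, dimnames = list(geneIds, NULL))
      else matrix(unname(as.vector(gammaMat)), nrow(Y), M,
                  dimnames = list(geneIds, colnames(covariates))),
      logLik = unname(ll),
      converged = as.logical(converged),
      link = link,
      groupLabels = levels(group),
      design = list(group = group, covariates = covariates,
                    piGroup = piGroup, sampleIds = colnames(Y)),
      nZero = as.integer(n0), nNonzero = as.integer(npos),
      geneIds = if (is.null(geneIds)) as.character(seq_len(nrow(Y)))
                else geneIds)
}

#' Fit the zero-inflated Exponential GLM gene by gene
#'
#' Maximum quasi-likelihood estimation of per-gene group effects (and
#' optional covariate coefficients) under the zero-inflated Exponential
#' working model. The zero-inflation is a group-saturated nuisance: each
#' design group carries its own nonzero probability, profiled in closed
#' form. For groups-only designs the joint maximum is fully closed form and
#' identical under both links, with natural-scale group mean
#' `lambda_k = S_k / n_k`, the group grand mean (zeros included) — which is
#' why the estimator stays unbiased when the data are NB or LN rather than
#' Exponential. Covariate models are fitted by alternating the nonzero
#' probability profile with a weighted Exponential GLM step (log link: a
#' Gamma GLM on the weighted nonzero values; identity link: direct
#' constrained optimization). Genes with all-zero expression cannot be
#' fitted and are returned with `NA` estimates; they should normally be
#' removed beforehand with [filterLowInfo()].
#'
#' @param object a [ZIExpDataSet-class], or a genes x samples numeric
#'   matrix.
#' @param link link function for the mean model, `"log"` (default; always
#'   yields positive fitted means) or `"identity"`.
#' @param group for the matrix method, a factor/vector of group labels, one
#'   per column.
#' @param covariates for the matrix method, an optional samples x M numeric
#'   matrix of covariates.
#' @param piGroup optional factor giving the grouping in which the
#'   zero-inflation nuisance is saturated; defaults to the design groups.
#'   [ziExpLRT()] uses this to give the null fit the same zero-inflation
#'   structure as the full fit.
#' @param ... unused.
#'
#' @return A [ZIExpFit-class] object.
#'
#' @examples
#' m <- rbind(g1 = c(0, 0, 2, 4), g2 = c(1, 2, 3, 4))
#' colnames(m) <- paste0("s", 1:4)
#' fit <- ziExpFit(m, group = rep("A", 4))
#' piEstimates(fit)   # 0.5, 1.0
#' groupMeans(fit)    # 1.5 (the grand mean) and 2.5
#' @rdname ziExpFit
#' @export
setMethod("ziExpFit", "ZIExpDataSet",
  function(object, link = c("log", "identity"), piGroup = NULL, ...) {
    link <- match.arg(link)
    V <- covariateMatrix(object)
    .fitMatrix(assay(object, "normcounts"), groupFactor(object),
               if (ncol(V) > 0L) V else NULL, link, piGroup)
  })

#' @rdname ziExpFit
#' @export
setMethod("ziExpFit", "matrix",
  function(object, group, covariates = NULL, link = c("log", "identity"),
           piGroup = NULL, ...) {
    link <- match.arg(link)
    if (any(!is.finite(object)) || any(object < 0))
      stop("expression values must be non-negative and finite")
    if (!is.null(covariates)) covariates <- as.matrix(covariates)
    if (is.null(rownames(object)))
      rownames(object) <- paste0("gene", seq_len(nrow(object)))
    .fitMatrix(object, group, covariates, link, piGroup)
  })

#' Fitted per-sample means
#'
#' Natural-scale fitted means `lambda_ij` for every gene and sample, from
#' the link-scale coefficients of a [ZIExpFit-class].
#'
#' @param object a [ZIExpFit-class].
#' @param ... unused.
#' @return genes x samples matrix of positive fitted means (`NA` rows for
#'   genes that could not be fitted).
#' @rdname fittedMeans
#' @export
setMethod("fittedMeans", "ZIExpFit", function(object, ...) {
  g <- object@design$group
  V <- object@design$covariates
  eta <- object@coef[, as.integer(g), drop = FALSE]
  if (!is.null(V) && ncol(V) > 0L)
    eta <- eta + object@covCoef %*% t(V)
  lam <- if (object@link == "log") exp(eta) else eta
  if (object@link == "identity" &&
      any(lam <= 0, na.rm = TRUE))
    stop("identity-link coefficients yield nonpositive fitted means")
  dimnames(lam) <- list(object@geneIds, object@design$sampleIds)
  lam
})
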