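# Independent oracles used across the suite. None of these call into the
# package's fitting path: they maximize the zero-inflated Exponential
# log-likelihood numerically, straight from its definition.

# direct evaluation of the zero-inflated log-likelihood for one group with
# its own (pi, lambda)
oracle_loglik_one_group <- function(y, pi, lambda) {
  if (pi < 0 || pi > 1 || lambda <= 0) return(-Inf)
  n0 <- sum(y == 0)
  if (n0 > 0 && pi >= 1) return(-Inf)
  if (n0 < length(y) && pi <= 0) return(-Inf)
  yp <- y[y > 0]
  (if (n0 > 0) n0 * log(1 - pi) else 0) +
    sum(2 * log(pi) - pi * yp / lambda - log(lambda))
}

# brute-force per-group maximization of the group-saturated model: each
# group's (pi_k, lambda_k) is optimized independently on a transformed
# scale, from several starts
oracle_fit_groups <- function(y, group) {
  group <- as.factor(group)
  lev <- levels(group)
  out <- list(pi = numeric(length(lev)), lambda = numeric(length(lev)),
              logLik = 0)
  for (k in seq_along(lev)) {
    yk <- y[group == lev[k]]
    if (all(yk == 0)) {
      out$pi[k] <- 0; out$lambda[k] <- NA_real_
      next
    }
    if (all(yk > 0)) {
      # no zeros: pi = 1 and plain Exponential MLE
      out$pi[k] <- 1; out$lambda[k] <- mean(yk)
      out$logLik <- out$logLik + oracle_loglik_one_group(yk, 1, mean(yk))
      next
    }
    obj <- function(par) {
      -oracle_loglik_one_group(yk, plogis(par[1]), exp(par[2]))
    }
    best <- NULL
    for (s in list(c(0, log(mean(yk))), c(1, 0), c(-1, 1))) {
      o <- optim(s, obj, method = "Nelder-Mead",
                 control = list(maxit = 5000, reltol = 1e-14))
      if (is.null(best) || o$value < best$value) best <- o
    }
    out$pi[k] <- plogis(best$par[1])
    out$lambda[k] <- exp(best$par[2])
    out$logLik <- out$logLik - best$value
  }
  out
}

# brute-force null fit: common lambda, per-group pi_k
oracle_fit_null <- function(y, group) {
  group <- as.factor(group)
  lev <- levels(group)
  K <- length(lev)
  obj <- function(par) {
    lambda <- exp(par[1])
    ll <- 0
    for (k in seq_len(K)) {
      yk <- y[group == lev[k]]
      if (all(yk == 0)) next
      ll <- ll + oracle_loglik_one_group(yk, plogis(par[1 + k]), lambda)
    }
    -ll
  }
  start <- c(log(sum(y) / sum(y > 0)),
             qlogis(pmin(0.95, pmax(0.05,
               tapply(y > 0, group, mean)))))
  best <- NULL
  for (jit in c(0, 0.3, -0.3)) {
    o <- optim(start + jit, obj, method = "Nelder-Mead",
               control = list(maxit = 10000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  list(lambda = exp(best$par[1]), pi = plogis(best$par[-1]),
       logLik = -best$value)
}

# brute-force LRT statistic for the group effect
oracle_lrt_stat <- function(y, group) {
  max(0, 2 * (oracle_fit_groups(y, group)$logLik -
                oracle_fit_null(y, group)$logLik))
}

# random zero-inflated Exponential test instance
random_instance <- function(K = sample(1:3, 1), n_range = 8:30,
                            pi_range = c(0.4, 1)) {
  g <- factor(rep(LETTERS[seq_len(K)], times = sample(n_range, K,
                                                      replace = TRUE)))
  mu <- runif(K, 0.5, 10)
  pi <- runif(K, pi_range[1], pi_range[2])
  y <- numeric(length(g))
  for (k in seq_len(K)) {
    idx <- which(g == LETTERS[k])
    y[idx] <- rbinom(length(idx), 1, pi[k]) *
      rexp(length(idx), rate = pi[k] / mu[k])
  }
  # guarantee at least one nonzero value overall
  if (all(y == 0)) y[1] <- rexp(1, 1 / mu[1])
  list(y = y, group = g)
}
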