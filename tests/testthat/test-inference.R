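make_fit <- function(loglik, K, geneIds = "g", link = "log",
                     group = NULL, piGroup = NULL) {
  # minimal ZIExpFit with a prescribed log-likelihood, for testing the LRT
  # arithmetic in isolation
  if (is.null(group)) group <- factor(rep(LETTERS[seq_len(K)], each = 2))
  n <- length(group)
  if (is.null(piGroup)) piGroup <- group
  new("ZIExpFit", pi = rep(0.5, length(geneIds)),
      coef = matrix(0, length(geneIds), K),
      covCoef = matrix(numeric(0), length(geneIds), 0),
      logLik = loglik, converged = rep(TRUE, length(geneIds)),
      link = link, groupLabels = levels(group),
      design = list(group = group, covariates = NULL, piGroup = piGroup,
                    sampleIds = paste0("s", seq_len(n))),
      nZero = rep(0L, length(geneIds)),
      nNonzero = rep(as.integer(n), length(geneIds)), geneIds = geneIds)
}

test_that("LRT statistic and p-value follow the chi-square contract", {
  g <- factor(rep(c("A", "B"), each = 2))
  null_g <- factor(rep("all", 4))
  # identical likelihoods: D = 0, p = 1
  full <- make_fit(-5, 2, group = g)
  null <- make_fit(-5, 1, group = null_g, piGroup = g)
  out <- lrtStatistics(full, null)
  expect_equal(out$stat, 0)
  expect_equal(out$pvalue, 1)
  expect_equal(out$df, 1L)
  # log-likelihood gap 1.92073 gives the chi-square(1) 95th percentile
  full2 <- make_fit(-5 + 1.92073, 2, group = g)
  out2 <- lrtStatistics(full2, null)
  expect_equal(out2$stat, 3.84146, tolerance = 1e-6)
  expect_equal(out2$pvalue, 0.05, tolerance = 1e-4)
})

test_that("non-nested or mismatched designs are rejected", {
  g <- factor(rep(c("A", "B"), each = 2))
  full <- make_fit(-5, 2, group = g)
  # not a coarsening: groups crossed
  other <- make_fit(-6, 2, group = factor(c("A", "B", "A", "B")),
                    piGroup = g)
  expect_error(lrtStatistics(full, other), "not nested")
  # same groups on both sides: nothing constrained, df would be 0
  same <- make_fit(-6, 2, group = g)
  expect_error(lrtStatistics(full, same), "at least one coefficient")
  crossed <- make_fit(-6, 1, group = factor(rep("all", 4)),
                      piGroup = factor(c("A", "B", "A", "B")))
  expect_error(lrtStatistics(full, crossed), "zero-inflation grouping")
  # different genes
  null <- make_fit(-5, 1, geneIds = "other", group = factor(rep("all", 4)),
                   piGroup = g)
  expect_error(lrtStatistics(full, null), "same genes")
})

test_that("D is non-negative over random instances with unbalanced zeros", {
  set.seed(31)
  for (r in 1:60) {
    inst <- random_instance(K = sample(2:3, 1))
    res <- ziExpLRT(rbind(g = inst$y), group = inst$group)
    if (res$status[1] == "ok") expect_gte(res$stat[1], 0)
  }
})

test_that("the LRT agrees with a brute-force maximization oracle", {
  set.seed(32)
  for (r in 1:10) {
    inst <- random_instance(K = 2, n_range = 10:20,
                            pi_range = c(0.5, 0.9))
    res <- ziExpLRT(rbind(g = inst$y), group = inst$group)
    expect_equal(res$stat[1], oracle_lrt_stat(inst$y, inst$group),
                 tolerance = 1e-4)
  }
})

test_that("identity and log link produce the same test", {
  set.seed(33)
  for (r in 1:20) {
    inst <- random_instance(K = 2)
    r1 <- ziExpLRT(rbind(g = inst$y), group = inst$group, link = "log")
    r2 <- ziExpLRT(rbind(g = inst$y), group = inst$group,
                   link = "identity")
    expect_equal(r1$stat, r2$stat, tolerance = 1e-6)
    expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-6)
  }
})

test_that("BH adjustment matches the step-up definition and the reference", {
  expect_equal(bhAdjust(0.04), 0.04)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # NA propagation: NAs excluded from m
  p <- c(0.01, NA, 0.04)
  expect_equal(bhAdjust(p), c(0.02, NA, 0.04))
  set.seed(34)
  for (r in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_lt(max(abs(bhAdjust(p) - p.adjust(p, "BH"))), 1e-12)
  }
})

test_that("empirical p-values follow the printed strict-inequality formula", {
  set.seed(35)
  # strong contrast: the observed labeling should beat every permutation
  y <- c(0.1, 0.2, 0.15, 0.1, 30, 35, 40, 28)
  g <- rep(c("A", "B"), each = 4)
  expect_equal(empiricalPValue(y, g, exhaustive = TRUE), 0)
  expect_equal(empiricalPValue(y, g, permutations = 50, seed = 1), 0)
  # smoothed estimator cannot return zero
  sm <- empiricalPValue(y, g, permutations = 50, seed = 1, smoothed = TRUE)
  expect_equal(sm, 1 / 51)
  # reproducibility
  y2 <- random_instance(K = 2)$y
  g2 <- rep(c("A", "B"), length.out = length(y2))
  e1 <- empiricalPValue(y2, g2, permutations = 100, seed = 9)
  e2 <- empiricalPValue(y2, g2, permutations = 100, seed = 9)
  expect_identical(e1, e2)
  expect_error(empiricalPValue(y, g, permutations = 0), "permutations")
})

test_that("exhaustive enumeration matches an independent oracle", {
  set.seed(36)
  y <- c(0, 1.2, 0.4, 2.5, 3.1, 0, 5.2, 4.4)
  g <- factor(rep(c("A", "B"), each = 4))
  D0 <- oracle_lrt_stat(y, g)
  sets <- combn(8, 4)
  Dp <- apply(sets, 2, function(ix) {
    gp <- factor(ifelse(seq_len(8) %in% ix, "A", "B"))
    oracle_lrt_stat(y, gp)
  })
  # relabelings tied with the observed statistic (e.g. the label-swapped
  # complement) sit exactly at D0, so bracket the strict-inequality count
  # by the oracle's numeric tolerance
  lo <- mean(Dp > D0 + 1e-5)
  hi <- mean(Dp > D0 - 1e-5)
  emp <- empiricalPValue(y, g, exhaustive = TRUE)
  expect_gte(emp, lo - 1e-8)
  expect_lte(emp, hi + 1e-8)
})

test_that("random permutations converge to the exhaustive value", {
  set.seed(37)
  y <- c(0, 0.8, 1.4, 0.3, 2.0, 2.6, 0, 3.3)
  g <- factor(rep(c("A", "B"), each = 4))
  exact <- empiricalPValue(y, g, exhaustive = TRUE)
  emp <- empiricalPValue(y, g, permutations = 400, seed = 5)
  se <- sqrt(exact * (1 - exact) / 400)
  expect_lt(abs(emp - exact), 3 * se + 1 / 400)
})

test_that("the DE driver handles null, strong and degenerate genes", {
  set.seed(38)
  n <- 100
  g <- rep(c("A", "B"), each = n)
  m <- rbind(
    matrix(sampleZI(10 * 2 * n, mean = 2, pi = 0.7), nrow = 10),
    strong = c(sampleZI(n, 1, 0.8), sampleZI(n, 8, 0.8)),
    dead = rep(0, 2 * n))
  rownames(m)[1:10] <- paste0("null", 1:10)
  res <- ziExpLRT(m, group = g)
  expect_s4_class(res, "ZIExpResults")
  expect_identical(rownames(res), rownames(m))  # input order kept
  # type-I control at small m: expect no more than ~2 of 10 null rejections
  expect_lte(sum(res[paste0("null", 1:10), "padj"] < 0.05, na.rm = TRUE), 2)
  # 8-fold contrast at N = 100/group is essentially always detected
  expect_lt(res["strong", "padj"], 0.05)
  expect_equal(unname(res["strong", "log2FoldChange"]), 3,
               tolerance = 0.5)
  # the all-zero gene is flagged and excluded from the BH family
  expect_identical(res["dead", "status"], "filtered")
  expect_true(is.na(res["dead", "pvalue"]))
  expect_identical(res[rownames(res) != "dead", "status"],
                   rep("ok", nrow(res) - 1L))
})

test_that("empirical p-values in the driver are deterministic given a seed", {
  set.seed(39)
  m <- matrix(sampleZI(5 * 40, mean = 2, pi = 0.8), nrow = 5)
  rownames(m) <- paste0("g", 1:5)
  g <- rep(c("A", "B"), each = 20)
  r1 <- ziExpLRT(m, group = g, empirical = TRUE, permutations = 60,
                 seed = 77)
  r2 <- ziExpLRT(m, group = g, empirical = TRUE, permutations = 60,
                 seed = 77)
  expect_identical(r1$empiricalP, r2$empiricalP)
  expect_true(all(r1$empiricalP >= 0 & r1$empiricalP <= 1))
  # empirical values are BH-adjustable downstream
  expect_equal(r1$empiricalPadj, bhAdjust(r1$empiricalP))
})

test_that("a single-group design is rejected for testing", {
  m <- matrix(rexp(20), nrow = 2,
              dimnames = list(c("a", "b"), paste0("s", 1:10)))
  expect_error(ziExpLRT(m, group = rep("A", 10)), "two groups")
  # but accepted for fitting
  expect_s4_class(ziExpFit(m, group = rep("A", 10)), "ZIExpFit")
})

test_that("asymptotic and empirical p-values agree on null genes", {
  set.seed(40)
  n <- 40
  g <- rep(c("A", "B"), each = n / 2)
  m <- matrix(sampleZI(60 * n, mean = 2, pi = 0.8), nrow = 60)
  rownames(m) <- paste0("g", 1:60)
  res <- ziExpLRT(m, group = g, empirical = TRUE, permutations = 120,
                  seed = 4)
  keep <- res$status == "ok"
  expect_gt(cor(res$pvalue[keep], res$empiricalP[keep]), 0.8)
})

test_that("covariate designs are tested with the covariate retained under the null", {
  set.seed(41)
  n <- 80
  g <- rep(c("A", "B"), each = n / 2)
  v <- matrix(rnorm(n, 0, 0.5), ncol = 1, dimnames = list(NULL, "age"))
  lam_de <- exp(log(c(2, 4))[as.integer(factor(g))] + 0.5 * v[, 1])
  lam_null <- exp(log(2) + 0.5 * v[, 1])
  m <- rbind(de = rbinom(n, 1, 0.8) * rexp(n, 0.8 / lam_de),
             null = rbinom(n, 1, 0.8) * rexp(n, 0.8 / lam_null))
  colnames(m) <- paste0("s", 1:n)
  res <- ziExpLRT(m, group = g, covariates = v)
  expect_identical(res$status, c("ok", "ok"))
  expect_identical(res$df, c(1L, 1L))
  expect_gte(min(res$stat), 0)
  # the gene with a genuine group effect scores far above the null gene
  expect_gt(res["de", "stat"], res["null", "stat"])
  # ZIExpDataSet route gives the same answer
  cd <- data.frame(group = g, age = v[, 1], row.names = colnames(m))
  zds <- ZIExpDataSet(m, colData = cd, group = "group",
                      covariates = "age")
  res2 <- ziExpLRT(zds)
  expect_equal(res2$stat, res$stat, tolerance = 1e-8)
})
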