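test_that("the generator matches its analytic moments", {
  set.seed(61)
  n <- 1e5
  for (cfg in list(
    list(fam = "exponential", mean = 2, pi = 0.5, disp = 0),
    list(fam = "exponential", mean = 5, pi = 1, disp = 0),
    list(fam = "nb", mean = 3, pi = 0.7, disp = 1),
    list(fam = "lognormal", mean = 2, pi = 0.9, disp = 0.25))) {
    y <- sampleZI(n, cfg$mean, cfg$pi, cfg$fam, cfg$disp)
    se <- sd(y) / sqrt(n)
    expect_lt(abs(mean(y) - cfg$mean), 3 * se)
    if (cfg$fam != "nb") {
      pz <- 1 - cfg$pi
      expect_lt(abs(mean(y == 0) - pz), 3 * sqrt(pz * (1 - pz) / n) + 1e-9)
    } else {
      # NB draws add their own zeros on top of the Bernoulli mask
      expect_gte(mean(y == 0), 1 - cfg$pi)
    }
  }
  # pi = 1 exponential: no zeros at all
  expect_identical(sum(sampleZI(1e4, 2, 1, "exponential") == 0), 0L)
})

test_that("the generator validates its arguments and respects seeds", {
  expect_error(sampleZI(10, mean = -1, pi = 0.5), "mean")
  expect_error(sampleZI(10, mean = 1, pi = 0), "pi")
  expect_error(sampleZI(10, mean = 1, pi = 0.5, family = "nb"), "disp")
  a <- sampleZI(50, 2, 0.7, "lognormal", 0.25, seed = 3)
  b <- sampleZI(50, 2, 0.7, "lognormal", 0.25, seed = 3)
  expect_identical(a, b)
  # caller RNG state is preserved
  set.seed(99); x1 <- runif(1)
  set.seed(99); invisible(sampleZI(10, 1, 0.5, seed = 7)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("scenarios force near-null shifts to exactly one", {
  sc <- buildScenario(nGenes = 30, nPerGroup = 10, seed = 2,
                      shifts = c(rep(1.3, 10), rep(2, 10), rep(0.4, 10)),
                      baselines = rep(1, 30))
  expect_true(all(sc@shifts[1:10] == 1))       # |log2 1.3| < 0.5: null
  expect_true(all(sc@shifts[11:20] == 2))      # |log2 2| = 1: DE
  expect_true(all(sc@shifts[21:30] == 0.4))    # |log2 0.4| > 0.5: DE
  expect_identical(sc@truth, sc@shifts != 1)
  # determinism of the synthetic generator
  s1 <- buildScenario(nGenes = 40, nPerGroup = 10, seed = 5)
  s2 <- buildScenario(nGenes = 40, nPerGroup = 10, seed = 5)
  expect_identical(s1@baselines, s2@baselines)
  expect_identical(s1@shifts, s2@shifts)
  # synthetic baselines respect the filter floor
  expect_true(all(s1@baselines >= 0.3))
})

test_that("replicate matrices honour the scenario parameters", {
  sc <- buildScenario(nGenes = 25, nPerGroup = 30, family = "exponential",
                      pi = 0.8, seed = 3)
  zds <- simulateCounts(sc, seed = 11)
  expect_s4_class(zds, "ZIExpDataSet")
  expect_identical(dim(zds), c(25L, 60L))
  expect_identical(levels(groupFactor(zds)), c("A", "B"))
  expect_identical(SummarizedExperiment::rowData(zds)$trueDE, sc@truth)
  # same seed, same matrix; different seed, different matrix
  expect_identical(normCounts(simulateCounts(sc, seed = 11)),
                   normCounts(zds))
  expect_false(identical(normCounts(simulateCounts(sc, seed = 12)),
                         normCounts(zds)))
})

test_that("performance metrics follow their definitions", {
  perfect <- data.frame(pvalue = c(rep(0, 5), rep(1, 5)),
                        padj = c(rep(0, 5), rep(1, 5)))
  truth <- rep(c(TRUE, FALSE), each = 5)
  out <- evaluatePerformance(perfect, truth)
  expect_equal(out[, c("fdr", "tpr", "auc")],
               data.frame(fdr = 0, tpr = 1, auc = 1))
  # no rejections: FDR and TPR are 0 by convention
  none <- data.frame(pvalue = rep(0.5, 10), padj = rep(1, 10))
  out2 <- evaluatePerformance(none, truth)
  expect_equal(out2$fdr, 0)
  expect_equal(out2$tpr, 0)
  expect_error(evaluatePerformance(perfect, truth[1:3]), "aligned")
})

test_that("AUC equals the rank-based reference on random scores", {
  set.seed(62)
  skip_if_not_installed("pROC")
  for (r in 1:10) {
    n <- 80
    truth <- rbinom(n, 1, 0.4) == 1
    if (!any(truth) || all(truth)) next
    p <- runif(n)
    res <- data.frame(pvalue = p, padj = p.adjust(p, "BH"))
    ours <- evaluatePerformance(res, truth)$auc
    ref <- suppressMessages(as.numeric(pROC::auc(
      pROC::roc(truth, 1 - p, quiet = TRUE,
                levels = c(FALSE, TRUE), direction = "<"))))
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("random scores give AUC near one half", {
  set.seed(63)
  n <- 4000
  truth <- rep(c(TRUE, FALSE), each = n / 2)
  p <- runif(n)
  res <- data.frame(pvalue = p, padj = p.adjust(p, "BH"))
  auc <- evaluatePerformance(res, truth)$auc
  expect_lt(abs(auc - 0.5), 3 / sqrt(n))
})

test_that("benchmark runs a reduced grid and reports every cell", {
  grid <- data.frame(family = c("exponential", "nb"), pi = 0.7,
                     disp = c(0, 1), nPerGroup = 40)
  out <- runBenchmark(grid, nGenes = 30, nReplicates = 3, seed = 8)
  expect_identical(nrow(out), 2L)
  expect_true(all(c("fdr", "tpr", "auc") %in% colnames(out)))
  expect_true(all(out$auc > 0.5))  # real signal present
  # null-only scenario: tpr 0 by convention
  sc_null <- buildScenario(nGenes = 20, nPerGroup = 30, seed = 4,
                           shifts = rep(1, 20))
  zds <- simulateCounts(sc_null, seed = 1)
  res <- ziExpLRT(zds)
  perf <- evaluatePerformance(res, SummarizedExperiment::rowData(zds)$trueDE)
  expect_equal(perf$tpr, 0)  # no true positives exist
  # the empty-rejection convention gives FDR 0
  noCalls <- data.frame(pvalue = res$pvalue, padj = pmax(res$padj, 0.5))
  expect_equal(
    evaluatePerformance(noCalls,
                        SummarizedExperiment::rowData(zds)$trueDE)$fdr, 0)
})

test_that("power increases with sample size", {
  set.seed(64)
  tpr_for_n <- function(n) {
    sc <- buildScenario(nGenes = 60, nPerGroup = n, pi = 0.7, seed = 21,
                        baselines = rep(2, 60),
                        shifts = rep(c(1, 2), each = 30))
    mean(vapply(1:8, function(b) {
      zds <- simulateCounts(sc, seed = 100 + b)
      evaluatePerformance(ziExpLRT(zds),
                          SummarizedExperiment::rowData(zds)$trueDE)$tpr
    }, numeric(1)))
  }
  t_small <- tpr_for_n(25)
  t_large <- tpr_for_n(150)
  expect_gt(t_large, t_small)
  expect_gt(t_large, 0.9)
})

test_that("the published scenario grid is complete", {
  g <- defaultScenarioGrid()
  expect_identical(nrow(g), 72L)  # 2 families x 4 dispersions x 3 pi x 3 N
  expect_identical(sort(unique(g$pi)), c(0.5, 0.7, 0.9))
  expect_identical(sort(unique(g$nPerGroup)), c(100, 200, 300))
  expect_identical(sort(unique(g$disp[g$family == "nb"])), c(1, 2, 10, 20))
  expect_identical(sort(unique(g$disp[g$family == "lognormal"])),
                   c(0.01, 0.25, 1, 2.25))
})
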