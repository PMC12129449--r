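test_that("one-way RM-ANOVA matches the aov decomposition exactly", {
  set.seed(101)
  Y <- matrix(rnorm(12, mean = rep(c(0, 0.5, 1), each = 4)), 4, 3,
              dimnames = list(paste0("s", 1:4), c("BL", "T1", "T2")))
  res <- oneWayRmAnova(rmTable(Y))
  oracle <- aovRmF(Y)
  expect_equal(statistic(res), oracle$F, tolerance = 1e-10)
  expect_equal(pValue(res), oracle$p, tolerance = 1e-10)
  expect_equal(res@df, c(2, 6))
  # identical condition means per subject: F = 0, p = 1
  Y0 <- matrix(rep(1:4, 3), 4, 3,
               dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  res0 <- oneWayRmAnova(rmTable(Y0))
  expect_equal(statistic(res0), 0)
  expect_equal(pValue(res0), 1)
})

test_that("RM-ANOVA with two levels satisfies F = t^2 of the paired t", {
  set.seed(7)
  x <- rnorm(9, 1); y <- rnorm(9, 1.4)
  Y <- cbind(a = x, b = y); rownames(Y) <- paste0("s", 1:9)
  f <- statistic(oneWayRmAnova(rmTable(Y)))
  tt <- pairedT(x, y)
  expect_equal(f, statistic(tt)^2, tolerance = 1e-8)
  expect_equal(pValue(oneWayRmAnova(rmTable(Y))), pValue(tt),
               tolerance = 1e-8)
})

test_that("Greenhouse-Geisser epsilon is bounded and conservative for F > 1", {
  set.seed(11)
  for (i in 1:8) {
    Y <- matrix(rnorm(9 * 4), 9, 4,
                dimnames = list(paste0("s", 1:9), paste0("t", 1:4)))
    res <- oneWayRmAnova(rmTable(Y))
    eps <- res@details$epsilonGG
    expect_gte(eps, 1 / 3)
    expect_lte(eps, 1)
    expect_true(res@pGG >= 0 && res@pGG <= 1)
    # shrinking both df raises the p-value whenever F exceeds 1
    if (statistic(res) > 1) {
      expect_gte(res@pGG, pValue(res) - 1e-12)
    }
  }
})

test_that("incomplete subjects are dropped listwise with a message", {
  Y <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
  tab <- rmTable(Y)
  tab <- tab[!(tab$subject_id == "s4" & tab$epoch == "c"), ]
  expect_message(res <- oneWayRmAnova(tab), "listwise")
  expect_equal(res@details$n, 3)
  expect_error(suppressMessages(oneWayRmAnova(tab[tab$subject_id %in%
                                                    c("s1", "s4"), ])),
               "insufficient")
})

test_that("two-way RM-ANOVA finds injected effects and nulls", {
  set.seed(3)
  d <- expand.grid(subject_id = paste0("s", 1:8),
                   treatment = c("SL", "J60"),
                   epoch = c("BL", "T1", "T2"),
                   stringsAsFactors = FALSE)
  d$value <- rnorm(nrow(d), sd = 0.3) + 2 * (d$treatment == "J60")
  res <- twoWayRmAnova(d)
  eff <- effectsTable(res)
  expect_lt(eff$p[eff$effect == "treatment"], 0.05)
  # identical across treatment: treatment F ~ 0
  d2 <- d
  v <- d2$value[d2$treatment == "SL"]
  d2$value[d2$treatment == "J60"] <- v
  eff2 <- effectsTable(twoWayRmAnova(d2))
  expect_lt(eff2$F[eff2$effect == "treatment"], 1e-10)
  # missing cells are reported
  d3 <- d[!(d$subject_id %in% paste0("s", 1:7) & d$epoch == "T2"), ]
  expect_error(suppressMessages(twoWayRmAnova(d3)), "insufficient")
})

test_that("paired t matches the textbook formula and is antisymmetric", {
  x <- c(5.1, 4.8, 6.2, 5.9, 5.5)
  y <- c(4.9, 4.9, 5.8, 5.2, 5.4)
  res <- pairedT(x, y)
  d <- x - y
  tOracle <- mean(d) / (sd(d) / sqrt(length(d)))
  expect_equal(statistic(res), tOracle, tolerance = 1e-12)
  expect_equal(pValue(res), 2 * pt(-abs(tOracle), 4), tolerance = 1e-12)
  swapped <- pairedT(y, x)
  expect_equal(statistic(swapped), -statistic(res))
  expect_equal(pValue(swapped), pValue(res))
  expect_error(pairedT(x, x), "zero variance")
})

test_that("Tukey HSD flags only genuinely shifted levels", {
  set.seed(21)
  n <- 8
  Y <- cbind(BL = rnorm(n, 0, 0.2), T1 = rnorm(n, 0, 0.2),
             T2 = rnorm(n, 3, 0.2))
  rownames(Y) <- paste0("s", 1:n)
  res <- oneWayRmAnova(rmTable(Y))
  ph <- tukeyHsd(res)
  hits <- ph$comparison[ph$p_adj <= 0.05]
  expect_setequal(hits, c("T2 - BL", "T2 - T1"))
  expect_true(all(ph$p_adj >= ph$p_unadj - 1e-12))
  # exactly equal level means: nothing significant
  Y0 <- matrix(rnorm(24, 5, 0.3), 8, 3,
               dimnames = list(paste0("s", 1:8), c("a", "b", "c")))
  Y0 <- sweep(Y0, 2, colMeans(Y0)) + 5
  ph0 <- tukeyHsd(oneWayRmAnova(rmTable(Y0)))
  expect_true(all(ph0$p_adj > 0.05))
  # fewer than 3 levels: not applicable
  Y2 <- Y0[, 1:2]
  expect_message(ph2 <- tukeyHsd(oneWayRmAnova(rmTable(Y2))),
                 "not applicable")
  expect_equal(nrow(ph2), 0L)
})

test_that("Yates chi-squared reproduces printed and closed-form values", {
  res <- chiSquaredYates(rbind(c(6, 5), c(9, 0)))
  expect_equal(round(statistic(res), 4), 3.2997)
  expect_equal(res@df, 1)
  expect_equal(round(pValue(res), 5), 0.06929)
  # proportional rows: statistic clamps to 0
  res0 <- chiSquaredYates(rbind(c(10, 10), c(5, 5)))
  expect_equal(statistic(res0), 0)
  expect_equal(pValue(res0), 1)
  # random tables against stats::chisq.test (independent route)
  set.seed(5)
  for (i in 1:200) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    mine <- chiSquaredYates(tab)
    ref <- suppressWarnings(chisq.test(tab, correct = TRUE))
    expect_equal(statistic(mine), unname(ref$statistic), tolerance = 1e-12)
    expect_equal(pValue(mine), ref$p.value, tolerance = 1e-12)
  }
  expect_error(chiSquaredYates(rbind(c(0, 0), c(1, 2))), "margin")
  expect_error(chiSquaredYates(rbind(c(1.5, 2), c(1, 2))), "integer")
})

test_that("Pearson correlation matches the covariance formula", {
  x <- c(1, 2, 3, 4, 5, 6)
  expect_equal(statistic(pearsonCorr(x, 2 * x + 1)), 1)
  expect_equal(statistic(pearsonCorr(x, -x)), -1)
  set.seed(9)
  y <- x + rnorm(6)
  res <- pearsonCorr(x, y)
  rOracle <- cov(x, y) / (sd(x) * sd(y))
  expect_equal(statistic(res), rOracle, tolerance = 1e-12)
  tOracle <- rOracle * sqrt(4 / (1 - rOracle^2))
  expect_equal(pValue(res), 2 * pt(-abs(tOracle), 4), tolerance = 1e-12)
  expect_error(pearsonCorr(rep(1, 5), 1:5), "constant")
})

test_that("the normality gate routes by distribution shape", {
  set.seed(13)
  paramHits <- mean(replicate(100, {
    normalityGate(rnorm(50)) == "parametric"
  }))
  expect_gt(paramHits, 0.85)
  heavyHits <- mean(replicate(100, {
    normalityGate(rcauchy(50)) == "nonparametric"
  }))
  expect_gt(heavyHits, 0.9)
  expect_identical(normalityGate(rep(2, 3)), "nonparametric")
  expect_identical(normalityGate(c(1, 2)), "nonparametric")
})

test_that("auto-gated comparisons dispatch the nonparametric equivalents", {
  set.seed(17)
  # heavy-tailed paired data go to the signed-rank test
  x <- rcauchy(20); y <- x + rcauchy(20)
  res <- pairedTAuto(x, y)
  expect_match(res@testName, "Wilcoxon")
  # clean Gaussian data stay parametric
  res2 <- pairedTAuto(rnorm(20), rnorm(20))
  expect_match(res2@testName, "paired t")
  # RM route: Cauchy cell noise triggers Friedman
  Yh <- matrix(rcauchy(9 * 4), 9, 4,
               dimnames = list(paste0("s", 1:9), paste0("t", 1:4)))
  resF <- oneWayRmAnovaAuto(rmTable(Yh))
  expect_match(resF@testName, "Friedman")
})

test_that("test statistics are invariant to positive rescaling", {
  set.seed(23)
  Y <- matrix(rnorm(9 * 3, 5), 9, 3,
              dimnames = list(paste0("s", 1:9), c("a", "b", "c")))
  f1 <- statistic(oneWayRmAnova(rmTable(Y)))
  f2 <- statistic(oneWayRmAnova(rmTable(Y * 137)))
  expect_equal(f1, f2, tolerance = 1e-9)
  x <- rnorm(8, 3); y <- rnorm(8, 3.5)
  expect_equal(statistic(pairedT(x * 7, y * 7)), statistic(pairedT(x, y)),
               tolerance = 1e-9)
  expect_equal(statistic(pearsonCorr(x * 7, y * 3)),
               statistic(pearsonCorr(x, y)), tolerance = 1e-12)
})
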