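# Confusion counts, scalar metrics, PR curves, radar transform, relative
# differences, Kruskal-Wallis, and fold summaries.

test_that("confusion counts are exact and match a per-pixel loop oracle", {
  a <- matrix(0, 4, 4); a[1:2, 1:2] <- 1
  cc <- confusionCounts(a, a)
  expect_equal(cc, list(tp = 4, fp = 0, fn = 0, tn = 12))

  b <- matrix(0, 4, 4); b[3:4, 3:4] <- 1
  cc2 <- confusionCounts(a, b)
  expect_equal(cc2[c("tp", "fp", "fn")], list(tp = 0, fp = 4, fn = 4))

  set.seed(21)
  p <- matrix(rbinom(32 * 32, 1, 0.3), 32, 32)
  y <- matrix(rbinom(32 * 32, 1, 0.2), 32, 32)
  oracle <- c(tp = 0, fp = 0, fn = 0, tn = 0)
  for (i in seq_along(p)) {
    k <- if (p[i] == 1 && y[i] == 1) "tp" else if (p[i] == 1) "fp"
         else if (y[i] == 1) "fn" else "tn"
    oracle[k] <- oracle[k] + 1
  }
  expect_equal(unlist(confusionCounts(p, y)), oracle)
  expect_equal(sum(unlist(confusionCounts(p, y))), 1024)

  expect_error(confusionCounts(matrix(0, 2, 2), matrix(0, 3, 3)), "shapes")
  expect_error(confusionCounts(matrix(0.5, 2, 2), matrix(0, 2, 2)), "binary")
})

test_that("scalar metrics match closed forms and degenerate conventions", {
  m <- scalarMetrics(list(tp = 2, fp = 2, fn = 2, tn = 10))
  expect_equal(m$dsc, 0.5)
  expect_equal(m$jaccard, 1 / 3)
  expect_equal(m$precision, 0.5)
  expect_equal(m$sensitivity, 0.5)

  perfect <- scalarMetrics(list(tp = 5, fp = 0, fn = 0, tn = 11))
  expect_true(all(unlist(perfect) == 1))

  empty <- scalarMetrics(list(tp = 0, fp = 0, fn = 0, tn = 16))
  expect_equal(empty$dsc, 1)
  expect_equal(empty$jaccard, 1)
  expect_equal(empty$precision, 1)
  expect_equal(empty$sensitivity, 1)

  falsePos <- scalarMetrics(list(tp = 0, fp = 3, fn = 0, tn = 13))
  expect_equal(falsePos$dsc, 0)
  expect_equal(falsePos$sensitivity, 0)
})

test_that("dsc = 2J/(1+J) and specificity + FPR = 1 for any counts", {
  set.seed(22)
  for (rep in 1:20) {
    cc <- as.list(stats::setNames(rmultinom(1, 256, c(.2, .2, .2, .4))[, 1],
                                  c("tp", "fp", "fn", "tn")))
    m <- scalarMetrics(cc)
    expect_equal(m$dsc, 2 * m$jaccard / (1 + m$jaccard), tolerance = 1e-12)
    fpr <- if (cc$fp + cc$tn > 0) cc$fp / (cc$fp + cc$tn) else 0
    expect_equal(m$specificity + fpr, 1, tolerance = 1e-12)
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
  }
})

test_that("PR curve and AUC match brute-force threshold enumeration", {
  # perfectly separating scores
  sep <- prCurve(c(.9, .8, .85, .2, .1, .3), c(1, 1, 1, 0, 0, 0))
  expect_equal(sep$auc, 1.0)

  # all-equal scores: single point at precision = prevalence
  flat <- prCurve(rep(0.7, 10), c(1, 1, 0, 0, 0, 1, 0, 0, 0, 0))
  expect_equal(nrow(flat$points), 1L)
  expect_equal(flat$points$precision, 0.3)
  expect_equal(flat$points$recall, 1)

  set.seed(23)
  for (rep in 1:10) {
    sc <- round(runif(10), 2)
    y <- rbinom(10, 1, 0.4)
    if (sum(y) == 0) y[1] <- 1
    r <- prCurve(sc, y)
    expect_equal(r$auc, bruteForcePr(sc, y), tolerance = 1e-12)
    expect_true(all(diff(r$points$recall) >= 0))
    expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  }

  expect_error(prCurve(c(.1, .2), c(0, 0)), "no positive")
})

test_that("PR AUC is invariant under strictly monotone score transforms", {
  set.seed(24)
  sc <- runif(50)
  y <- rbinom(50, 1, 0.3); if (sum(y) == 0) y[1] <- 1
  a1 <- prCurve(sc, y)$auc
  expect_equal(prCurve(plogis(5 * sc - 2), y)$auc, a1, tolerance = 1e-12)
  expect_equal(prCurve(sc^3, y)$auc, a1, tolerance = 1e-12)
})

test_that("radar transform endpoints and worked value hold", {
  expect_equal(radarPercentage(0.816, 0.816), 100)
  expect_equal(radarPercentage(0.5, 0.816), 0)
  expect_equal(radarPercentage(0.790, 0.816), 91.77, tolerance = 1e-2)
  expect_error(radarPercentage(0.4, 0.5), "exceed")
})

test_that("relative differences reproduce the reported comparisons", {
  expect_equal(relativeDifference(0.816, 0.790), -3.19)   # Dice, lower
  expect_equal(relativeDifference(0.825, 0.706), -14.42)  # precision, lower
  expect_equal(relativeDifference(0.814, 0.903), 9.86)    # sensitivity, higher
  expect_equal(relativeDifference(0.5, 0.5), 0)
  # symmetric in magnitude, antisymmetric in sign
  expect_equal(relativeDifference(0.7, 0.9), -relativeDifference(0.9, 0.7))
  expect_error(relativeDifference(0, 1), "positive")
})

# from-scratch rank-formula oracle with tie correction
kwOracle <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), vapply(groups, length, integer(1)))
  n <- length(x)
  r <- rank(x)
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  list(statistic = H,
       p.value = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

test_that("Kruskal-Wallis matches the rank-formula oracle and its invariances", {
  same <- kruskalWallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p.value, 1)

  g <- list(c(1, 2, 3), c(4, 5, 6))
  r <- kruskalWallis(g)
  o <- kwOracle(g)
  expect_equal(r$statistic, o$statistic, tolerance = 1e-10)
  expect_equal(r$p.value, o$p.value, tolerance = 1e-10)

  set.seed(25)
  for (rep in 1:5) {
    gg <- list(rnorm(7), rnorm(5, 1), rnorm(6, -1))
    rr <- kruskalWallis(gg)
    oo <- kwOracle(gg)
    expect_equal(rr$statistic, oo$statistic, tolerance = 1e-10)
    expect_gt(rr$p.value, 0); expect_lte(rr$p.value, 1)
    # invariant under common strictly monotone transforms
    rt <- kruskalWallis(lapply(gg, function(v) exp(v)))
    expect_equal(rt$statistic, rr$statistic, tolerance = 1e-10)
  }

  expect_error(kruskalWallis(list(1:3)), "two")
  expect_error(kruskalWallis(list(1:3, numeric(0))), "non-empty")
})

test_that("fold summaries reproduce the cross-validation table means", {
  s1 <- foldSummary(c(0.8020, 0.8044, 0.8030, 0.7552, 0.7923))
  expect_equal(round(s1$mean, 4), 0.7914)
  s2 <- foldSummary(c(0.8080, 0.7870, 0.8023, 0.7295, 0.7627))
  expect_equal(round(s2$mean, 4), 0.7779)
  expect_equal(s2$sd, sd(c(0.8080, 0.7870, 0.8023, 0.7295, 0.7627)))

  single <- foldSummary(0.75)
  expect_equal(single$mean, 0.75)
  expect_equal(single$sd, 0)
  expect_error(foldSummary(numeric(0)), "empty")
})
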