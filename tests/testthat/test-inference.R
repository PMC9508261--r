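test_that("Cohen's d uses the pooled SD", {
  expect_equal(cohensD(c(1, 2), c(1, 2)), 0)
  x <- 1 + c(-1, 1) / sqrt(2)                 # mean 1, SD 1
  y <- 0 + c(-1, 1) / sqrt(2)                 # mean 0, SD 1
  expect_equal(cohensD(x, y), 1)
  expect_equal(cohensD(c(2, 4), c(1, 3)), 1 / sqrt(2))
  expect_error(cohensD(c(1, 1), c(1, 1)), "pooled SD")
})

test_that("BH-FDR matches the brute-force step-up oracle", {
  fd <- bhFDR(c(0.01, 0.02, 0.03, 0.04), alpha = 0.05)
  expect_true(all(fd$reject))
  expect_false(any(bhFDR(rep(1, 5), 0.05)$reject))
  one <- bhFDR(0.04, 0.05)
  expect_true(one$reject); expect_equal(one$q, 0.04)
  expect_length(bhFDR(numeric(0), 0.05)$q, 0)

  set.seed(41)
  for (i in 1:60) {
    p <- round(runif(sample(1:6, 1)), sample(1:3, 1))
    ours <- bhFDR(p, alpha = 0.05)
    oracle <- bruteBH(p, alpha = 0.05)
    expect_equal(ours$q, oracle$q, tolerance = 1e-12)
    expect_equal(ours$reject, oracle$reject)
  }
})

test_that("two-sample t tests reproduce the published summary comparisons", {
  acc <- tTestSummary(84.5, 10.1, 29, 91.5, 6.0, 29)
  expect_equal(round(acc$p, 3), 0.002)
  iq <- tTestSummary(100.2, 11.8, 27, 109.3, 10.2, 29)
  expect_equal(round(iq$p, 3), 0.003)
  rt <- tTestSummary(949.6, 147.7, 29, 879.5, 129.7, 29)
  expect_lt(abs(rt$p - 0.059), 0.001)

  ## Welch variant reproduces accuracy and IQ to printed precision too
  expect_equal(round(tTestSummary(84.5, 10.1, 29, 91.5, 6.0, 29, "welch")$p, 3), 0.002)
  expect_equal(round(tTestSummary(100.2, 11.8, 27, 109.3, 10.2, 29, "welch")$p, 3), 0.003)

  same <- tTestSummary(5, 1, 10, 5, 1, 10)
  expect_equal(same$t, 0); expect_equal(same$p, 1)

  ## summary path agrees with stats::t.test on raw samples
  set.seed(42)
  a <- rnorm(12); b <- rnorm(15, 0.5)
  expect_equal(tTestSummary(mean(a), sd(a), 12, mean(b), sd(b), 15)$p,
               tTestTwoSample(a, b)$p, tolerance = 1e-12)
})

test_that("group permutation test handles degenerate and planted cases", {
  set.seed(43)
  D <- matrix(rnorm(20 * 8), 20, 8)
  D[11:20, ] <- D[1:10, ]                     # identical groups per pairing
  res <- groupPermutationTest(D, rep(c("a", "b"), each = 10), nPerm = 200)
  expect_true(all(resultTable(res)$p == 1))
  expect_true(all(resultTable(res)$statistic == 0))

  D2 <- matrix(rnorm(20 * 30), 20, 30)
  D2[1:10, 3] <- D2[1:10, 3] + 4              # large planted shift
  res2 <- groupPermutationTest(D2, rep(c("a", "b"), each = 10), nPerm = 500,
                               seed = 7)
  tb <- resultTable(res2)
  expect_true(tb$significant[3])
  expect_gt(tb$d[3], 1)
  expect_error(groupPermutationTest(D2, rep("a", 20), nPerm = 200), "two groups")
})

test_that("group permutation p-values are valid and reproducible", {
  set.seed(44)
  D <- matrix(rnorm(16 * 40), 16, 40)
  labels <- rep(c("a", "b"), each = 8)
  r1 <- groupPermutationTest(D, labels, nPerm = 300, seed = 5)
  r2 <- groupPermutationTest(D, labels, nPerm = 300, seed = 5)
  expect_identical(resultTable(r1), resultTable(r2))
  p <- resultTable(r1)$p
  expect_true(all(p >= 0 & p <= 1))
  ## doubling permutations moves p by no more than Monte-Carlo error
  r4 <- groupPermutationTest(D, labels, nPerm = 600, seed = 9)
  mc <- sqrt(p * (1 - p) / 300)
  expect_true(mean(abs(resultTable(r4)$p - p) <= 4 * mc + 0.02) > 0.9)
})

test_that("correlation test recovers perfect and null couplings", {
  set.seed(45)
  D <- matrix(rnorm(30 * 12), 30, 12)
  res <- correlationPermutationTest(D, D[, 4], nPerm = 500)
  tb <- resultTable(res)
  expect_equal(tb$statistic[4], 1, tolerance = 1e-10)
  expect_lt(tb$p[4], 1e-6)
  expect_true(tb$significant[4])

  y <- residuals(lm(rnorm(30) ~ D[, 2]))      # exactly orthogonal to parcel 2
  res0 <- correlationPermutationTest(D, y, nPerm = 500)
  tb0 <- resultTable(res0)
  expect_equal(tb0$statistic[2], 0, tolerance = 1e-10)
  expect_equal(tb0$z[2], 0, tolerance = 1e-10)
  expect_equal(tb0$p[2], 1, tolerance = 1e-10)

  expect_error(correlationPermutationTest(D, rep(1, 30), nPerm = 200),
               "zero variance")
})

test_that("z-based p agrees in ordering with the direct permutation tail", {
  set.seed(46)
  n <- 30
  D <- matrix(rnorm(n * 60), n, 60)
  y <- rnorm(n) + 0.5 * D[, 1] + 0.3 * D[, 2]
  res <- correlationPermutationTest(D, y, nPerm = 800, seed = 11)
  zP <- resultTable(res)$p
  ## independent tail computation with plain loops
  r <- apply(D, 2, function(col) cor(col, y))
  set.seed(99)
  nullR <- replicate(800, apply(D, 2, function(col) cor(col, sample(y))))
  tailP <- vapply(seq_len(60), function(j) mean(abs(nullR[j, ]) >= abs(r[j])),
                  numeric(1))
  expect_gt(cor(rank(zP), rank(tailP), method = "spearman"), 0.95)
})
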