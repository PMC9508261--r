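test_that("proportional thresholding keeps the strongest edges with the floor rule", {
  w <- fourParcelMatrix()
  expect_equal(connWeights(proportionalThreshold(w, 1.0)), w)

  half <- connWeights(proportionalThreshold(w, 0.5))      # top 3 of 6 edges
  kept <- which(half[upper.tri(half)] > 0)
  expect_equal(sum(half > 0) / 2, 3)
  expect_equal(half[1, 2], 0.9); expect_equal(half[1, 3], 0.8)
  expect_equal(half[1, 4], 0.7); expect_equal(half[2, 3], 0)

  tiny <- connWeights(proportionalThreshold(w, 0.1))      # floor(0.6)=0 -> keep 1
  expect_equal(sum(tiny > 0) / 2, 1)
  expect_equal(tiny[1, 2], 0.9)

  expect_warning(proportionalThreshold(matrix(0, 3, 3), 0.5), "all-zero")
  expect_error(proportionalThreshold(w, 0), "density")
})

test_that("ties are broken deterministically by index order", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[1, 3] <- w[2, 4] <- 0.5
  w <- w + t(w)
  kept <- connWeights(proportionalThreshold(w, 2 / 6))    # m = 2 of 3 tied edges
  expect_equal(kept[1, 2], 0.5)
  expect_equal(kept[1, 3], 0.5)
  expect_equal(kept[2, 4], 0)
})

test_that("weighted degree is the row sum of edge weights", {
  w2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(weightedDegree(w2), c(0.5, 0.5))
  expect_equal(weightedDegree(matrix(0, 3, 3)), rep(0, 3))
  w3 <- matrix(0, 3, 3)
  w3[1, 2] <- 0.2; w3[1, 3] <- 0.3; w3[2, 3] <- 0.4
  expect_equal(weightedDegree(w3 + t(w3)), c(0.5, 0.6, 0.7))
})

test_that("composite degree reproduces the hand-computed 4-parcel case", {
  w <- fourParcelMatrix()
  expect_equal(compositeDegree(w, sweep = 1.0), weightedDegree(w))
  expect_equal(unname(compositeDegree(w, sweep = c(0.5, 1.0))),
               c(4.8, 2.3, 2.0, 1.7))
})

test_that("an edge surviving every density contributes once per density", {
  set.seed(31)
  w <- randomConnMatrix(8)
  w[1, 2] <- w[2, 1] <- 10           # always in the top edges
  sweep <- densitySweep()
  contrib <- sum(sapply(sweep, function(d)
    connWeights(proportionalThreshold(w, d))[1, 2]))
  expect_equal(contrib, length(sweep) * 10)
})

test_that("degree is monotone in density (nested edge sets)", {
  set.seed(32)
  for (i in 1:10) {
    w <- randomConnMatrix(7)
    ks <- sapply(c(0.2, 0.5, 0.8, 1.0), function(d)
      weightedDegree(proportionalThreshold(w, d)))
    expect_true(all(diff(t(ks)) >= -1e-12))
  }
})

test_that("composite degree matches the brute-force edge-enumeration oracle", {
  set.seed(33)
  for (i in 1:50) {
    n <- sample(3:6, 1)
    w <- randomConnMatrix(n)
    sweep <- sort(runif(sample(1:4, 1)))
    expect_equal(unname(compositeDegree(w, sweep)),
                 bruteCompositeDegree(w, sweep), tolerance = 1e-12)
  }
})

test_that("within + between equals total for all inputs", {
  set.seed(34)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    w <- randomConnMatrix(n)
    parc <- Parcellation(network = sample(c("A", "B", "C"), n, replace = TRUE))
    pd <- partitionDegree(w, parc)
    expect_equal(pd$within + pd$between, pd$total, tolerance = 1e-12)
    expect_equal(unname(pd$total), unname(compositeDegree(w)), tolerance = 1e-12)
  }
})

test_that("degenerate partitions behave as forced", {
  w <- fourParcelMatrix()
  one <- partitionDegree(w, Parcellation(network = rep("A", 4)), sweep = 1.0)
  expect_equal(one$between, rep(0, 4))
  expect_equal(one$within, one$total)

  ab <- partitionDegree(w, smallParcellation(), sweep = 1.0)
  expect_equal(unname(ab$within[1]), 0.9)
  expect_equal(unname(ab$between[1]), 1.5)
  expect_equal(unname(ab$total[1]), 2.4)

  solo <- partitionDegree(w, Parcellation(network = c("A", "B", "C", "D")),
                          sweep = 1.0)
  expect_equal(solo$within, rep(0, 4))
  expect_error(partitionDegree(w, Parcellation(network = c("A", "B"))),
               "match")
})

test_that("relabeling parcels permutes degree identically", {
  set.seed(35)
  w <- randomConnMatrix(6)
  perm <- sample(6)
  k <- compositeDegree(w)
  kp <- compositeDegree(w[perm, perm])
  expect_equal(unname(kp), unname(k[perm]))
})
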