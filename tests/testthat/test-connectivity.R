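test_that("framewise displacement follows the 50 mm arc-length convention", {
  T <- 10
  still <- matrix(0, T, 6)
  expect_equal(framewiseDisplacement(still), rep(0, T))

  trans <- still
  trans[5:T, 4] <- 0.1                      # one 0.1 mm translation step
  fd <- framewiseDisplacement(trans)
  expect_equal(fd[5], 0.1)
  expect_equal(fd[-5], rep(0, T - 1))

  rot <- still
  rot[5:T, 2] <- 0.002                      # 0.002 rad -> 50 * 0.002 = 0.1 mm
  expect_equal(framewiseDisplacement(rot)[5], 0.1)

  expect_equal(framewiseDisplacement(trans)[1], 0)   # first volume defined 0
  expect_error(framewiseDisplacement(matrix(0, 5, 5)), "6 columns")
})

test_that("motion QC applies the 0.25 mm exclusion and 0.5 mm scrub rules", {
  q <- motionQC(c(0, 0.1, 0.1))
  expect_true(q$include)
  expect_equal(q$scrubbedFraction, 0)

  q <- motionQC(c(0, 0.6, 0.1))
  expect_true(q$include)                    # mean 0.233 <= 0.25
  expect_equal(which(!q$keepMask), 2L)

  q <- motionQC(rep(0.3, 20))
  expect_false(q$include)
})

test_that("confound regression projects out matching signals", {
  set.seed(2)
  T <- 200
  x <- matrix(rnorm(T * 3), T, 3)
  cleaned <- cleanTimeSeries(x, tr = 3, confounds = x[, 1])
  expect_lt(max(abs(cleaned[30:170, 1])), 1e-8)

  const <- matrix(5, T, 2)
  out <- cleanTimeSeries(const, tr = 3)
  expect_lt(max(abs(out)), 1e-8)
  expect_lt(max(abs(colMeans(cleanTimeSeries(x, tr = 3)))), 1e-6)
})

test_that("the band-pass keeps 0.05 Hz and suppresses 0.005 Hz at TR = 3 s", {
  T <- 1500; tr <- 3
  tt <- seq(0, by = tr, length.out = T)
  core <- 300:1200
  inband <- cleanTimeSeries(cbind(sin(2 * pi * 0.05 * tt)), tr = tr)
  expect_gte(max(abs(inband[core])) / 1, 0.9)
  slow <- cleanTimeSeries(cbind(sin(2 * pi * 0.005 * tt)), tr = tr)
  expect_lte(max(abs(slow[core])) / 1, 0.1)
})

test_that("cleaning validates the band and drops collinear confounds", {
  x <- matrix(rnorm(100), 50, 2)
  expect_error(cleanTimeSeries(x, tr = 3, bandHigh = 0.2), "Nyquist")
  conf <- cbind(rnorm(50), rnorm(50))
  conf <- cbind(conf, conf[, 1] + conf[, 2])
  expect_warning(cleanTimeSeries(x, tr = 3, confounds = conf), "collinear")
})

test_that("connectivity applies Fisher z and removes negative correlations", {
  ts <- exactCorrSeries(0.5)
  C <- connectivityMatrix(ts)
  expect_equal(connWeights(C)[1, 2], atanh(0.5), tolerance = 1e-10)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)

  orth <- exactCorrSeries(0)
  expect_equal(connWeights(connectivityMatrix(orth))[1, 2], 0)

  anti <- exactCorrSeries(-1)[, 1:2]
  anti[, 2] <- -anti[, 1]
  expect_equal(connWeights(connectivityMatrix(anti))[1, 2], 0)
})

test_that("zero-variance parcels get zero edges with a warning", {
  set.seed(5)
  ts <- cbind(rnorm(40), rnorm(40), 0)
  expect_warning(C <- connectivityMatrix(ts), "zero-variance")
  expect_equal(connWeights(C)[3, ], rep(0, 3))
})

test_that("scrubbed volumes do not influence the matrix", {
  set.seed(6)
  ts <- matrix(rnorm(200), 50, 4)
  mask <- rep(TRUE, 50); mask[17] <- FALSE
  base <- connectivityMatrix(ts, keepMask = mask)
  spiked <- ts; spiked[17, ] <- 1e3
  expect_equal(connWeights(connectivityMatrix(spiked, keepMask = mask)),
               connWeights(base))
  expect_error(connectivityMatrix(ts[1:12, ], keepMask = c(rep(TRUE, 8), rep(FALSE, 4))),
               "fewer than 10")
})

test_that("connectivity matrices are symmetric, nonnegative, zero-diagonal", {
  set.seed(7)
  for (i in 1:20) {
    ts <- matrix(rnorm(30 * 6), 30, 6)
    w <- connWeights(connectivityMatrix(ts))
    expect_true(all(w >= 0))
    expect_equal(w, t(w))
    expect_equal(diag(w), rep(0, 6))
  }
})

test_that("Fisher z preserves the ordering of nonnegative correlations", {
  r <- sort(runif(20))
  expect_true(all(diff(atanh(r)) > 0))
  ## saturated correlations stay finite through the clip
  ts <- cbind(1:20 + rnorm(20, sd = 1e-9), 1:20)
  expect_true(all(is.finite(connWeights(connectivityMatrix(ts)))))
})
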