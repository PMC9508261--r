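test_that("subject simulation is deterministic for (model, group, seed)", {
  m <- smallModel()
  a <- simulateSubject(m, "patient", seed = 5L)
  b <- simulateSubject(m, "patient", seed = 5L)
  expect_identical(a, b)
  c <- simulateSubject(m, "patient", seed = 6L)
  expect_false(identical(a$ts, c$ts))
})

test_that("independent parcels show near-zero sample correlations", {
  m <- cohortModel(nParcels = 5L, networkSizes = c(A = 3L, B = 2L),
                   rhoWithin = 0, rhoBetween = 0, rhoHub = 0,
                   hubNodes = integer(0), couplingNodes = integer(0), beta = 0,
                   groupSizes = c(control = 2L, patient = 2L),
                   nVolumes = 5000L)
  s <- simulateSubject(m, "control", seed = 11L)
  r <- cor(s$ts)
  expect_lt(max(abs(r[upper.tri(r)])), 3 / sqrt(5000))
})

test_that("realized correlations converge to the block covariance", {
  m <- cohortModel(nParcels = 20L, networkSizes = c(A = 10L, B = 10L),
                   rhoWithin = 0.5, rhoBetween = 0.1, rhoHub = 0,
                   hubNodes = integer(0), couplingNodes = integer(0), beta = 0,
                   groupSizes = c(control = 2L, patient = 2L),
                   nVolumes = 5000L)
  s <- simulateSubject(m, "control", seed = 21L)
  r <- cor(s$ts)
  blk <- rep(c("A", "B"), each = 10)
  same <- outer(blk, blk, "==") & upper.tri(r)
  diff <- outer(blk, blk, "!=") & upper.tri(r)
  expect_lt(abs(mean(r[same]) - 0.5), 0.05)
  expect_lt(abs(mean(r[diff]) - 0.1), 0.05)
})

test_that("PSD repair clips negative eigenvalues and preserves symmetry", {
  S <- matrix(0.9, 3, 3); diag(S) <- 1
  S[1, 2] <- S[2, 1] <- -0.9          # indefinite triple
  R <- repairPSD(S)
  expect_gte(min(eigen(R, symmetric = TRUE)$values), 0)
  expect_equal(R, t(R))
  ok <- diag(3)
  expect_equal(repairPSD(ok), ok)     # PSD inputs pass through
})

test_that("zero spike rate keeps all framewise displacements below threshold", {
  m <- smallModel(spikeRate = 0)
  s <- simulateSubject(m, "control", seed = 9L)
  fd <- framewiseDisplacement(s$motion)
  expect_true(all(fd <= 0.5))
})

test_that("boosted hub correlations raise expected hub degree in the boosted group", {
  m <- cohortModel(nParcels = 30L, networkSizes = c(A = 10L, B = 10L, C = 10L),
                   hubNodes = 1:3, groupDelta = -0.12,
                   couplingNodes = integer(0), beta = 0,
                   groupSizes = c(control = 15L, patient = 15L),
                   nVolumes = 150L)
  kc <- kp <- matrix(NA_real_, 3, 15)
  for (i in 1:15) {
    sc <- simulateSubject(m, "control", seed = childSeed(100L, i))
    sp <- simulateSubject(m, "patient", seed = childSeed(200L, i))
    kc[, i] <- compositeDegree(connectivityMatrix(sc$ts))[1:3]
    kp[, i] <- compositeDegree(connectivityMatrix(sp$ts))[1:3]
  }
  expect_gt(mean(kc), mean(kp))
})

test_that("behavior is exactly linear in coupled degree when noise-free", {
  m <- smallModel(beta = 1, sigmaY = 0,
                  behavior = list(accIntercept = 50, accGroupOffset = 0))
  deg <- matrix(rnorm(24 * 20, sd = 2), 24, 20)
  beh <- attachBehavior(deg, m, group = rep("control", 20), seed = 4L)
  kbar <- colMeans(deg[1:2, ])
  expect_equal(cor(beh$acc_combined, kbar), 1, tolerance = 1e-12)
})

test_that("uncoupled behavior is independent of degree", {
  m <- smallModel(beta = 0, sigmaY = 5)
  deg <- matrix(rnorm(24 * 400), 24, 400)
  beh <- attachBehavior(deg, m, group = rep("control", 400), seed = 8L)
  expect_lt(abs(cor(beh$acc_combined, colMeans(deg[1:2, ]))), 0.15)
})

test_that("coupling at true R^2 = 0.25 yields sample r in [0.3, 0.7] almost always", {
  ## two iid N(0,1) coupling nodes: var(mean) = 1/2, so sigmaY = sqrt(3/2)
  ## gives R^2 = (1/2) / (1/2 + 3/2) = 0.25
  m <- smallModel(beta = 1, sigmaY = sqrt(1.5),
                  behavior = list(accIntercept = 50, accGroupOffset = 0))
  set.seed(301)
  hits <- vapply(1:200, function(rep) {
    deg <- matrix(rnorm(24 * 60), 24, 60)
    beh <- attachBehavior(deg, m, group = rep("control", 60),
                          seed = childSeed(300L, rep))
    r <- cor(beh$acc_combined, colMeans(deg[1:2, ]))
    r >= 0.3 && r <= 0.7
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a nonzero coupling slope requires coupling nodes", {
  expect_error(smallModel(couplingNodes = integer(0), beta = 1),
               "coupling set")
})

test_that("cohort simulation is deterministic and internally consistent", {
  m <- smallModel(groupSizes = c(control = 3L, patient = 3L), nVolumes = 60L)
  a <- simulateCohort(m, seed = 13L)
  b <- simulateCohort(m, seed = 13L)
  expect_identical(a$degrees, b$degrees)
  expect_identical(a$behavior, b$behavior)
  expect_equal(ncol(a$degrees), 6L)
  expect_equal(a$behavior$group, rep(c("control", "patient"), each = 3))
  expect_true(all(a$behavior$acc_combined >= 0 & a$behavior$acc_combined <= 100))
  expect_true(all(a$behavior$rt_combined > 0))
})
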