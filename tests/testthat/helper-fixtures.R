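## shared fixtures: tiny matrices and small cohort models built in code

## 4-parcel matrix with distinct edge weights; all hand computations in the
## degree tests refer to this graph
fourParcelMatrix <- function() {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[1, 3] <- 0.8; w[1, 4] <- 0.7
  w[2, 3] <- 0.3; w[2, 4] <- 0.2; w[3, 4] <- 0.1
  w + t(w)
}

## random symmetric nonnegative zero-diagonal matrix
randomConnMatrix <- function(n, rng = NULL) {
  w <- matrix(0, n, n)
  w[upper.tri(w)] <- runif(n * (n - 1) / 2)
  w + t(w)
}

smallParcellation <- function(n = 4, networks = c("A", "A", "B", "B")) {
  Parcellation(network = networks[seq_len(n)])
}

smallModel <- function(...) {
  args <- list(nParcels = 24L, networkSizes = c(A = 8L, B = 8L, C = 8L),
               hubNodes = 1:3, couplingNodes = 1:2,
               groupSizes = c(control = 7L, patient = 7L), nVolumes = 80L)
  args[names(list(...))] <- list(...)
  do.call(cohortModel, args)
}

## time series with an exact sample correlation r between columns 1 and 2
exactCorrSeries <- function(r, T = 64) {
  u <- sin(2 * pi * seq_len(T) / T)
  v <- cos(2 * pi * seq_len(T) / T)
  u <- (u - mean(u)) / sd(u)
  v <- residuals(lm(v ~ u))
  v <- (v - mean(v)) / sd(v)
  cbind(a = u, b = r * u + sqrt(1 - r^2) * v)
}
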