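## independent brute-force oracles, deliberately written as plain loops so
## they share no code with the package implementations

## composite weighted degree by explicit edge enumeration and sorting
bruteCompositeDegree <- function(w, sweep) {
  n <- nrow(w)
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    edges <- rbind(edges, c(i, j, w[i, j]))
  ord <- order(-edges[, 3], edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  k <- numeric(n)
  for (d in sweep) {
    m <- max(1, floor(d * nrow(edges)))
    for (e in seq_len(m)) {
      i <- edges[e, 1]; j <- edges[e, 2]; val <- edges[e, 3]
      k[i] <- k[i] + val
      k[j] <- k[j] + val
    }
  }
  k
}

## Benjamini-Hochberg step-up by direct definition
bruteBH <- function(p, alpha) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord]
  reject_upto <- 0
  for (i in seq_len(m)) if (ranked[i] <= i * alpha / m) reject_upto <- i
  reject <- logical(m)
  if (reject_upto > 0) reject[ord[seq_len(reject_upto)]] <- TRUE
  q_sorted <- numeric(m)
  running <- 1
  for (i in m:1) {
    running <- min(running, m * ranked[i] / i)
    q_sorted[i] <- running
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  list(q = q, reject = reject)
}
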