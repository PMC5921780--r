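# Shared fixtures: tiny hand-built metapopulations and desk-scale configs.

# Metapopulation from an explicit count matrix (bypasses the trMVN pipeline).
makeMetapop <- function(counts, k = 0L, q = 0, fixedEnv = NULL) {
  counts <- as.matrix(counts)
  N <- nrow(counts)
  g <- ncol(counts)
  M <- sum(counts[1L, ])
  nd <- 2L^k
  if (is.null(fixedEnv))
    fixedEnv <- matrix(rep(1 / g, nd * g), nrow = nd)
  new("Metapopulation", counts = counts,
      demeId = rep(seq_len(nd), each = N %/% nd),
      ageSteps = rep(0L, N), fixedEnv = fixedEnv, k = as.integer(k),
      M = as.numeric(M), q = as.numeric(q),
      taxa = sprintf("taxon_%03d", seq_len(g)))
}

# Random equal-size host count matrix for property tests.
randomCounts <- function(n, g, M) {
  t(vapply(seq_len(n), function(i) {
    w <- runif(g)
    drop(rmultinom(1L, size = M, prob = w / sum(w)))
  }, numeric(g)))
}

deskConfig <- function(...) {
  args <- list(...)
  base <- list(N = 64, M = 1e4, g = 30, recordEvery = 64)
  base[names(args)] <- args
  do.call(simConfig, base)
}

# State wrapper for engine tests.
makeState <- function(metapop, x = 0.5, y = 0.5) {
  a <- solveAcquisition(x)
  t <- envPerStep(a, metapop@M, nrow(metapop@counts))
  new("SimulationState", step = 0L, metapop = metapop,
      params = list(x = x, a = a, t = t, y = y, q = metapop@q,
                    N = nrow(metapop@counts), M = metapop@M,
                    g = ncol(metapop@counts), k = metapop@k,
                    shannonBase = exp(1), pairCap = 1e5),
      mixedEnv = matrix(0, nrow = 2L^metapop@k, ncol = ncol(metapop@counts)))
}
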