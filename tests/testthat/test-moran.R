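test_that("birth-death events conserve population and capacity", {
  set.seed(60)
  counts <- randomCounts(16, 5, 200)
  st <- makeState(makeMetapop(counts, k = 1), x = 0.5, y = 0.5)
  ev <- moranEvent(st)
  mp <- simMetapop(ev$state)
  expect_identical(nHosts(mp), 16L)
  expect_true(all(rowSums(hostCounts(mp)) == 200))
  expect_identical(hostAges(mp)[ev$newborn], 0L)

  # monomorphic parents breed monomorphic offspring
  mono <- matrix(0, 8, 3); mono[, 2] <- 100
  stm <- makeState(makeMetapop(mono), x = 1, y = 0)
  evm <- moranEvent(stm)
  expect_identical(hostCounts(simMetapop(evm$state))[evm$newborn, ],
                   c(0, 100, 0), ignore_attr = TRUE)
})

test_that("offspring composition is multinomial around the parent's", {
  set.seed(61)
  c0 <- c(0.3, 0.2, 0.5)
  M <- 1000
  counts <- matrix(rep(c0 * M, 2), 2, byrow = TRUE)  # both hosts identical
  st <- makeState(makeMetapop(counts), x = 1, y = 0)
  reps <- t(vapply(1:4000, function(i) {
    ev <- moranEvent(st)
    hostCounts(simMetapop(ev$state))[ev$newborn, ] / M
  }, numeric(3)))
  se <- sqrt(c0 * (1 - c0) / (M * 4000))
  expect_true(all(abs(colMeans(reps) - c0) <= 3 * se))
})

test_that("environmental acquisition blends self and environment as M:t", {
  set.seed(62)
  M <- 1000
  # t = 0: pure self-resampling, support can only shrink
  host <- c(600, 0, 400)
  for (i in 1:50) {
    new <- acquireFromEnvironment(host, c(0, 1, 0), t = 0, M = M)
    expect_identical(sum(new), 1000L)
    expect_identical(new[2], 0L)
  }

  # t = M: expected composition is the midpoint of self and environment
  draws <- t(vapply(1:4000, function(i)
    acquireFromEnvironment(c(M, 0), c(0, 1), t = M, M = M) / M, numeric(2)))
  se <- sqrt(0.25 / (M * 4000))
  expect_lt(abs(mean(draws[, 1]) - 0.5), 3 * se)

  # e equal to the host's own composition is a fixed point in expectation
  h <- c(300, 700)
  d2 <- t(vapply(1:4000, function(i)
    acquireFromEnvironment(h, h / M, t = 250, M = M) / M, numeric(2)))
  se2 <- sqrt(0.3 * 0.7 / (M * 4000))
  expect_lt(abs(mean(d2[, 1]) - 0.3), 3 * se2)
})

test_that("advancing steps conserves N and M and respects the vertical limit", {
  set.seed(63)
  counts <- randomCounts(16, 6, 500)
  st <- makeState(makeMetapop(counts, k = 1, q = 0.2), x = 0.8, y = 0.5)
  for (i in 1:10) st <- advanceStep(st)
  mp <- simMetapop(st)
  expect_identical(simStep(st), 10L)
  expect_identical(nHosts(mp), 16L)
  expect_true(all(rowSums(hostCounts(mp)) == 500))

  # x = 1 (t = 0): taxa can be lost, never gained -> population support shrinks
  stv <- makeState(makeMetapop(counts, k = 0, q = 0), x = 1, y = 0.5)
  support <- function(s) colSums(hostCounts(simMetapop(s))) > 0
  s0 <- support(stv)
  for (i in 1:20) {
    stv <- advanceStep(stv)
    s1 <- support(stv)
    expect_true(all(s0 | !s1))  # s1 subset of s0
    s0 <- s1
  }
})

test_that("per-host richness never grows under pure vertical transmission", {
  set.seed(64)
  counts <- randomCounts(8, 10, 300)
  st <- makeState(makeMetapop(counts), x = 1, y = 0)
  for (i in 1:15) {
    prev <- hostCounts(simMetapop(st))
    st <- advanceStep(st)
    cur <- hostCounts(simMetapop(st))
    ages <- hostAges(simMetapop(st))
    # survivors resample themselves: support (hence richness) cannot grow
    for (h in which(ages > 0))
      expect_true(all(prev[h, ] > 0 | cur[h, ] == 0))
  }
})

test_that("a generation run records on schedule and is seed-deterministic", {
  cfg <- simConfig(N = 16, M = 500, g = 10, x = 0.7, y = 0.5, k = 0,
                   recordEvery = 1)
  res <- runGeneration(cfg, seed = 70)
  rec <- traceRecords(res$trace)
  expect_identical(nrow(rec), 17L)
  expect_identical(rec$step, 0:16)
  expect_true(all(is.na(rec$beta_b)))
  expect_true(all(is.na(rec$gamma_w)))

  res2 <- runGeneration(cfg, seed = 70)
  expect_identical(traceRecords(res$trace), traceRecords(res2$trace))
  expect_identical(hostCounts(simMetapop(res$state)),
                   hostCounts(simMetapop(res2$state)))
})

test_that("high parental inheritance preserves more between-host difference than high environmental", {
  finals <- sapply(c(0.1, 0.9), function(x) {
    res <- sapply(1:8, function(s) {
      rec <- traceRecords(runGeneration(deskConfig(x = x, y = 0.5), s)$trace)
      c(alpha = rec$alpha[nrow(rec)], beta = rec$beta[nrow(rec)])
    })
    rowMeans(res)
  })
  expect_lt(finals["alpha", 2], finals["alpha", 1])  # MA90 alpha below MA10
  expect_gt(finals["beta", 2], finals["beta", 1])    # MA90 beta above MA10
})

test_that("pure vertical transmission erodes within-host diversity", {
  drops <- vapply(1:10, function(s) {
    rec <- traceRecords(runGeneration(deskConfig(x = 1, y = 0.5), s)$trace)
    rec$alpha[nrow(rec)] < rec$alpha[1]
  }, logical(1))
  expect_gt(sum(drops), 8)  # sign test: 9+/10 at p < 0.05
})

test_that("a dominant fixed environment homogenizes hosts", {
  # x small, y = 0: host compositions converge to the deme's fixed profile
  drops <- vapply(1:10, function(s) {
    rec <- traceRecords(runGeneration(deskConfig(x = 0.05, y = 0), s)$trace)
    rec$beta[nrow(rec)] < rec$beta[1]
  }, logical(1))
  expect_true(all(drops))
})
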