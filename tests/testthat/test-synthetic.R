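test_that("baseline table is a long-tailed, normalized, reproducible community", {
  tab <- generateBaselineTable(g = 129, nSamples = 100, seed = 1)
  expect_identical(dim(tab), c(100L, 129L))
  expect_equal(rowSums(tab), rep(1, 100), ignore_attr = TRUE)
  # long tail: dominant taxon orders of magnitude above the rarest
  cm <- colMeans(tab)
  expect_gt(cm[1] / cm[129], 100)
  expect_gt(sum(cm > 0.01), 2)          # a few dominant taxa
  expect_gt(sum(cm < 1e-3), 50)         # many rare ones

  tiny <- generateBaselineTable(g = 2, nSamples = 2, seed = 1)
  expect_identical(dim(tiny), c(2L, 2L))
  expect_equal(rowSums(tiny), rep(1, 2), ignore_attr = TRUE)

  expect_identical(generateBaselineTable(30, 10, seed = 7),
                   generateBaselineTable(30, 10, seed = 7))
  expect_error(generateBaselineTable(g = 1, nSamples = 10), "g must be")
  expect_error(generateBaselineTable(g = 5, nSamples = 1), "nSamples")
})

test_that("trMVN fit recovers moments of the table", {
  r <- c(0.2, 0.3, 0.5)
  same <- rbind(r, r, r)
  m <- fitTrMVN(same)
  expect_equal(modelMean(m), r, ignore_attr = TRUE)
  expect_lt(max(abs(modelCov(m))), 1e-9)   # zero variance + tiny ridge

  two <- rbind(c(1, 0), c(0, 1))
  expect_equal(modelMean(fitTrMVN(two)), c(0.5, 0.5), ignore_attr = TRUE)

  expect_error(fitTrMVN(matrix(r, nrow = 1)), "insufficient|>= 2")
  expect_error(fitTrMVN(rbind(c(0.5, 0.4), c(0.5, 0.5))), "sum to 1")
})

test_that("fit round-trips a hand-constructed clamped MVN sample", {
  set.seed(31)
  mu <- c(0.5, 0.3, 0.15, 0.05)
  Sigma <- diag(c(0.02, 0.01, 0.005, 0.002))
  raw <- MASS::mvrnorm(1000, mu, Sigma)
  raw[raw < 0] <- 0
  tab <- raw / rowSums(raw)
  fitted <- fitTrMVN(tab)
  se <- apply(tab, 2, sd) / sqrt(nrow(tab))
  expect_true(all(abs(modelMean(fitted) - colMeans(tab)) <= 3 * se + 1e-12))
  ev <- eigen(modelCov(fitted), only.values = TRUE)$values
  expect_true(all(ev >= -1e-9))
})

test_that("trMVN sampling clamps, rescales, and degenerates correctly", {
  # zero covariance: every draw is the (valid) mean
  m <- TrMVNModel(c(0.25, 0.75), matrix(0, 2, 2))
  draws <- sampleTrMVN(m, 5, seed = 1)
  expect_equal(draws, matrix(rep(c(0.25, 0.75), each = 5), 5, 2),
               ignore_attr = TRUE)

  # negative mean entry with zero covariance: clamp then renormalize
  m2 <- TrMVNModel(c(0.5, 0.6, -0.1), matrix(0, 3, 3))
  d2 <- sampleTrMVN(m2, 3, seed = 1)
  expect_equal(d2[1, ], c(0.5, 0.6, 0) / 1.1, ignore_attr = TRUE)

  # contract on a dispersed model
  m3 <- fitTrMVN(generateBaselineTable(20, 50, seed = 3))
  d3 <- sampleTrMVN(m3, 200, seed = 4)
  expect_true(all(d3 >= 0))
  expect_equal(rowSums(d3), rep(1, 200), ignore_attr = TRUE)
  expect_identical(sampleTrMVN(m3, 10, seed = 5), sampleTrMVN(m3, 10, seed = 5))

  # all-mass-negative mean cannot yield a valid draw
  bad <- TrMVNModel(c(-1, -1), matrix(0, 2, 2))
  expect_error(sampleTrMVN(bad, 1, seed = 1, retryCap = 5), "degenerate")
})

test_that("deme tree bifurcates into 2^k leaves and diverges across siblings", {
  root <- fitTrMVN(generateBaselineTable(30, 100, seed = 10))
  t0 <- buildDemeTree(root, k = 0)
  expect_identical(treeLevels(t0), 0L)
  expect_length(leafModels(t0), 1L)
  expect_identical(modelMean(leafModels(t0)[[1]]), modelMean(root))

  t2 <- buildDemeTree(root, k = 2, seed = 2)
  expect_length(leafModels(t2), 4L)
  expect_error(buildDemeTree(root, k = -1), "k must be")

  # siblings' means (independent parent draws, compounded truncation) spread
  # at least as much as two draws within one leaf
  set.seed(12)
  sib <- numeric(0); win <- numeric(0)
  for (i in 1:100) {
    tr <- buildDemeTree(root, k = 2)
    lm_ <- leafModels(tr)
    sib <- c(sib,
             sqrt(sum((modelMean(lm_[[1]]) - modelMean(lm_[[2]]))^2)),
             sqrt(sum((modelMean(lm_[[3]]) - modelMean(lm_[[4]]))^2)))
    d <- sampleTrMVN(lm_[[1]], 2)
    win <- c(win, sqrt(sum((d[1, ] - d[2, ])^2)))
  }
  expect_gt(mean(sib), mean(win))
})

test_that("metapopulation initialization conserves sizes and hits leaf means", {
  root <- fitTrMVN(generateBaselineTable(10, 50, seed = 20))
  tree <- buildDemeTree(root, k = 2, seed = 21)
  common <- modelMean(root) / sum(modelMean(root))
  mp <- initMetapopulation(tree, common, N = 64, M = 1e3, seed = 22)
  expect_identical(nHosts(mp), 64L)
  expect_identical(nDemes(mp), 4L)
  expect_identical(as.integer(table(demeAssignment(mp))), rep(16L, 4))
  expect_true(all(rowSums(hostCounts(mp)) == 1e3))

  expect_error(initMetapopulation(tree, common, N = 63, M = 1e3),
               "divisible")

  # zero-covariance leaves: host compositions are multinomial around the leaf mean
  zero <- TrMVNModel(common, matrix(0, 10, 10))
  tz <- new("DemeTree", levels = 0L, rootModel = zero, leafModels = list(zero))
  mpz <- initMetapopulation(tz, common, N = 1000, M = 1e3, seed = 23)
  est <- colMeans(hostCounts(mpz)) / 1e3
  se <- sqrt(common * (1 - common) / (1000 * 1e3))
  expect_true(all(abs(est - common) <= 3 * se + 1e-9))

  # single-deme fixed environment equals the common profile
  expect_equal(fixedEnvironments(mpz)[1, ], common, ignore_attr = TRUE)
})

test_that("KS validation separates faithful from shifted resamples", {
  # mild-truncation regime (negatives ~5 sd away): fit + resample is
  # distribution-faithful, which is what the validation is meant to certify
  p0 <- 0.7^(1:10); p0 <- p0 / sum(p0)
  seedModel <- TrMVNModel(p0, diag((0.2 * p0)^2))
  tab <- sampleTrMVN(seedModel, 500, seed = 30)
  model <- fitTrMVN(tab)
  res <- sampleTrMVN(model, 500, seed = 31)

  self <- ksValidate(tab, tab)
  expect_true(all(self$taxon$statistic == 0))
  expect_identical(self$shannon$statistic, 0)

  faithful <- ksValidate(tab, res)
  expect_gt(median(faithful$taxon$p.value), 0.05)
  expect_gt(faithful$shannon$p.value, 0.01)

  # power check: shift taxon 1 by +0.5 and renormalize
  shifted <- modelMean(model); shifted[1] <- shifted[1] + 0.5
  mShift <- TrMVNModel(shifted / sum(shifted), modelCov(model))
  resShift <- sampleTrMVN(mShift, 500, seed = 32)
  expect_lt(ksValidate(tab, resShift)$taxon$p.value[1], 0.01)

  expect_error(ksValidate(tab, res[, 1:5]), "same taxa")
})

test_that("abundance-table TSV and deme-tree JSON round trips work", {
  tab <- generateBaselineTable(g = 8, nSamples = 5, seed = 40)
  f <- tempfile(fileext = ".tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, col.names = NA)
  back <- readAbundanceTable(f)
  expect_equal(unname(back), unname(tab))

  tree <- buildDemeTree(fitTrMVN(tab), k = 1, seed = 41)
  jf <- tempfile(fileext = ".json")
  writeDemeTree(tree, jf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$levels, 1L)
  expect_equal(unlist(parsed$root$mean), modelMean(fitTrMVN(tab)),
               ignore_attr = TRUE)
  expect_length(parsed$leaves, 2L)
})
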