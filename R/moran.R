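#' One Moran birth-death event
#'
#' Chooses one deme uniformly at random; within it, a reproducing host and a
#' dying host are chosen independently and uniformly (they may coincide). The
#' offspring's microbiome is a multinomial draw of M microbes from the
#' parent's relative composition; it replaces the dead host with age 0.
#'
#' @param state a [SimulationState-class].
#' @return list with `state` (updated state) and `newborn` (the replaced host
#'   slot index).
#' @export
moranEvent <- function(state) {
  mp <- state@metapop
  nd <- 2L^mp@k
  d <- if (nd == 1L) 1L else sample.int(nd, 1L)
  rows <- which(mp@demeId == d)
  parent <- rows[sample.int(length(rows), 1L)]
  dying <- rows[sample.int(length(rows), 1L)]
  prob <- mp@counts[parent, ] / mp@M
  mp@counts[dying, ] <- drop(rmultinom(1L, size = mp@M, prob = prob))
  mp@ageSteps[dying] <- 0L
  state@metapop <- mp
  list(state = state, newborn = dying)
}

#' Environmental acquisition for one host
#'
#' Replaces a host's microbiome by one multinomial draw of size M from the
#' blended weights (M c + t e) / (M + t), where c is the host's current
#' relative composition and e the deme's mixed environment. The retention
#' weight M/(M+t) is the per-step parental-origin retention ratio underlying
#' the generation-level parental fraction.
#'
#' @param counts the host's current count vector (sums to M).
#' @param e mixed environmental profile.
#' @param t per-step environmental acquisition count (real, >= 0).
#' @param M microbiome capacity.
#' @return new count vector summing to M.
#' @export
acquireFromEnvironment <- function(counts, e, t, M) {
  stopifnot(t >= 0, length(counts) == length(e))
  w <- (counts + t * e) / (M + t)
  drop(rmultinom(1L, size = M, prob = w))
}

#' Advance the simulation one Moran time step
#'
#' Ordered sub-steps: (1) recompute each deme's pooled and mixed environments
#' from the hosts' end-of-previous-step state; (2) one birth-death event in a
#' uniformly chosen deme; (3) every host except the step's newborn acquires t
#' microbes (in expectation) from its deme's mixed environment and ages one
#' step; (4) migration. Newborns skip acquisition in their birth step: a
#' newborn is 100 percent parental at age 0.
#'
#' @param state a [SimulationState-class].
#' @return the advanced state.
#' @export
advanceStep <- function(state) {
  p <- state@params
  env <- .mixedEnvironments(state@metapop, p$y)
  state@mixedEnv <- env
  ev <- moranEvent(state)
  state <- ev$state
  mp <- state@metapop
  M <- mp@M
  t <- p$t
  for (i in seq_len(nrow(mp@counts))) {
    if (i == ev$newborn) next
    if (t > 0)
      mp@counts[i, ] <- acquireFromEnvironment(mp@counts[i, ],
                                               env[mp@demeId[i], ], t, M)
    else
      mp@counts[i, ] <- drop(rmultinom(1L, size = M, prob = mp@counts[i, ] / M))
    mp@ageSteps[i] <- mp@ageSteps[i] + 1L
  }
  if (mp@q > 0) mp <- migrate(mp)
  state@metapop <- mp
  state@step <- state@step + 1L
  state
}

## Internal: one DiversityTrace row from the current metapopulation.
.diversityRow <- function(metapop, step, base = exp(1), pairCap = 1e5) {
  b <- betaDiversities(metapop@counts, metapop@demeId, pairCap = pairCap)
  structured <- 2L^metapop@k > 1L
  data.frame(step = step,
             alpha = alphaDiversity(metapop@counts, base = base),
             beta = b$beta,
             beta_b = if (structured) b$beta_b else NA_real_,
             beta_w = if (structured) b$beta_w else NA_real_,
             gamma = gammaDiversity(metapop@counts, base = base),
             gamma_w = if (structured)
               gammaWithin(metapop@counts, metapop@demeId, base = base)
             else NA_real_)
}

#' Run one host generation
#'
#' Initializes the community (baseline table, trMVN fit, deme tree,
#' metapopulation), then executes N Moran time steps, recording diversity at
#' step 0 and every `recordEvery` steps (the final step is always recorded).
#' Fully reproducible under a fixed seed.
#'
#' @param config a configuration list from [simConfig()].
#' @param seed root seed (integer).
#' @return list with `trace` (a [DiversityTrace-class]) and `state` (the
#'   final [SimulationState-class]).
#' @export
runGeneration <- function(config, seed) {
  config <- do.call(simConfig, config)
  set.seed(as.integer(seed))
  baseline <- generateBaselineTable(g = config$g, nSamples = config$nSamplesFit,
                                    abundanceRange = config$baselineRange,
                                    sdLog = config$baselineSdLog)
  model <- fitTrMVN(baseline)
  tree <- buildDemeTree(model, k = config$k, shrinkFactor = config$shrinkFactor)
  common <- .asProfile(colMeans(baseline))
  mp <- initMetapopulation(tree, common, N = config$N, M = config$M,
                           q = config$q, feSampleSize = config$feSampleSize)
  a <- solveAcquisition(config$x)
  t <- envPerStep(a, config$M, config$N)
  params <- list(x = config$x, a = a, t = t, y = config$y, q = config$q,
                 N = config$N, M = config$M, g = config$g, k = config$k,
                 shannonBase = config$shannonBase, pairCap = config$pairCap)
  state <- new("SimulationState", step = 0L, metapop = mp, params = params,
               mixedEnv = matrix(0, nrow = 2L^config$k, ncol = config$g))
  rows <- list(.diversityRow(mp, 0L, base = config$shannonBase,
                             pairCap = config$pairCap))
  for (s in seq_len(config$N)) {
    state <- advanceStep(state)
    if (s %% config$recordEvery == 0L || s == config$N)
      rows[[length(rows) + 1L]] <- .diversityRow(state@metapop, s,
                                                 base = config$shannonBase,
                                                 pairCap = config$pairCap)
  }
  rec <- do.call(rbind, rows)
  rec <- rec[!duplicated(rec$step), ]
  rownames(rec) <- NULL
  list(trace = new("DiversityTrace", records = rec), state = state)
}
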