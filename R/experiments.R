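#' Simulation configuration
#'
#' Builds and validates the configuration list consumed by [runGeneration()]
#' and the drivers. Defaults are the full-scale study conditions (N = 4096
#' hosts, M = 1e7 microbes per host, g = 129 genera); tests and examples use
#' desk-scale values (N = 64, M = 1e4, g = 30).
#'
#' @param N host population size (power of 2 required when k > 0).
#' @param M per-host microbiome capacity.
#' @param g number of taxa.
#' @param x expected parental fraction per generation, in (0, 1].
#' @param y pooled-environment weight, in [0, 1].
#' @param k deme tree levels (2^k demes), 0 <= k <= log2(N).
#' @param q host dispersal rate in [0, 1].
#' @param recordEvery record diversity every this many steps.
#' @param nSamplesFit baseline-table samples used to fit the trMVN.
#' @param feSampleSize multinomial sample size for deme fixed environments.
#' @param shrinkFactor covariance shrink per deme-tree level.
#' @param shannonBase logarithm base for Shannon indices.
#' @param pairCap exact-enumeration cap for pairwise beta diversity.
#' @param baselineRange rarest-to-dominant base abundance ratio of the
#'   synthetic baseline (see [generateBaselineTable()]).
#' @param baselineSdLog log-normal sample noise of the synthetic baseline.
#' @return validated named list.
#' @export
simConfig <- function(N = 4096, M = 1e7, g = 129, x = 0.5, y = 0.5,
                      k = 0, q = 0, recordEvery = max(1, N %/% 16),
                      nSamplesFit = 100, feSampleSize = 1e6,
                      shrinkFactor = 1, shannonBase = exp(1),
                      pairCap = 1e5, baselineRange = 1e-4, baselineSdLog = 1) {
  if (x <= 0 || x > 1) stop("x must be in (0, 1]", call. = FALSE)
  if (y < 0 || y > 1) stop("y must be in [0, 1]", call. = FALSE)
  if (q < 0 || q > 1) stop("q must be in [0, 1]", call. = FALSE)
  if (k < 0 || 2^k > N) stop("k must satisfy 0 <= k <= log2(N)", call. = FALSE)
  if (k > 0 && N %% 2^k != 0)
    stop("N must be divisible by 2^k", call. = FALSE)
  if (g < 2) stop("g must be >= 2", call. = FALSE)
  if (recordEvery < 1) stop("recordEvery must be >= 1", call. = FALSE)
  list(N = as.integer(N), M = M, g = as.integer(g), x = x, y = y,
       k = as.integer(k), q = q, recordEvery = as.integer(recordEvery),
       nSamplesFit = as.integer(nSamplesFit), feSampleSize = feSampleSize,
       shrinkFactor = shrinkFactor, shannonBase = shannonBase,
       pairCap = pairCap, baselineRange = baselineRange,
       baselineSdLog = baselineSdLog)
}

#' Read / write a simulation configuration
#'
#' YAML (or JSON, by extension) round trip of a [simConfig()] list.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return for `readConfig`, a validated configuration list.
#' @export
readConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(simConfig, raw)
}

#' @rdname readConfig
#' @param config configuration list.
#' @export
writeConfig <- function(config, path) {
  config <- do.call(simConfig, config)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Real time per Moran step
#'
#' Wall-clock duration of one Moran time step for a host species with the
#' given generation time: generation_years x 365.25 x 24 / N hours. For a
#' human generation of 30 years and N = 4096 steps this is about 64 h, i.e.
#' hosts exchange microbes with the environment roughly every two and a half
#' days.
#'
#' @param generationYears host generation time in years (> 0).
#' @param N steps per generation (>= 1).
#' @return list with `hours` (exact) and `rounded` (nearest hour).
#' @export
realTimePerStep <- function(generationYears, N) {
  stopifnot(generationYears > 0, N >= 1)
  hours <- generationYears * 365.25 * 24 / N
  list(hours = hours, rounded = round(hours))
}

#' Run seeded replicate generations
#'
#' Runs [runGeneration()] `nReps` times with replicate seeds derived from the
#' root seed and summarizes every diversity column per recorded step as
#' mean, sd and n across replicates.
#'
#' @param config configuration list ([simConfig()]).
#' @param nReps number of replicates (>= 1).
#' @param seed root seed.
#' @return list with `summary` (long data.frame: step, metric, mean, sd, n)
#'   and `traces` (list of [DiversityTrace-class]).
#' @export
runReplicates <- function(config, nReps, seed) {
  stopifnot(nReps >= 1)
  traces <- vector("list", nReps)
  for (r in seq_len(nReps))
    traces[[r]] <- runGeneration(config, seed = .childSeed(seed, r))$trace
  metrics <- c("alpha", "beta", "beta_b", "beta_w", "gamma", "gamma_w")
  recs <- lapply(traces, traceRecords)
  steps <- recs[[1L]]$step
  rows <- list()
  for (m in metrics) {
    vals <- vapply(recs, function(r) r[[m]], numeric(length(steps)))
    vals <- matrix(vals, nrow = length(steps))
    rows[[m]] <- data.frame(step = steps, metric = m,
                            mean = rowMeans(vals),
                            sd = apply(vals, 1L, sd),
                            n = nReps)
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  list(summary = summary, traces = traces)
}

#' Run a parameter sweep over deme counts and dispersal rates
#'
#' For every combination of x, y, deme count and dispersal rate q in the
#' grid, runs `nReps` replicate generations and records the replicate mean
#' and sd of each diversity metric at step 0 and at generation end.
#'
#' @param grid list with `x_values`, `y_values`, `demeCounts` (powers of 2),
#'   `qValues`, `nReps`.
#' @param baseConfig configuration list supplying all other parameters.
#' @param seed root seed.
#' @param keepReplicates if TRUE, attach the per-replicate initial and final
#'   values as attribute `"replicates"` (long data.frame with a `rep` column).
#' @return data.frame with columns x, y, demes, q, metric, initial, mean, sd,
#'   n (one row per metric per grid cell).
#' @export
runSweep <- function(grid, baseConfig, seed, keepReplicates = FALSE) {
  stopifnot(all(c("x_values", "y_values", "demeCounts", "qValues") %in%
                names(grid)))
  nReps <- if (is.null(grid$nReps)) 10L else as.integer(grid$nReps)
  metrics <- c("alpha", "beta", "beta_b", "beta_w", "beta_ratio",
               "gamma", "gamma_w")
  out <- list()
  reps <- list()
  cell <- 0L
  for (x in grid$x_values) for (y in grid$y_values)
    for (nd in grid$demeCounts) for (q in grid$qValues) {
      cell <- cell + 1L
      cfg <- baseConfig
      cfg$x <- x; cfg$y <- y; cfg$q <- q; cfg$k <- as.integer(log2(nd))
      if (2^cfg$k != nd) stop("demeCounts must be powers of 2", call. = FALSE)
      finals <- matrix(NA_real_, nrow = nReps, ncol = length(metrics),
                       dimnames = list(NULL, metrics))
      inits <- finals
      for (r in seq_len(nReps)) {
        res <- runGeneration(cfg, seed = .childSeed(seed, cell * 1000L + r))
        rec <- traceRecords(res$trace)
        first <- rec[1L, ]; last <- rec[nrow(rec), ]
        for (m in setdiff(metrics, "beta_ratio")) {
          finals[r, m] <- last[[m]]
          inits[r, m] <- first[[m]]
        }
        finals[r, "beta_ratio"] <- last$beta_b / last$beta_w
        inits[r, "beta_ratio"] <- first$beta_b / first$beta_w
      }
      for (m in metrics)
        out[[length(out) + 1L]] <- data.frame(
          x = x, y = y, demes = nd, q = q, metric = m,
          initial = mean(inits[, m]),
          mean = mean(finals[, m]), sd = sd(finals[, m]), n = nReps)
      if (keepReplicates)
        for (m in metrics)
          reps[[length(reps) + 1L]] <- data.frame(
            x = x, y = y, demes = nd, q = q, metric = m,
            rep = seq_len(nReps), initial = inits[, m], final = finals[, m])
    }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  if (keepReplicates) attr(res, "replicates") <- do.call(rbind, reps)
  res
}

#' Write a diversity trace as TSV
#'
#' Columns step, alpha, beta, beta_b, beta_w, gamma, gamma_w; between/within
#' columns are empty when the population is unstructured.
#'
#' @param trace a [DiversityTrace-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTrace <- function(trace, path) {
  stopifnot(is(trace, "DiversityTrace"))
  utils::write.table(traceRecords(trace), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Write sweep results as one TSV matrix per metric and (x, y) cell
#'
#' Rows = deme counts, columns = dispersal rates; cells = replicate means of
#' the generation-end value.
#'
#' @param sweep data.frame from [runSweep()].
#' @param dir output directory (created if absent).
#' @return character vector of written paths, invisibly.
#' @export
writeSweepMatrices <- function(sweep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (x in unique(sweep$x)) for (y in unique(sweep$y))
    for (m in unique(sweep$metric)) {
      sub <- sweep[sweep$x == x & sweep$y == y & sweep$metric == m, ]
      if (!nrow(sub)) next
      demes <- sort(unique(sub$demes))
      qs <- sort(unique(sub$q), decreasing = TRUE)
      mat <- matrix(NA_real_, length(demes), length(qs),
                    dimnames = list(demes, signif(qs, 6)))
      for (i in seq_len(nrow(sub)))
        mat[as.character(sub$demes[i]), as.character(signif(sub$q[i], 6))] <-
          sub$mean[i]
      p <- file.path(dir, sprintf("%s_x%02d_y%02d.tsv", m,
                                  round(100 * x), round(100 * y)))
      utils::write.table(cbind(demes = rownames(mat), as.data.frame(mat)), p,
                         sep = "\t", quote = FALSE, row.names = FALSE, na = "")
      paths <- c(paths, p)
    }
  invisible(paths)
}

#' Write a final-state snapshot
#'
#' Host-by-taxon count matrix as TSV plus a JSON metadata sidecar (step,
#' parameters, deme assignment).
#'
#' @param state a [SimulationState-class].
#' @param prefix output path prefix; writes `<prefix>_counts.tsv` and
#'   `<prefix>_meta.json`.
#' @return character vector of the two paths, invisibly.
#' @export
writeStateSnapshot <- function(state, prefix) {
  stopifnot(is(state, "SimulationState"))
  mp <- state@metapop
  countsPath <- paste0(prefix, "_counts.tsv")
  metaPath <- paste0(prefix, "_meta.json")
  df <- data.frame(host = seq_len(nrow(mp@counts)), deme = mp@demeId,
                   age = mp@ageSteps, mp@counts, check.names = FALSE)
  utils::write.table(df, countsPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(step = state@step, params = state@params,
                            nDemes = 2L^mp@k, taxa = mp@taxa),
                       metaPath, auto_unbox = TRUE, digits = NA)
  invisible(c(countsPath, metaPath))
}
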