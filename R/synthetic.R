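#' Generate a synthetic baseline genus-level abundance table
#'
#' Builds a stool-like genus-level relative-abundance table without any
#' download: taxon base abundances follow a geometric rank-abundance series
#' (few dominant genera, a long tail of rare ones) and each sample perturbs
#' them with multiplicative log-normal noise before renormalization.
#'
#' The geometric ratio is derived from `abundanceRange`, the base abundance
#' of the rarest taxon relative to the most dominant one, so the community
#' shape (dominance plus a tail reaching several orders of magnitude down) is
#' preserved whatever the number of taxa. The default range of 1e-4 mirrors
#' genus-level stool tables, where the dominant genus sits at tens of percent
#' and the rare tail below 0.01 percent.
#'
#' @param g number of taxa (>= 2); default 129 genera.
#' @param nSamples number of samples (>= 2).
#' @param seed seed for reproducibility.
#' @param abundanceRange ratio of rarest to most dominant base abundance in
#'   (0, 1); sets the geometric decay as `abundanceRange^(1/(g-1))`.
#' @param decay optional explicit geometric ratio in (0, 1); overrides
#'   `abundanceRange`.
#' @param sdLog standard deviation of the log-normal sample noise; default 1.
#' @return nSamples x g matrix of relative abundances, rows summing to 1;
#'   column names are taxon identifiers, row names sample identifiers.
#' @export
generateBaselineTable <- function(g = 129L, nSamples = 100L, seed = NULL,
                                  abundanceRange = 1e-4, decay = NULL,
                                  sdLog = 1) {
  if (g < 2) stop("g must be >= 2", call. = FALSE)
  if (nSamples < 2) stop("nSamples must be >= 2", call. = FALSE)
  if (is.null(decay)) {
    if (abundanceRange <= 0 || abundanceRange >= 1)
      stop("abundanceRange must be in (0, 1)", call. = FALSE)
    decay <- abundanceRange^(1 / (g - 1))
  }
  if (decay <= 0 || decay >= 1) stop("decay must be in (0, 1)", call. = FALSE)
  .maybeSeed(seed)
  base <- decay^(seq_len(g) - 1L)
  base <- base / sum(base)
  noise <- matrix(exp(rnorm(nSamples * g, mean = 0, sd = sdLog)),
                  nrow = nSamples, ncol = g)
  tab <- sweep(noise, 2L, base, `*`)
  tab <- tab / rowSums(tab)
  dimnames(tab) <- list(sprintf("sample_%03d", seq_len(nSamples)),
                        sprintf("taxon_%03d", seq_len(g)))
  tab
}

#' Read a sample-by-taxon relative-abundance table from TSV
#'
#' Expects a header row of taxon identifiers and one tab-separated row of
#' relative abundances per sample (optionally with row names in the first
#' column).
#'
#' @param path TSV file path.
#' @return numeric matrix, rows = samples, columns = taxa.
#' @export
readAbundanceTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (ncol(df) > 1 && !is.numeric(df[[1]])) {
    rn <- df[[1]]
    df <- df[, -1, drop = FALSE]
    rownames(df) <- rn
  }
  as.matrix(df)
}

#' Fit a truncated multivariate normal model to an abundance table
#'
#' The model mean is the per-taxon column mean, the covariance is the sample
#' covariance of the columns, regularized by adding epsilon to the diagonal
#' to guarantee positive-semidefiniteness.
#'
#' @param table sample-by-taxon relative-abundance matrix; every row must sum
#'   to 1 (within 1e-6).
#' @param epsilon diagonal regularization (default 1e-10).
#' @return a [TrMVNModel-class].
#' @export
fitTrMVN <- function(table, epsilon = 1e-10) {
  table <- as.matrix(table)
  if (nrow(table) < 2) stop("insufficient data: need >= 2 samples", call. = FALSE)
  if (any(abs(rowSums(table) - 1) > 1e-6))
    stop("every row must sum to 1", call. = FALSE)
  mu <- colMeans(table)
  sigma <- cov(table)
  sigma <- (sigma + t(sigma)) / 2
  diag(sigma) <- diag(sigma) + epsilon
  taxa <- colnames(table)
  if (is.null(taxa)) taxa <- sprintf("taxon_%03d", seq_along(mu))
  TrMVNModel(mean = mu, covariance = sigma, taxa = taxa)
}

#' Draw community profiles from a truncated multivariate normal model
#'
#' Each draw samples the underlying multivariate normal, truncates by
#' clamping negative entries to zero, and rescales to unit sum. A draw whose
#' entries are all zero after clamping is redrawn, up to a retry cap.
#'
#' @param model a [TrMVNModel-class].
#' @param n number of profiles (>= 1).
#' @param seed optional seed.
#' @param retryCap redraw attempts per degenerate draw (default 100).
#' @return n x g matrix of relative-abundance profiles (rows sum to 1).
#' @export
sampleTrMVN <- function(model, n, seed = NULL, retryCap = 100L) {
  stopifnot(is(model, "TrMVNModel"), n >= 1)
  .maybeSeed(seed)
  g <- length(model@mean)
  raw <- MASS::mvrnorm(n = n, mu = model@mean, Sigma = model@covariance)
  if (n == 1L) raw <- matrix(raw, nrow = 1L)
  raw[raw < 0] <- 0
  bad <- which(rowSums(raw) <= 0)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > retryCap)
      stop("degenerate model: draws remain all-zero after ", retryCap,
           " retries", call. = FALSE)
    redo <- MASS::mvrnorm(n = length(bad), mu = model@mean,
                          Sigma = model@covariance)
    if (length(bad) == 1L) redo <- matrix(redo, nrow = 1L)
    redo[redo < 0] <- 0
    raw[bad, ] <- redo
    bad <- which(rowSums(raw) <= 0)
  }
  out <- raw / rowSums(raw)
  colnames(out) <- model@taxa
  out
}

#' Build a complete binary tree of deme community models
#'
#' The root carries the fitted population model. Each child node's mean is a
#' single truncated-MVN draw from its parent's model and its covariance is
#' the parent covariance scaled by `shrinkFactor`; the 2^k terminal nodes are
#' the per-deme models.
#'
#' @param root root [TrMVNModel-class].
#' @param k tree levels (0 gives a single leaf equal to the root).
#' @param seed optional seed.
#' @param shrinkFactor covariance multiplier applied at each level (default 1).
#' @return a [DemeTree-class] with 2^k leaves.
#' @export
buildDemeTree <- function(root, k, seed = NULL, shrinkFactor = 1) {
  stopifnot(is(root, "TrMVNModel"))
  if (k < 0) stop("k must be >= 0", call. = FALSE)
  .maybeSeed(seed)
  k <- as.integer(k)
  level <- list(root)
  if (k > 0L) {
    for (lev in seq_len(k)) {
      nxt <- vector("list", 2L * length(level))
      for (i in seq_along(level)) {
        parent <- level[[i]]
        childCov <- parent@covariance * shrinkFactor
        for (j in 1:2) {
          childMean <- drop(sampleTrMVN(parent, 1L))
          nxt[[2L * (i - 1L) + j]] <- TrMVNModel(childMean, childCov,
                                                 taxa = parent@taxa)
        }
      }
      level <- nxt
    }
  }
  new("DemeTree", levels = k, rootModel = root, leafModels = level)
}

#' Initialize a structured host metapopulation
#'
#' Creates N hosts split equally over the 2^k demes of a [DemeTree-class].
#' Each host's microbiome is a multinomial draw of size M from a per-host
#' profile sampled from its deme's leaf model. Each deme's fixed environment
#' is one large multinomial sample from the common environmental profile
#' (taken as the common profile itself when the population is unstructured).
#'
#' @param tree a [DemeTree-class].
#' @param common common environmental profile (relative abundances over the
#'   tree's taxa) feeding the per-deme fixed environments.
#' @param N host population size; must be divisible by 2^k.
#' @param M per-host microbiome capacity.
#' @param q host dispersal rate in [0, 1].
#' @param feSampleSize size of the multinomial sample defining each deme's
#'   fixed environment (default 1e6).
#' @param seed optional seed.
#' @return a [Metapopulation-class].
#' @export
initMetapopulation <- function(tree, common, N, M, q = 0,
                               feSampleSize = 1e6, seed = NULL) {
  stopifnot(is(tree, "DemeTree"))
  .assertProfile(common, "common environmental profile")
  .maybeSeed(seed)
  nd <- 2L^tree@levels
  if (N %% nd != 0)
    stop("N must be divisible by the number of demes (2^k)", call. = FALSE)
  g <- length(common)
  perDeme <- N %/% nd
  counts <- matrix(0, nrow = N, ncol = g)
  demeId <- rep(seq_len(nd), each = perDeme)
  for (d in seq_len(nd)) {
    profiles <- sampleTrMVN(tree@leafModels[[d]], perDeme)
    rows <- which(demeId == d)
    for (i in seq_len(perDeme))
      counts[rows[i], ] <- rmultinom(1L, size = M, prob = profiles[i, ])
  }
  if (nd == 1L) {
    fixedEnv <- matrix(common, nrow = 1L)
  } else {
    fixedEnv <- t(vapply(seq_len(nd), function(d)
      demeFixedEnvironment(common, feSampleSize), numeric(g)))
  }
  taxa <- tree@rootModel@taxa
  colnames(counts) <- taxa
  colnames(fixedEnv) <- taxa
  new("Metapopulation", counts = counts, demeId = as.integer(demeId),
      ageSteps = rep(0L, N), fixedEnv = fixedEnv, k = tree@levels,
      M = as.numeric(M), q = as.numeric(q), taxa = taxa)
}

#' Kolmogorov-Smirnov validation of resampled communities
#'
#' Two-sample KS tests comparing (i) each taxon's abundance distribution and
#' (ii) the distribution of per-sample Shannon indices between a source table
#' and a resampled set of profiles.
#'
#' @param sourceTable sample-by-taxon relative-abundance matrix.
#' @param resampled matrix of resampled profiles over the same taxa.
#' @return list with `taxon` (data.frame: taxon, statistic, p.value) and
#'   `shannon` (list: statistic, p.value).
#' @export
ksValidate <- function(sourceTable, resampled) {
  sourceTable <- as.matrix(sourceTable)
  resampled <- as.matrix(resampled)
  if (nrow(sourceTable) < 1 || nrow(resampled) < 1)
    stop("both inputs must be non-empty", call. = FALSE)
  if (ncol(sourceTable) != ncol(resampled))
    stop("inputs must share the same taxa", call. = FALSE)
  g <- ncol(sourceTable)
  perTaxon <- lapply(seq_len(g), function(j) {
    kt <- suppressWarnings(ks.test(sourceTable[, j], resampled[, j]))
    data.frame(taxon = j, statistic = unname(kt$statistic),
               p.value = kt$p.value)
  })
  hSrc <- apply(sourceTable, 1L, shannonIndex)
  hRes <- apply(resampled, 1L, shannonIndex)
  ksH <- suppressWarnings(ks.test(hSrc, hRes))
  list(taxon = do.call(rbind, perTaxon),
       shannon = list(statistic = unname(ksH$statistic), p.value = ksH$p.value))
}

#' Write a fitted model and deme tree to JSON
#'
#' @param tree a [DemeTree-class].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeDemeTree <- function(tree, path) {
  stopifnot(is(tree, "DemeTree"))
  ser <- function(m) list(mean = m@mean, covariance = m@covariance,
                          taxa = m@taxa)
  obj <- list(levels = tree@levels,
              root = ser(tree@rootModel),
              leaves = lapply(tree@leafModels, ser))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
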