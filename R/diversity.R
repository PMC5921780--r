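#' Shannon-Wiener index of a profile
#'
#' -sum p_i log p_i with the convention 0 log 0 = 0. Natural logarithm by
#' default (nats); the base is configurable.
#'
#' @param p relative-abundance profile (or non-negative weights; normalized
#'   internally).
#' @param base logarithm base (default e).
#' @return Shannon index in [0, log(g)].
#' @export
shannonIndex <- function(p, base = exp(1)) {
  s <- sum(p)
  if (s <= 0) stop("profile must have positive total", call. = FALSE)
  p <- p / s
  p <- p[p > 0]
  -sum(p * log(p)) / log(base)
}

#' Bray-Curtis dissimilarity between two hosts
#'
#' sum |u_i - v_i| / sum (u_i + v_i) on raw counts. With all hosts carrying
#' exactly M microbes this coincides with the relative-abundance version.
#'
#' @param u,v count (or abundance) vectors over the same taxa.
#' @return dissimilarity in [0, 1].
#' @export
brayCurtis <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must share taxa", call. = FALSE)
  sum(abs(u - v)) / sum(u + v)
}

#' Alpha diversity of a host collection
#'
#' Mean of per-host Shannon indices.
#'
#' @param counts host-by-taxon count matrix (>= 1 row).
#' @param base logarithm base.
#' @return mean within-host Shannon index.
#' @export
alphaDiversity <- function(counts, base = exp(1)) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1) stop("need at least one host", call. = FALSE)
  mean(apply(counts, 1L, shannonIndex, base = base))
}

#' Gamma diversity of a host collection
#'
#' Shannon index of the pooled (mean) relative composition of all hosts in
#' scope.
#'
#' @param counts host-by-taxon count matrix (>= 1 row).
#' @param base logarithm base.
#' @return pooled Shannon index.
#' @export
gammaDiversity <- function(counts, base = exp(1)) {
  shannonIndex(pooledProfile(as.matrix(counts)), base = base)
}

#' Within-deme gamma diversity
#'
#' Mean over demes of each deme's gamma diversity.
#'
#' @param counts host-by-taxon count matrix.
#' @param demeId deme membership of each host.
#' @param base logarithm base.
#' @return mean per-deme pooled Shannon index.
#' @export
gammaWithin <- function(counts, demeId, base = exp(1)) {
  counts <- as.matrix(counts)
  demes <- sort(unique(demeId))
  mean(vapply(demes, function(d)
    gammaDiversity(counts[demeId == d, , drop = FALSE], base = base),
    numeric(1)))
}

## Internal: full pairwise Bray-Curtis matrix (hosts all sum to M).
.bcMatrix <- function(counts) {
  n <- nrow(counts)
  M2 <- 2 * sum(counts[1L, ])
  acc <- matrix(0, n, n)
  for (j in seq_len(ncol(counts)))
    acc <- acc + abs(outer(counts[, j], counts[, j], `-`))
  acc / M2
}

#' Beta diversities of a structured host collection
#'
#' Mean pairwise Bray-Curtis dissimilarity over all unordered host pairs
#' (`beta`), over pairs from different demes only (`beta_b`), and over pairs
#' within the same deme only (`beta_w`), plus the ratio `beta_ratio` =
#' beta_b / beta_w. Pairs are enumerated exactly when their number is at most
#' `pairCap`, and uniformly subsampled to `pairCap` pairs otherwise.
#'
#' Undefined components are NA: `beta_b` with a single deme, `beta_w` when
#' demes hold one host each, `beta_ratio` when either is NA or `beta_w` is 0.
#'
#' @param counts host-by-taxon count matrix (>= 2 rows, equal row sums).
#' @param demeId deme membership of each host (default: one deme).
#' @param pairCap maximum number of pairs evaluated exactly (default 1e5).
#' @return list with beta, beta_b, beta_w, beta_ratio.
#' @export
betaDiversities <- function(counts, demeId = NULL, pairCap = 1e5) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  if (n < 2) stop("need at least two hosts", call. = FALSE)
  if (is.null(demeId)) demeId <- rep(1L, n)
  nPairs <- n * (n - 1) / 2
  if (nPairs <= pairCap) {
    bc <- .bcMatrix(counts)
    same <- outer(demeId, demeId, `==`)
    ut <- upper.tri(bc)
    dAll <- bc[ut]
    dW <- bc[ut & same]
    dB <- bc[ut & !same]
  } else {
    idx <- sample.int(nPairs, pairCap)
    ## map linear upper-triangle index to (i, j), column-major over j > i
    j <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
    i <- idx - (j - 1) * (j - 2) / 2
    M2 <- 2 * sum(counts[1L, ])
    dAll <- rowSums(abs(counts[i, , drop = FALSE] -
                        counts[j, , drop = FALSE])) / M2
    sameP <- demeId[i] == demeId[j]
    dW <- dAll[sameP]
    dB <- dAll[!sameP]
  }
  beta <- mean(dAll)
  beta_w <- if (length(dW)) mean(dW) else NA_real_
  beta_b <- if (length(dB)) mean(dB) else NA_real_
  beta_ratio <- if (is.na(beta_b) || is.na(beta_w) || beta_w == 0)
    NA_real_ else beta_b / beta_w
  list(beta = beta, beta_b = beta_b, beta_w = beta_w, beta_ratio = beta_ratio)
}
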