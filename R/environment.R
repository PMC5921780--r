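#' Pooled environmental profile of a host collection
#'
#' Arithmetic mean of the hosts' relative compositions. Because every host
#' carries exactly M microbes this equals the relative composition of the
#' elementwise sum of all host counts.
#'
#' @param counts host-by-taxon count matrix (>= 1 row).
#' @return relative-abundance profile over the taxa.
#' @export
pooledProfile <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 1) stop("need at least one host", call. = FALSE)
  colMeans(.relComp(counts))
}

#' Mix fixed and pooled environmental components
#'
#' e = (1 - y) f + y p, elementwise over taxa.
#'
#' @param f fixed environmental profile.
#' @param p pooled environmental profile.
#' @param y pooled-environment weight in [0, 1].
#' @return mixed environmental profile.
#' @export
mixEnvironment <- function(f, p, y) {
  if (length(f) != length(p)) stop("profiles must share taxa", call. = FALSE)
  if (y < 0 || y > 1) stop("y must be in [0, 1]", call. = FALSE)
  .assertProfile(f, "fixed environment")
  .assertProfile(p, "pooled environment")
  (1 - y) * f + y * p
}

#' Draw a deme's fixed environmental profile
#'
#' One large multinomial sample of `sampleSize` microbes from the common
#' environmental profile, renormalized; drawn once per deme at initialization
#' and held constant thereafter.
#'
#' @param common common environmental profile.
#' @param sampleSize multinomial sample size (>= 1); default 1e6.
#' @param seed optional seed.
#' @return a relative-abundance profile.
#' @export
demeFixedEnvironment <- function(common, sampleSize = 1e6, seed = NULL) {
  .assertProfile(common, "common environmental profile")
  if (sampleSize < 1) stop("sampleSize must be >= 1", call. = FALSE)
  .maybeSeed(seed)
  drop(rmultinom(1L, size = sampleSize, prob = common)) / sampleSize
}

## Internal: per-deme mixed environments from current host state.
.mixedEnvironments <- function(metapop, y) {
  nd <- 2L^metapop@k
  g <- ncol(metapop@counts)
  env <- matrix(0, nrow = nd, ncol = g)
  for (d in seq_len(nd)) {
    rows <- metapop@demeId == d
    p <- pooledProfile(metapop@counts[rows, , drop = FALSE])
    env[d, ] <- (1 - y) * metapop@fixedEnv[d, ] + y * p
  }
  colnames(env) <- metapop@taxa
  env
}
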