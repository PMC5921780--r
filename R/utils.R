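#' @import methods
#' @importFrom stats cov rbinom rmultinom rnorm runif ks.test sd
NULL

PROFILE_TOL <- 1e-9

## Internal: check a relative-abundance profile (non-negative, unit sum).
.assertProfile <- function(p, what = "profile") {
  if (!is.numeric(p) || length(p) < 1L)
    stop(what, " must be a non-empty numeric vector", call. = FALSE)
  if (any(p < -PROFILE_TOL))
    stop(what, " has negative entries", call. = FALSE)
  if (abs(sum(p) - 1) > PROFILE_TOL)
    stop(what, " does not sum to 1 (sum = ", format(sum(p)), ")", call. = FALSE)
  invisible(TRUE)
}

## Internal: renormalize counts/weights to a profile.
.asProfile <- function(x) {
  s <- sum(x)
  if (s <= 0) stop("cannot normalize an all-zero vector", call. = FALSE)
  x / s
}

## Internal: rows of a count matrix as relative compositions.
.relComp <- function(counts) counts / rowSums(counts)

## Internal: derived replicate seed, kept inside 32-bit integer range.
.childSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000 + i) %% 2147483647)
}

## Internal: set seed only when one is supplied.
.maybeSeed <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
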