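#' Expected parental fraction as a function of the acquisition intensity
#'
#' Closed form for the expected fraction of a host's microbiome that traces
#' back to its parent over one host generation, as a function of the
#' dimensionless acquisition intensity a = T/M = N t / M:
#' x = (1 - exp(-a)) / a, with x = 1 at a = 0 (pure vertical transmission).
#'
#' @param a non-negative acquisition intensity (vectorized).
#' @return expected parental fraction x in (0, 1].
#' @export
parentalFractionClosedForm <- function(a) {
  stopifnot(all(a >= 0))
  out <- ifelse(a == 0, 1, (1 - exp(-a)) / a)
  as.numeric(out)
}

#' Solve the acquisition intensity for a target parental fraction
#'
#' Inverts x = (1 - exp(-a))/a by bisection. The target function is strictly
#' decreasing on a > 0, so the root is unique; x = 1 maps to a = 0 exactly.
#'
#' @param x target parental fraction in (0, 1].
#' @param tol absolute tolerance on |closedForm(a) - x| (default 1e-12).
#' @param aMax bracket cap; x small enough to need a > aMax is an error.
#' @return acquisition intensity a >= 0.
#' @export
solveAcquisition <- function(x, tol = 1e-12, aMax = 1e6) {
  if (!is.numeric(x) || length(x) != 1L || x <= 0 || x > 1)
    stop("x must be a single value in (0, 1]", call. = FALSE)
  if (tol <= 0) stop("tol must be positive", call. = FALSE)
  if (x == 1) return(0)
  lo <- 0; hi <- 1
  while (parentalFractionClosedForm(hi) > x) {
    hi <- hi * 2
    if (hi > aMax) stop("x too small: a exceeds bracket cap ", aMax, call. = FALSE)
  }
  ## bisection: f is strictly decreasing, f(lo) >= x >= f(hi)
  for (iter in seq_len(200L)) {
    mid <- (lo + hi) / 2
    fm <- parentalFractionClosedForm(mid)
    if (abs(fm - x) <= tol) return(mid)
    if (fm > x) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Per-step environmental acquisition count
#'
#' Number of microbes each host recruits from its local environment per Moran
#' time step, t = a M / N. Kept real-valued; it enters the engine only through
#' mixture weights, so no rounding is applied.
#'
#' @param a acquisition intensity.
#' @param M per-host microbiome capacity.
#' @param N host population size.
#' @return t >= 0 (real).
#' @export
envPerStep <- function(a, M, N) {
  stopifnot(a >= 0, M >= 1, N >= 1)
  a * M / N
}

#' Finite-population expected parental fraction
#'
#' Exact finite sum (1/N) * sum_{i=0}^{N-1} (M/(M+t))^i with t = a M / N.
#' Since M/(M+t) = 1/(1 + a/N), the capacity M cancels. This is the exact
#' expectation at population size N; the closed form
#' [parentalFractionClosedForm()] is its N -> Inf limit.
#'
#' @param a acquisition intensity.
#' @param N host population size (= steps per generation).
#' @return expected parental fraction at finite N.
#' @export
expectedParentalFractionFinite <- function(a, N) {
  stopifnot(a >= 0, N >= 1)
  if (a == 0) return(1)
  r <- 1 / (1 + a / N)
  ## geometric sum (1 - r^N) / (1 - r), averaged over N terms
  (1 - r^N) / (1 - r) / N
}

#' Simulate realized parental-origin retention along host lineages
#'
#' Monte-Carlo oracle tying the engine's acquisition step to the analytic
#' parameterization. A newborn starts with all M microbes of parental origin;
#' at each of the following N-1 steps its microbiome is multinomially
#' resampled from the blend (M c + t e)/(M + t), so the parental-origin count
#' K evolves as K' ~ Binomial(M, K/(M + t)). The realized generation-average
#' parental fraction is mean(K_i/M) over ages i = 0..N-1.
#'
#' @param x configured parental fraction in (0, 1].
#' @param N host population size (steps per generation).
#' @param M per-host microbiome capacity.
#' @param nReps number of independent lineages to simulate.
#' @param seed optional seed for reproducibility.
#' @return numeric vector of nReps realized generation-average fractions.
#' @export
lineageRetention <- function(x, N, M, nReps = 50L, seed = NULL) {
  .maybeSeed(seed)
  a <- solveAcquisition(x)
  t <- envPerStep(a, M, N)
  vapply(seq_len(nReps), function(rep) {
    K <- M
    fracs <- numeric(N)
    fracs[1] <- 1
    for (i in seq_len(N - 1L)) {
      K <- rbinom(1L, size = as.integer(M), prob = K / (M + t))
      fracs[i + 1L] <- K / M
    }
    mean(fracs)
  }, numeric(1))
}
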