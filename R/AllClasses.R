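#' Truncated multivariate normal community model
#'
#' Generative model for initial microbiome profiles: a multivariate normal
#' over g taxa whose draws are truncated at zero and rescaled to sum to one.
#'
#' @slot mean numeric vector of length g, mean relative abundances.
#' @slot covariance symmetric positive-semidefinite g x g matrix.
#' @slot taxa character vector of taxon identifiers (length g).
#'
#' @seealso [fitTrMVN()], [sampleTrMVN()]
#' @export
setClass("TrMVNModel",
  representation(mean = "numeric", covariance = "matrix", taxa = "character"))

setValidity("TrMVNModel", function(object) {
  g <- length(object@mean)
  msg <- character()
  if (!all(dim(object@covariance) == c(g, g)))
    msg <- c(msg, "covariance dimensions do not match mean length")
  else {
    if (max(abs(object@covariance - t(object@covariance))) > 1e-9)
      msg <- c(msg, "covariance is not symmetric within 1e-9")
    ev <- eigen(object@covariance, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-9)
      msg <- c(msg, "covariance is not positive-semidefinite (eigenvalue < -1e-9)")
  }
  if (length(object@taxa) != g)
    msg <- c(msg, "taxa length does not match mean length")
  if (length(msg)) msg else TRUE
})

#' Construct a TrMVNModel
#'
#' @param mean numeric mean vector over taxa.
#' @param covariance symmetric PSD covariance matrix.
#' @param taxa taxon identifiers; defaults to `taxon_001`, ...
#' @return A [TrMVNModel-class] object.
#' @export
TrMVNModel <- function(mean, covariance, taxa = NULL) {
  if (is.null(taxa)) taxa <- sprintf("taxon_%03d", seq_along(mean))
  new("TrMVNModel", mean = as.numeric(mean),
      covariance = as.matrix(covariance), taxa = as.character(taxa))
}

#' @describeIn TrMVNModel-class mean vector accessor
#' @param object,x a `TrMVNModel`
#' @export
modelMean <- function(object) object@mean

#' @describeIn TrMVNModel-class covariance accessor
#' @export
modelCov <- function(object) object@covariance

#' @describeIn TrMVNModel-class taxon identifiers
#' @export
modelTaxa <- function(object) object@taxa

setMethod("show", "TrMVNModel", function(object) {
  cat("TrMVNModel over", length(object@mean), "taxa\n")
  cat("  mean range: [", format(min(object@mean), digits = 3), ", ",
      format(max(object@mean), digits = 3), "]\n", sep = "")
  cat("  total variance:", format(sum(diag(object@covariance)), digits = 3), "\n")
})

#' Complete binary tree of deme community models
#'
#' A complete binary tree with k levels whose root carries the population-wide
#' community model and whose 2^k leaves carry per-deme models, each derived
#' from its parent by one truncated-MVN draw (the child mean) plus covariance
#' shrinkage.
#'
#' @slot levels integer k >= 0.
#' @slot rootModel the root [TrMVNModel-class].
#' @slot leafModels list of 2^k leaf [TrMVNModel-class] objects.
#'
#' @seealso [buildDemeTree()]
#' @export
setClass("DemeTree",
  representation(levels = "integer", rootModel = "TrMVNModel", leafModels = "list"))

setValidity("DemeTree", function(object) {
  msg <- character()
  if (object@levels < 0L) msg <- c(msg, "levels must be >= 0")
  if (length(object@leafModels) != 2L^object@levels)
    msg <- c(msg, "number of leaves must equal 2^levels")
  if (!all(vapply(object@leafModels, is, logical(1), "TrMVNModel")))
    msg <- c(msg, "all leaves must be TrMVNModel objects")
  if (length(msg)) msg else TRUE
})

#' @describeIn DemeTree-class number of tree levels (k)
#' @param object a `DemeTree`
#' @export
treeLevels <- function(object) object@levels

#' @describeIn DemeTree-class list of leaf models, one per deme
#' @export
leafModels <- function(object) object@leafModels

setMethod("show", "DemeTree", function(object) {
  cat("DemeTree: k =", object@levels, "levels,",
      length(object@leafModels), "leaf model(s) over",
      length(object@rootModel@mean), "taxa\n")
})

#' Structured host metapopulation
#'
#' Hosts of a constant-size population, partitioned into 2^k equal demes.
#' Each host carries an integer microbiome of exactly M microbes over g taxa;
#' each deme carries a fixed environmental profile drawn once at
#' initialization.
#'
#' @slot counts N x g numeric matrix of per-host microbe counts (each row
#'   sums to M).
#' @slot demeId integer vector of length N mapping host slots to demes (1-based).
#' @slot ageSteps integer vector of length N, steps since each host's birth.
#' @slot fixedEnv 2^k x g matrix of per-deme fixed environmental profiles.
#' @slot k integer, deme tree levels (2^k demes).
#' @slot M numeric, per-host microbiome capacity.
#' @slot q numeric host dispersal rate in [0, 1].
#' @slot taxa character taxon identifiers.
#'
#' @export
setClass("Metapopulation",
  representation(counts = "matrix", demeId = "integer", ageSteps = "integer",
                 fixedEnv = "matrix", k = "integer", M = "numeric",
                 q = "numeric", taxa = "character"))

setValidity("Metapopulation", function(object) {
  msg <- character()
  N <- nrow(object@counts)
  nd <- 2L^object@k
  if (length(object@demeId) != N) msg <- c(msg, "demeId length != number of hosts")
  if (length(object@ageSteps) != N) msg <- c(msg, "ageSteps length != number of hosts")
  if (nrow(object@fixedEnv) != nd) msg <- c(msg, "fixedEnv must have one row per deme")
  if (ncol(object@fixedEnv) != ncol(object@counts))
    msg <- c(msg, "fixedEnv and counts must share taxa")
  if (any(object@counts < 0)) msg <- c(msg, "negative host counts")
  if (any(abs(rowSums(object@counts) - object@M) > 1e-6))
    msg <- c(msg, "every host must carry exactly M microbes")
  sizes <- tabulate(object@demeId, nbins = nd)
  if (length(unique(sizes)) != 1L)
    msg <- c(msg, "demes must be equal-sized")
  if (object@q < 0 || object@q > 1) msg <- c(msg, "q must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn Metapopulation-class host-by-taxon count matrix
#' @param object a `Metapopulation`
#' @export
hostCounts <- function(object) object@counts

#' @describeIn Metapopulation-class deme membership of each host slot
#' @export
demeAssignment <- function(object) object@demeId

#' @describeIn Metapopulation-class per-deme fixed environmental profiles
#' @export
fixedEnvironments <- function(object) object@fixedEnv

#' @describeIn Metapopulation-class number of demes (2^k)
#' @export
nDemes <- function(object) as.integer(2L^object@k)

#' @describeIn Metapopulation-class number of hosts
#' @export
nHosts <- function(object) nrow(object@counts)

#' @describeIn Metapopulation-class host ages in steps since birth
#' @export
hostAges <- function(object) object@ageSteps

setMethod("show", "Metapopulation", function(object) {
  cat("Metapopulation:", nrow(object@counts), "hosts in", 2L^object@k,
      "deme(s);", ncol(object@counts), "taxa; M =", format(object@M),
      "; q =", object@q, "\n")
})

#' Simulation state
#'
#' Bundles the metapopulation with the acquisition/environment parameters and
#' the step counter. One host generation is N time steps.
#'
#' @slot step integer step counter (0 at initialization).
#' @slot metapop the [Metapopulation-class].
#' @slot params named list: x, a, t, y, q and bookkeeping fields.
#' @slot mixedEnv 2^k x g matrix of the per-deme mixed environments used in
#'   the most recent step (zero rows before the first step).
#'
#' @export
setClass("SimulationState",
  representation(step = "integer", metapop = "Metapopulation",
                 params = "list", mixedEnv = "matrix"))

setMethod("show", "SimulationState", function(object) {
  cat("SimulationState at step", object@step, "\n")
  show(object@metapop)
  cat("  x =", object@params$x, " y =", object@params$y,
      " t =", format(object@params$t, digits = 4), "\n")
})

#' @describeIn SimulationState-class current step counter
#' @param object a `SimulationState`
#' @export
simStep <- function(object) object@step

#' @describeIn SimulationState-class the metapopulation
#' @export
simMetapop <- function(object) object@metapop

#' @describeIn SimulationState-class simulation parameters
#' @export
simParams <- function(object) object@params

#' Diversity trace
#'
#' Per-step records of alpha, beta (overall / between-deme / within-deme),
#' gamma and within-deme gamma diversity. Between/within columns are NA when
#' the population is unstructured.
#'
#' @slot records data.frame with columns step, alpha, beta, beta_b, beta_w,
#'   gamma, gamma_w.
#'
#' @export
setClass("DiversityTrace", representation(records = "data.frame"))

setValidity("DiversityTrace", function(object) {
  need <- c("step", "alpha", "beta", "beta_b", "beta_w", "gamma", "gamma_w")
  if (!all(need %in% names(object@records)))
    return("records must contain step, alpha, beta, beta_b, beta_w, gamma, gamma_w")
  TRUE
})

#' @describeIn DiversityTrace-class records as a data.frame
#' @param object a `DiversityTrace`
#' @export
traceRecords <- function(object) object@records

setMethod("show", "DiversityTrace", function(object) {
  r <- object@records
  cat("DiversityTrace:", nrow(r), "records, steps",
      min(r$step), "-", max(r$step), "\n")
  print(utils::head(r, 4))
  if (nrow(r) > 4) cat("  ...\n")
})

#' Coerce a DiversityTrace to data.frame
#'
#' @param x a [DiversityTrace-class]
#' @param ... unused
#' @return the records data.frame
#' @export
as.data.frame.DiversityTrace <- function(x, ...) x@records
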