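#' @import methods
NULL

#' Gene-age distribution of duplication nodes
#'
#' Container for the per-species age distribution of gene duplications: one
#' synonymous-divergence (Ks) value per retained duplication node of the
#' species' gene-family trees, plus provenance metadata (which estimator
#' produced the values, which filters were applied, how many values were
#' discarded as saturated).
#'
#' @slot species single character, species identifier.
#' @slot ks numeric vector of node Ks values (finite, >= 0).
#' @slot familyId character vector parallel to `ks` (may be empty).
#' @slot nodeId character vector parallel to `ks` (may be empty).
#' @slot nSaturated integer, number of values discarded as saturated.
#' @slot estimator single character, e.g. `"NG86"` or `"external"`.
#' @slot filters named list of filter settings used upstream.
#'
#' @seealso [ageDistribution()], [ksValues()], [writeAgeDistribution()]
#' @export
setClass("AgeDistribution",
  representation(
    species = "character",
    ks = "numeric",
    familyId = "character",
    nodeId = "character",
    nSaturated = "integer",
    estimator = "character",
    filters = "list"
  ),
  prototype(
    species = NA_character_, ks = numeric(0), familyId = character(0),
    nodeId = character(0), nSaturated = 0L, estimator = "NG86",
    filters = list()
  )
)

setValidity("AgeDistribution", function(object) {
  msg <- character(0)
  if (length(object@species) != 1L)
    msg <- c(msg, "'species' must be a single identifier")
  if (any(!is.finite(object@ks)) || any(object@ks < 0))
    msg <- c(msg, "all Ks values must be finite and >= 0")
  if (length(object@familyId) &&
      length(object@familyId) != length(object@ks))
    msg <- c(msg, "'familyId' must be empty or parallel to 'ks'")
  if (length(object@nodeId) && length(object@nodeId) != length(object@ks))
    msg <- c(msg, "'nodeId' must be empty or parallel to 'ks'")
  if (length(msg)) msg else TRUE
})

#' Null model for a gene-age distribution without ancient WGDs
#'
#' A constant-duplication / exponential-survival background: paralog ages are
#' modelled as an exponential decay truncated to the analysis window
#' `(window[1], window[2]]`, with decay rate `rate` fitted by maximum
#' likelihood.
#'
#' @slot rate positive numeric, exponential decay rate per unit Ks.
#' @slot window numeric length-2, (Ks-min, Ks-max] fitting window.
#' @slot n integer, number of Ks values used in the fit.
#'
#' @seealso [fitNull()], [ksGoodnessOfFit()]
#' @export
setClass("KsNullModel",
  representation(rate = "numeric", window = "numeric", n = "integer"),
  prototype(rate = 1, window = c(0.01, 2), n = 0L)
)

setValidity("KsNullModel", function(object) {
  msg <- character(0)
  if (length(object@rate) != 1L || !is.finite(object@rate) ||
      object@rate <= 0)
    msg <- c(msg, "'rate' must be a single positive number")
  if (length(object@window) != 2L || object@window[1] >= object@window[2])
    msg <- c(msg, "'window' must be (lo, hi) with lo < hi")
  if (length(msg)) msg else TRUE
})

#' Gaussian mixture fit to a Ks age distribution
#'
#' Result of expectation-maximisation fitting of a K-component Gaussian
#' mixture on untransformed Ks values inside a window, with the number of
#' components selected by BIC.
#'
#' @slot k integer, number of components of the selected model.
#' @slot weight,mean,sd numeric vectors of length `k`.
#' @slot logLik numeric, total log-likelihood of the selected model.
#' @slot bic numeric, BIC of the selected model.
#' @slot converged logical, EM convergence flag.
#' @slot window numeric length-2 fitting window.
#' @slot n integer, number of observations fitted.
#'
#' @seealso [fitKsMixture()], [callPeaks()]
#' @export
setClass("KsMixtureFit",
  representation(
    k = "integer", weight = "numeric", mean = "numeric", sd = "numeric",
    logLik = "numeric", bic = "numeric", converged = "logical",
    window = "numeric", n = "integer"
  )
)

setValidity("KsMixtureFit", function(object) {
  msg <- character(0)
  k <- object@k
  if (length(object@weight) != k || length(object@mean) != k ||
      length(object@sd) != k)
    msg <- c(msg, "'weight', 'mean', 'sd' must each have length k")
  if (any(object@weight <= 0) || abs(sum(object@weight) - 1) > 1e-6)
    msg <- c(msg, "weights must be positive and sum to 1")
  if (any(object@sd <= 0))
    msg <- c(msg, "component sds must be positive")
  if (length(msg)) msg else TRUE
})

#' Per-node MAPS profile of shared gene duplications
#'
#' For every internal node N1 (tip-most) .. Nk (root) of a ladderized species
#' tree: the number of gene-tree subtrees counted at that node, the number of
#' those whose root is a duplication shared by the node's descendant taxa,
#' and the resulting percentage.
#'
#' @slot node character vector of node labels, tip-most to root.
#' @slot nSubtrees,nDup integer vectors parallel to `node`.
#' @slot pctDup numeric vector, `100 * nDup / nSubtrees` (NA when no
#'   subtrees were counted at a node).
#' @slot occupancy numeric, minimum ingroup-taxa fraction applied.
#' @slot nTrees integer, number of gene trees aggregated.
#'
#' @seealso [mapsProfile()], [fisherVsNull()]
#' @export
setClass("MapsProfile",
  representation(
    node = "character", nSubtrees = "integer", nDup = "integer",
    pctDup = "numeric", occupancy = "numeric", nTrees = "integer"
  )
)

setValidity("MapsProfile", function(object) {
  msg <- character(0)
  n <- length(object@node)
  if (length(object@nSubtrees) != n || length(object@nDup) != n ||
      length(object@pctDup) != n)
    msg <- c(msg, "count vectors must be parallel to 'node'")
  if (any(object@nDup > object@nSubtrees))
    msg <- c(msg, "nDup cannot exceed nSubtrees at any node")
  if (any(object@nDup < 0) || any(object@nSubtrees < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A set of simulated gene trees with its resampling plan
#'
#' Gene trees generated by the birth-death guest-tree simulator (optionally
#' with an injected WGD), together with the configuration that produced them
#' and a without-replacement resampling plan used to express uncertainty in
#' downstream Fisher tests.
#'
#' @slot trees list of `phylo` gene trees, all passing the one-copy-per-taxon
#'   family filter.
#' @slot config named list: rates, WGD events, n, seed, rejection count.
#' @slot resamples list of integer index vectors into `trees`.
#'
#' @seealso [buildNullSet()], [buildPositiveSet()], [simulateGuestTree()]
#' @export
setClass("SimulationSet",
  representation(trees = "list", config = "list", resamples = "list")
)

setValidity("SimulationSet", function(object) {
  msg <- character(0)
  if (!all(vapply(object@trees, inherits, logical(1), "phylo")))
    msg <- c(msg, "'trees' must be a list of phylo objects")
  n <- length(object@trees)
  for (r in object@resamples) {
    if (any(r < 1L) || any(r > n) || anyDuplicated(r))
      msg <- c(msg, "resample indices must be distinct and within 1..n")
  }
  if (length(msg)) msg else TRUE
})
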