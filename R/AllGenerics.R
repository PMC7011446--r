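#' Accessors for wgdinfer containers
#'
#' Small accessor generics so downstream code never reaches into slots.
#'
#' @param x a wgdinfer S4 object.
#' @return `ksValues` returns the numeric Ks vector; `speciesId` the species
#'   identifier; `nullRate` the fitted decay rate; `mixtureComponents` a
#'   data.frame (weight, mean, sd); `profileTable` a data.frame (node,
#'   nSubtrees, nDup, pctDup); `simTrees` the list of `phylo` gene trees;
#'   `simResamples` the list of resample index vectors.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ksValues", function(x) standardGeneric("ksValues"))

#' @rdname accessors
#' @export
setGeneric("speciesId", function(x) standardGeneric("speciesId"))

#' @rdname accessors
#' @export
setGeneric("nullRate", function(x) standardGeneric("nullRate"))

#' @rdname accessors
#' @export
setGeneric("mixtureComponents",
           function(x) standardGeneric("mixtureComponents"))

#' @rdname accessors
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname accessors
#' @export
setGeneric("simTrees", function(x) standardGeneric("simTrees"))

#' @rdname accessors
#' @export
setGeneric("simResamples", function(x) standardGeneric("simResamples"))

#' @rdname accessors
setMethod("ksValues", "AgeDistribution", function(x) x@ks)

#' @rdname accessors
setMethod("speciesId", "AgeDistribution", function(x) x@species)

#' @rdname accessors
setMethod("nullRate", "KsNullModel", function(x) x@rate)

#' @rdname accessors
setMethod("mixtureComponents", "KsMixtureFit", function(x)
  data.frame(component = seq_len(x@k), weight = x@weight,
             mean = x@mean, sd = x@sd))

#' @rdname accessors
setMethod("profileTable", "MapsProfile", function(x)
  data.frame(node = x@node, nSubtrees = x@nSubtrees, nDup = x@nDup,
             pctDup = x@pctDup))

#' @rdname accessors
setMethod("simTrees", "SimulationSet", function(x) x@trees)

#' @rdname accessors
setMethod("simResamples", "SimulationSet", function(x) x@resamples)

setMethod("show", "AgeDistribution", function(object) {
  cat("AgeDistribution for", object@species, "\n")
  cat(" ", length(object@ks), "duplication-node Ks values (",
      object@nSaturated, "saturated excluded )\n")
  cat("  estimator:", object@estimator, "\n")
  if (length(object@ks))
    cat("  median Ks:", format(stats::median(object@ks), digits = 3), "\n")
})

setMethod("show", "KsNullModel", function(object) {
  cat("KsNullModel: truncated exponential on (",
      object@window[1], ",", object@window[2], "]\n")
  cat("  rate:", format(object@rate, digits = 4),
      " fitted from n =", object@n, "\n")
})

setMethod("show", "KsMixtureFit", function(object) {
  cat("KsMixtureFit:", object@k, "Gaussian component(s) on (",
      object@window[1], ",", object@window[2], "], n =", object@n, "\n")
  cat("  logLik:", format(object@logLik, digits = 6),
      " BIC:", format(object@bic, digits = 6),
      " converged:", object@converged, "\n")
  print(mixtureComponents(object), row.names = FALSE, digits = 3)
})

setMethod("show", "MapsProfile", function(object) {
  cat("MapsProfile over", length(object@node), "species-tree nodes,",
      object@nTrees, "gene trees, occupancy =", object@occupancy, "\n")
  print(profileTable(object), row.names = FALSE, digits = 4)
})

setMethod("show", "SimulationSet", function(object) {
  cfg <- object@config
  cat("SimulationSet:", length(object@trees), "gene trees,",
      length(object@resamples), "resamples\n")
  if (!is.null(cfg$lambda))
    cat("  lambda =", cfg$lambda, " mu =", cfg$mu, "\n")
  if (!is.null(cfg$wgd) && length(cfg$wgd))
    cat("  WGD at:", paste(vapply(cfg$wgd, `[[`, "", "node"),
                           collapse = ", "), "\n")
})
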