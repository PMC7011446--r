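## Fisher-exact comparison of observed MAPS profiles to null and positive
## simulation sets, per-node episode classification, and the
## total-evidence WGD caller.

#' Per-resample MAPS count matrices of a simulation set
#'
#' Computes per-tree subtree/duplication counts once and sums them over
#' each stored resample.
#'
#' @param set a [SimulationSet-class].
#' @param species species tree or [speciesIndex()] result.
#' @param occupancy minimum ingroup-taxa fraction (default 0.45).
#' @param delimiter taxon prefix delimiter.
#' @return list with `nSubtrees` and `nDup`, each a resamples x nodes
#'   integer matrix (node columns tip-most to root), plus `nodes`.
#' @export
resampleProfiles <- function(set, species, occupancy = 0.45,
                             delimiter = "_") {
  idx <- if (is.list(species) && !inherits(species, "phylo")) species
         else speciesIndex(species)
  per <- mapsProfile(simTrees(set), idx, occupancy, delimiter,
                     perTree = TRUE)
  res <- simResamples(set)
  if (!length(res)) res <- list(seq_along(simTrees(set)))
  sub <- t(vapply(res, function(ix) colSums(per$perTreeSub[ix, ,
                                                           drop = FALSE]),
                  numeric(length(idx$nodeLabels))))
  dup <- t(vapply(res, function(ix) colSums(per$perTreeDup[ix, ,
                                                           drop = FALSE]),
                  numeric(length(idx$nodeLabels))))
  list(nSubtrees = sub, nDup = dup, nodes = idx$nodeLabels)
}

.fisherOneSided <- function(obsDup, obsSub, simDup, simSub, alternative) {
  tab <- matrix(c(obsDup, obsSub - obsDup, simDup, simSub - simDup), 2, 2)
  stats::fisher.test(tab, alternative = alternative)$p.value
}

#' Fisher tests of an observed profile against null simulations
#'
#' For each species-tree node and each null resample, a 2x2 contingency
#' table (duplicated vs non-duplicated subtrees, observed vs null) is
#' tested one-sided for the observed data having MORE shared duplications.
#' A node is a significant episode of duplication (a burst) when the test
#' rejects at `alpha` in at least `fracRequired` of the resamples.
#'
#' @param observed a [MapsProfile-class].
#' @param null output of [resampleProfiles()] on the null set.
#' @param alpha per-test significance level (default 0.01).
#' @param fracRequired fraction of resamples that must reject (default
#'   0.95).
#' @return data.frame per node: node, obsDup, obsSubtrees, fracSignificant,
#'   burst, tested (FALSE when the node had no observed subtrees).
#' @export
fisherVsNull <- function(observed, null, alpha = 0.01,
                         fracRequired = 0.95) {
  pt <- profileTable(observed)
  stopifnot(identical(pt$node, null$nodes))
  rows <- lapply(seq_len(nrow(pt)), function(i) {
    if (pt$nSubtrees[i] == 0)
      return(data.frame(node = pt$node[i], obsDup = 0L, obsSubtrees = 0L,
                        fracSignificant = NA_real_, burst = FALSE,
                        tested = FALSE, stringsAsFactors = FALSE))
    p <- vapply(seq_len(nrow(null$nSubtrees)), function(j)
      .fisherOneSided(pt$nDup[i], pt$nSubtrees[i],
                      null$nDup[j, i], null$nSubtrees[j, i], "greater"),
      numeric(1))
    frac <- mean(p < alpha)
    data.frame(node = pt$node[i], obsDup = pt$nDup[i],
               obsSubtrees = pt$nSubtrees[i], fracSignificant = frac,
               burst = frac >= fracRequired, tested = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Fisher tests of an observed profile against positive simulations
#'
#' One-sided test of the observed shared-duplication proportion being
#' LOWER than each positive-simulation resample. A burst node is
#' consistent with the simulated WGD when the test fails to reject
#' (`p >= alpha`) in at least `fracRequired` of the positive resamples.
#'
#' @param observed a [MapsProfile-class].
#' @param positive output of [resampleProfiles()] on a positive set.
#' @param alpha per-test significance level (default 0.01).
#' @param fracRequired fraction of non-rejecting resamples required
#'   (default 0.5).
#' @return data.frame per node: node, fracConsistent, consistent, tested.
#' @export
fisherVsPositive <- function(observed, positive, alpha = 0.01,
                             fracRequired = 0.5) {
  pt <- profileTable(observed)
  stopifnot(identical(pt$node, positive$nodes))
  rows <- lapply(seq_len(nrow(pt)), function(i) {
    if (pt$nSubtrees[i] == 0)
      return(data.frame(node = pt$node[i], fracConsistent = NA_real_,
                        consistent = FALSE, tested = FALSE,
                        stringsAsFactors = FALSE))
    p <- vapply(seq_len(nrow(positive$nSubtrees)), function(j)
      .fisherOneSided(pt$nDup[i], pt$nSubtrees[i],
                      positive$nDup[j, i], positive$nSubtrees[j, i],
                      "less"),
      numeric(1))
    frac <- mean(p >= alpha)
    data.frame(node = pt$node[i], fracConsistent = frac,
               consistent = frac >= fracRequired, tested = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Classify per-node duplication episodes
#'
#' Combines the null-side and positive-side Fisher tests into the MAPS
#' decision: `background` (no significant excess over the null), `burst`
#' (significant excess but not consistent with a simulated WGD at that
#' node, or no positive set available), `WGD-consistent` (significant
#' excess and statistically consistent with the positive simulations).
#' Estimates at the tip-most and root nodes carry a low-confidence flag:
#' gene-tree error inflates duplication mapping at the ends of the ladder.
#'
#' @param nullTest data.frame from [fisherVsNull()].
#' @param positiveTests named list of [fisherVsPositive()] results, one
#'   per candidate node (names are node labels); may be empty.
#' @return data.frame per node: node, obsDup, obsSubtrees,
#'   fracSignificant, fracConsistent, classification, lowConfidence.
#' @export
episodeTests <- function(nullTest, positiveTests = list()) {
  k <- nrow(nullTest)
  rows <- lapply(seq_len(k), function(i) {
    node <- nullTest$node[i]
    fracCons <- NA_real_
    cls <- "background"
    if (isTRUE(nullTest$burst[i])) {
      cls <- "burst"
      pt <- positiveTests[[node]]
      if (!is.null(pt)) {
        row <- pt[pt$node == node, ]
        if (nrow(row) == 1 && isTRUE(row$tested)) {
          fracCons <- row$fracConsistent
          if (isTRUE(row$consistent)) cls <- "WGD-consistent"
        }
      }
    }
    data.frame(node = node, obsDup = nullTest$obsDup[i],
               obsSubtrees = nullTest$obsSubtrees[i],
               fracSignificant = nullTest$fracSignificant[i],
               fracConsistent = fracCons, classification = cls,
               lowConfidence = i == 1L || i == k,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Total-evidence WGD calls
#'
#' Weighs the three evidence lines for each candidate placement: a Ks-plot
#' peak, the ortholog-divergence placement, and the MAPS episode test. A
#' WGD is called when at least two lines support the placement and MAPS
#' does not contradict the other two; Ks-plot plus ortholog support with a
#' non-supporting MAPS result is recorded as a significant burst of gene
#' duplication; conflicting placements yield no call.
#'
#' @param evidence data.frame with columns `placement` (character label of
#'   the candidate branch), `ksSupport` (logical), `orthoSupport`
#'   (logical), `mapsSupport` (logical or NA when no MAPS analysis covers
#'   the placement) and optionally `conflict` (logical).
#' @return the input with added columns `nSupport` and `verdict`
#'   (`"WGD"`, `"significant-burst"`, `"none"`).
#' @export
totalEvidence <- function(evidence) {
  if (!nrow(evidence)) {
    evidence$nSupport <- integer(0)
    evidence$verdict <- character(0)
    return(evidence)
  }
  if (is.null(evidence$conflict)) evidence$conflict <- FALSE
  n <- nrow(evidence)
  nSupport <- integer(n)
  verdict <- character(n)
  for (i in seq_len(n)) {
    ks <- isTRUE(evidence$ksSupport[i])
    ortho <- isTRUE(evidence$orthoSupport[i])
    maps <- evidence$mapsSupport[i]
    nSupport[i] <- ks + ortho + isTRUE(maps)
    verdict[i] <-
      if (isTRUE(evidence$conflict[i])) "none"
      else if (ks && ortho && !is.na(maps) && !isTRUE(maps))
        "significant-burst"
      else if (nSupport[i] >= 2) "WGD"
      else "none"
  }
  evidence$nSupport <- nSupport
  evidence$verdict <- verdict
  evidence
}

#' Full MAPS inference for an observed tree collection
#'
#' Convenience wrapper: computes the observed profile, builds (or accepts)
#' a null set, runs the null-side Fisher tests, then builds positive sets
#' for every burst node and classifies each node.
#'
#' @param trees list of observed `phylo` gene trees (already
#'   family-filtered).
#' @param species rooted `phylo` species tree with branch lengths.
#' @param lambda,mu background rates for the simulations; when NULL they
#'   are estimated from the observed trees' copy counts via
#'   [estimateRates()].
#' @param occupancy minimum ingroup-taxa fraction (default 0.45).
#' @param r retention probability for positive simulations (default 0.2).
#' @param n,subset,nResamples simulation-set sizes (defaults 3000, 1000,
#'   100).
#' @param seed master seed.
#' @param alpha Fisher significance level (default 0.01).
#' @param delimiter taxon prefix delimiter.
#' @return list: `profile` ([MapsProfile-class]), `rates`, `nullTest`,
#'   `positiveTests`, `episodes` (data.frame from [episodeTests()]).
#' @export
mapsInference <- function(trees, species, lambda = NULL, mu = NULL,
                          occupancy = 0.45, r = 0.2, n = 3000,
                          subset = 1000, nResamples = 100, seed = 1,
                          alpha = 0.01, delimiter = "_") {
  idx <- speciesIndex(species)
  obs <- mapsProfile(trees, idx, occupancy, delimiter)
  rates <- NULL
  if (is.null(lambda) || is.null(mu)) {
    cc <- copyCounts(trees, idx$taxa, delimiter)
    rates <- estimateRates(cc, idx$tree)
    lambda <- rates$lambda
    mu <- rates$mu
  }
  seeds <- deriveSeeds(seed, 2L + length(idx$nodeLabels))
  nullSet <- buildNullSet(idx$tree, lambda, mu, n = n, subset = subset,
                          nResamples = nResamples, seed = seeds[1])
  nullRes <- resampleProfiles(nullSet, idx, occupancy, delimiter)
  nullTest <- fisherVsNull(obs, nullRes, alpha = alpha)
  positiveTests <- list()
  for (i in which(nullTest$burst)) {
    node <- nullTest$node[i]
    posSet <- buildPositiveSet(idx$tree, lambda, mu, wgdNode = node,
                               r = r, n = n, subset = subset,
                               nResamples = nResamples,
                               seed = seeds[2 + i])
    posRes <- resampleProfiles(posSet, idx, occupancy, delimiter)
    positiveTests[[node]] <- fisherVsPositive(obs, posRes, alpha = alpha)
  }
  list(profile = obs, rates = rates, nullTest = nullTest,
       positiveTests = positiveTests,
       episodes = episodeTests(nullTest, positiveTests))
}
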