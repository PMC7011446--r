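## Reciprocal-best-hit orthology, ortholog Ks divergence summaries and the
## paralog-vs-ortholog placement rule for WGDs.

.bestHitPerQuery <- function(hits) {
  if (!nrow(hits))
    return(hits[0, c("query", "subject", "identity", "bitscore")])
  ord <- order(hits$query, -hits$bitscore, -hits$identity, hits$subject,
               method = "radix")
  h <- hits[ord, , drop = FALSE]
  h[!duplicated(h$query), c("query", "subject", "identity", "bitscore"),
    drop = FALSE]
}

#' Reciprocal best hits between two transcriptomes
#'
#' Orthologs are taken as reciprocal best BLAST hits: gene a's best hit in
#' species B is b, and b's best hit in species A is a. The best hit per
#' query is chosen by bitscore, ties broken by higher identity and then by
#' lexicographically smaller subject id.
#'
#' @param hitsAB BLAST tabular data.frame, species A queries vs B subjects.
#' @param hitsBA the reverse search, B queries vs A subjects.
#' @return data.frame with columns geneA, geneB, one row per ortholog
#'   pair, sorted by geneA.
#' @export
reciprocalBestHits <- function(hitsAB, hitsBA) {
  bestAB <- .bestHitPerQuery(hitsAB)
  bestBA <- .bestHitPerQuery(hitsBA)
  backOf <- stats::setNames(bestBA$subject, bestBA$query)
  keep <- !is.na(backOf[bestAB$subject]) &
    backOf[bestAB$subject] == bestAB$query
  keep[is.na(keep)] <- FALSE
  out <- data.frame(geneA = bestAB$query[keep],
                    geneB = bestAB$subject[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$geneA, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise ortholog synonymous divergence
#'
#' Mean and median Ks over unsaturated ortholog pairs for one species pair.
#'
#' @param ks numeric vector of per-pair ortholog Ks values; NA marks
#'   saturated or failed pairs and is excluded.
#' @param speciesPair length-2 character, the two species.
#' @param minPairs minimum number of usable pairs (default 20).
#' @return data.frame with one row: speciesA, speciesB, n, meanKs,
#'   medianKs.
#' @export
orthologDivergence <- function(ks, speciesPair = c("A", "B"),
                               minPairs = 20) {
  ks <- ks[!is.na(ks)]
  if (length(ks) < minPairs)
    stop(errorCondition(
      paste0("only ", length(ks), " usable ortholog pairs; need ",
             minPairs),
      class = c("wgdinfer_insufficient", "error", "condition")))
  data.frame(speciesA = speciesPair[1], speciesB = speciesPair[2],
             n = length(ks), meanKs = mean(ks),
             medianKs = stats::median(ks), stringsAsFactors = FALSE)
}

#' Place a WGD peak relative to a lineage divergence
#'
#' If the median Ks of the WGD paralogs is younger (smaller) than the
#' median ortholog divergence between two species, the WGD postdates their
#' split (`"after-divergence"`); if it is older (larger), the WGD is shared
#' by the two lineages (`"shared"`). Near-equal medians are left
#' `"unresolved"`. With `ci` given, the verdict is also unresolved whenever
#' the peak's 95% CI contains the ortholog median.
#'
#' @param peakMedian median Ks of the WGD paralog peak (from
#'   [callPeaks()]).
#' @param orthologMedian median ortholog Ks of the species pair.
#' @param margin half-width of the unresolved band (default 0: strict
#'   comparison of point medians).
#' @param ci optional length-2 numeric, the peak's 95% CI.
#' @return single character verdict: `"shared"`, `"after-divergence"` or
#'   `"unresolved"`.
#' @examples
#' placeWgd(0.3, 0.18)  # "shared"
#' placeWgd(0.3, 0.6)   # "after-divergence"
#' @export
placeWgd <- function(peakMedian, orthologMedian, margin = 0, ci = NULL) {
  if (!is.null(ci) && orthologMedian >= ci[1] && orthologMedian <= ci[2])
    return("unresolved")
  if (peakMedian < orthologMedian - margin) "after-divergence"
  else if (peakMedian > orthologMedian + margin) "shared"
  else "unresolved"
}

#' Placement table for a set of peaks against a set of divergences
#'
#' @param peaks data.frame from [callPeaks()] (only rows with
#'   `isPeak = TRUE` are placed).
#' @param divergences data.frame of rows from [orthologDivergence()].
#' @param margin,useCi placement options; `useCi = TRUE` applies the
#'   CI-overlap unresolved rule.
#' @return data.frame: peak component, peak median, speciesA, speciesB,
#'   orthologMedian, verdict.
#' @export
placementTable <- function(peaks, divergences, margin = 0, useCi = FALSE) {
  pk <- peaks[peaks$isPeak, , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(pk))) for (j in seq_len(nrow(divergences))) {
    ci <- if (useCi) c(pk$ciLo[i], pk$ciHi[i]) else NULL
    rows[[length(rows) + 1L]] <- data.frame(
      component = pk$component[i], peakMedian = pk$median[i],
      speciesA = divergences$speciesA[j],
      speciesB = divergences$speciesB[j],
      orthologMedian = divergences$medianKs[j],
      verdict = placeWgd(pk$median[i], divergences$medianKs[j],
                         margin, ci),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(component = integer(0), peakMedian = numeric(0),
                      speciesA = character(0), speciesB = character(0),
                      orthologMedian = numeric(0), verdict = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
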