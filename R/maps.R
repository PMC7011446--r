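## MAPS gene-tree sorting: map duplications onto a ladderized species tree
## by the species-overlap criterion, filter subtrees by ingroup occupancy,
## and aggregate per-node shared-duplication percentages.

.popcount <- function(x) {
  n <- integer(length(x))
  while (any(x > 0L)) {
    n <- n + bitwAnd(x, 1L)
    x <- bitwShiftR(x, 1L)
  }
  n
}

.childrenList <- function(tree) {
  split(tree$edge[, 2], tree$edge[, 1])
}

# postorder taxon bitmasks for every node of a (binary, rooted) tree
.nodeMasks <- function(tree, bitOf, delimiter) {
  nt <- length(tree$tip.label)
  taxa <- taxonFromLabel(tree$tip.label, delimiter)
  unknown <- setdiff(taxa, names(bitOf))
  if (length(unknown))
    stop("unknown taxon in gene tree: ", paste(unique(unknown),
                                               collapse = ", "))
  masks <- integer(nt + tree$Nnode)
  masks[seq_len(nt)] <- bitOf[taxa]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(po)))
    masks[po[i, 1]] <- bitwOr(masks[po[i, 1]], masks[po[i, 2]])
  masks
}

#' Validate a ladderized species tree and number its nodes
#'
#' MAPS species trees are pectinate (fully asymmetric) and their internal
#' nodes are numbered N1 for the tip-most node up to Nk for the root.
#' Trees with 6-8 taxa match the intended analysis scale; other sizes are
#' accepted with a warning.
#'
#' @param tree a rooted `phylo` over taxon identifiers.
#' @return character vector `c("N1", ..., "Nk")`, tip-most to root.
#' @examples
#' sp <- ape::read.tree(text = "((((A,B),C),D),E);")
#' validateSpeciesTree(sp)
#' @export
validateSpeciesTree <- function(tree) {
  idx <- speciesIndex(tree)
  nt <- length(tree$tip.label)
  if (nt < 6 || nt > 8)
    warning("species tree has ", nt,
            " taxa; MAPS analyses are designed for 6-8")
  idx$nodeLabels
}

#' Build the lookup index of a ladder species tree
#'
#' Internal nodes are ordered by clade size (tip-most first) and labelled
#' N1..Nk; taxa are assigned bit positions so clade membership tests are
#' bitmask operations.
#'
#' @param tree rooted pectinate `phylo` over taxon ids.
#' @return a list: `taxa`, `bitOf` (named int), `nodeLabels`, `cladeMask`,
#'   `daughterMasks` (list of 2-int), `minTaxaAt` closure input sizes.
#' @keywords internal
#' @export
speciesIndex <- function(tree) {
  if (!ape::is.rooted(tree)) stop("species tree must be rooted")
  if (!ape::is.binary(tree)) tree <- binarizeTree(tree)
  nt <- length(tree$tip.label)
  taxa <- tree$tip.label
  bitOf <- stats::setNames(bitwShiftL(1L, seq_len(nt) - 1L), taxa)
  masks <- .nodeMasks(tree, bitOf, delimiter = "\u0001")  # tips are taxa
  internal <- (nt + 1L):(nt + tree$Nnode)
  sizes <- .popcount(masks[internal])
  if (anyDuplicated(sizes) || !setequal(sizes, 2:nt)) {
    bad <- internal[which(duplicated(sizes))[1]]
    if (is.na(bad)) bad <- internal[1]
    stop("species tree is not pectinate: node with clade {",
         paste(taxa[.maskTaxa(masks[bad], bitOf)], collapse = ","),
         "} violates the ladder structure")
  }
  ord <- internal[order(sizes)]
  kids <- .childrenList(tree)
  daughterMasks <- lapply(ord, function(nd)
    masks[kids[[as.character(nd)]]])
  list(taxa = taxa, bitOf = bitOf,
       nodeLabels = paste0("N", seq_along(ord)),
       nodeIds = ord,
       cladeMask = masks[ord],
       daughterMasks = daughterMasks,
       tipMask = masks[seq_len(nt)],
       tree = tree)
}

.maskTaxa <- function(mask, bitOf) {
  which(bitwAnd(mask, bitOf) > 0L)
}

# species node (label) that is the MRCA of a taxon bitmask
.speciesMrca <- function(mask, idx) {
  tipHit <- which(idx$tipMask == mask)
  if (length(tipHit)) return(idx$taxa[tipHit[1]])
  super <- which(bitwAnd(idx$cladeMask, mask) == mask)
  idx$nodeLabels[super[1]]  # cladeMask ordered by size; first = smallest
}

#' Map gene-tree duplications onto the species tree
#'
#' Walks the gene tree in postorder applying the species-overlap criterion:
#' an internal gene-tree node is a duplication when the taxon sets of its
#' two child clades share at least one taxon. Each duplication is mapped to
#' the species-tree most recent common ancestor of the union of the child
#' taxon sets (a taxon name when the union is a single taxon, i.e. a
#' terminal-branch duplication).
#'
#' @param gene rooted binary `phylo` gene tree with `taxon<delim>gene`
#'   leaf labels.
#' @param species rooted pectinate `phylo` species tree, or an index from
#'   [speciesIndex()].
#' @param delimiter taxon prefix delimiter in gene leaf labels.
#' @return data.frame with one row per duplication: geneNode (ape node
#'   number), speciesNode (label `"Ni"` or taxon name), nLeft, nRight
#'   (distinct taxa in each child clade), leftTaxa, rightTaxa
#'   (comma-separated).
#' @export
mapDuplications <- function(gene, species, delimiter = "_") {
  idx <- if (is.list(species) && !inherits(species, "phylo")) species
         else speciesIndex(species)
  if (!ape::is.binary(gene)) gene <- binarizeTree(gene)
  nt <- length(gene$tip.label)
  masks <- .nodeMasks(gene, idx$bitOf, delimiter)
  kids <- .childrenList(gene)
  nodes <- (nt + 1L):(nt + gene$Nnode)
  geneNode <- nLeft <- nRight <- integer(0)
  speciesNode <- leftTaxa <- rightTaxa <- character(0)
  for (nd in nodes) {
    ch <- kids[[as.character(nd)]]
    mL <- masks[ch[1]]; mR <- masks[ch[2]]
    if (bitwAnd(mL, mR) == 0L) next
    geneNode <- c(geneNode, nd)
    speciesNode <- c(speciesNode, .speciesMrca(bitwOr(mL, mR), idx))
    nLeft <- c(nLeft, .popcount(mL))
    nRight <- c(nRight, .popcount(mR))
    leftTaxa <- c(leftTaxa,
                  paste(idx$taxa[.maskTaxa(mL, idx$bitOf)], collapse = ","))
    rightTaxa <- c(rightTaxa,
                   paste(idx$taxa[.maskTaxa(mR, idx$bitOf)], collapse = ","))
  }
  structure(list(geneNode = geneNode, speciesNode = speciesNode,
                 nLeft = nLeft, nRight = nRight,
                 leftTaxa = leftTaxa, rightTaxa = rightTaxa),
            class = "data.frame",
            row.names = c(NA_integer_, -length(geneNode)))
}

# per-tree subtree/duplication counts at each species node; the workhorse
# behind collectSubtrees and mapsProfile
.treeNodeCounts <- function(gene, idx, occupancy, delimiter = "_",
                            detail = FALSE) {
  if (!ape::is.binary(gene)) gene <- binarizeTree(gene)
  nt <- length(gene$tip.label)
  masks <- .nodeMasks(gene, idx$bitOf, delimiter)
  kids <- .childrenList(gene)
  nNodes <- nt + gene$Nnode
  root <- nt + 1L
  parent <- integer(nNodes)
  parent[gene$edge[, 2]] <- gene$edge[, 1]
  k <- length(idx$nodeLabels)
  nSub <- nDup <- integer(k)
  recs <- if (detail) list()
  for (i in seq_len(k)) {
    Ci <- idx$cladeMask[i]
    d1 <- idx$daughterMasks[[i]][1]
    d2 <- idx$daughterMasks[[i]][2]
    minTaxa <- ceiling(occupancy * .popcount(Ci))
    for (v in seq_len(nNodes)) {
      m <- masks[v]
      if (bitwAnd(m, Ci) != m) next                  # not within clade(Ni)
      if (v != root && bitwAnd(masks[parent[v]], Ci) == masks[parent[v]])
        next                                         # not maximal
      if (bitwAnd(m, d1) == 0L || bitwAnd(m, d2) == 0L) next
      if (.popcount(m) < minTaxa) next
      nSub[i] <- nSub[i] + 1L
      isDup <- FALSE
      if (v > nt) {
        ch <- kids[[as.character(v)]]
        mL <- masks[ch[1]]; mR <- masks[ch[2]]
        if (bitwAnd(mL, mR) != 0L &&
            .popcount(mL) >= minTaxa && .popcount(mR) >= minTaxa)
          isDup <- TRUE
      }
      if (isDup) nDup[i] <- nDup[i] + 1L
      if (detail)
        recs[[length(recs) + 1L]] <- data.frame(
          node = idx$nodeLabels[i], geneNode = v,
          nTaxa = .popcount(m), sharedDup = isDup,
          stringsAsFactors = FALSE)
    }
  }
  if (detail)
    list(nSubtrees = nSub, nDup = nDup,
         records = if (length(recs)) do.call(rbind, recs)
                   else data.frame(node = character(0),
                                   geneNode = integer(0),
                                   nTaxa = integer(0),
                                   sharedDup = logical(0)))
  else list(nSubtrees = nSub, nDup = nDup)
}

#' Collect occupancy-filtered subtrees of one gene tree
#'
#' For each species-tree node Ni, finds the maximal gene-tree clades whose
#' taxon set lies within clade(Ni), contains taxa from both daughter
#' lineages of Ni, and has at least `ceiling(occupancy * |clade(Ni)|)`
#' distinct ingroup taxa. A counted subtree is a shared duplication at Ni
#' when its root is a duplication (species-overlap) and each of its two
#' child clades independently meets the occupancy minimum.
#'
#' @param gene rooted binary `phylo` gene tree.
#' @param species species tree or [speciesIndex()] result.
#' @param occupancy minimum ingroup-taxa fraction (default 0.45).
#' @param delimiter taxon prefix delimiter.
#' @return list with `counts` (data.frame node, nSubtrees, nDup) and
#'   `records` (one row per counted subtree).
#' @export
collectSubtrees <- function(gene, species, occupancy = 0.45,
                            delimiter = "_") {
  idx <- if (is.list(species) && !inherits(species, "phylo")) species
         else speciesIndex(species)
  res <- .treeNodeCounts(gene, idx, occupancy, delimiter, detail = TRUE)
  list(counts = data.frame(node = idx$nodeLabels,
                           nSubtrees = res$nSubtrees, nDup = res$nDup,
                           stringsAsFactors = FALSE),
       records = res$records)
}

#' Aggregate a MAPS profile over a collection of gene trees
#'
#' Sums [collectSubtrees()] counts over all gene trees and converts them to
#' the percentage of subtrees containing a shared duplication at each
#' species-tree node.
#'
#' @param trees list of rooted `phylo` gene trees.
#' @param species species tree or [speciesIndex()] result.
#' @param occupancy minimum ingroup-taxa fraction (default 0.45).
#' @param delimiter taxon prefix delimiter.
#' @param perTree if TRUE, also return the per-tree count matrices (used
#'   by the resampling machinery).
#' @return a [MapsProfile-class]; with `perTree = TRUE`, a list
#'   `(profile, perTreeSub, perTreeDup)` where the matrices are
#'   trees x nodes.
#' @export
mapsProfile <- function(trees, species, occupancy = 0.45,
                        delimiter = "_", perTree = FALSE) {
  if (!length(trees)) stop("need at least one gene tree")
  idx <- if (is.list(species) && !inherits(species, "phylo")) species
         else speciesIndex(species)
  k <- length(idx$nodeLabels)
  subM <- dupM <- matrix(0L, length(trees), k)
  for (i in seq_along(trees)) {
    res <- .treeNodeCounts(trees[[i]], idx, occupancy, delimiter)
    subM[i, ] <- res$nSubtrees
    dupM[i, ] <- res$nDup
  }
  nSub <- colSums(subM)
  nDup <- colSums(dupM)
  prof <- new("MapsProfile", node = idx$nodeLabels,
              nSubtrees = as.integer(nSub), nDup = as.integer(nDup),
              pctDup = ifelse(nSub > 0, 100 * nDup / nSub, NA_real_),
              occupancy = occupancy, nTrees = length(trees))
  if (perTree) list(profile = prof, perTreeSub = subM, perTreeDup = dupM)
  else prof
}

#' Filter gene trees by full taxon representation
#'
#' MAPS analyses use only gene families with at least one gene copy from
#' every taxon: a tree is kept when its leaf taxon set equals the full
#' analysis taxon set.
#'
#' @param trees list of `phylo` gene trees.
#' @param taxa character vector, the full analysis taxon set.
#' @param delimiter taxon prefix delimiter.
#' @return the retained sublist of `trees`.
#' @export
familyFilter <- function(trees, taxa, delimiter = "_") {
  keep <- vapply(trees, function(tr)
    setequal(unique(taxonFromLabel(tr$tip.label, delimiter)), taxa),
    logical(1))
  trees[keep]
}

#' Write a MAPS profile as TSV
#'
#' @param profile a [MapsProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMapsProfile <- function(profile, path) {
  utils::write.table(profileTable(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
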