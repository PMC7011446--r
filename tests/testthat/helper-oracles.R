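## Independent oracle implementations used to validate the package's
## algorithmic components. These deliberately avoid the package's own
## machinery (bitmasks, igraph, precomputed codon tables) and recompute
## everything from first principles with different algorithms.

## ---- canonical species trees ------------------------------------------

ladder4 <- function() ape::read.tree(text = "(((A:1,B:1):1,C:2):1,D:3);")

ladder6 <- function()
  ape::read.tree(text = "(((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5);")

ladder6deep <- function()
  ape::read.tree(
    text = "(((((A:50,B:50):50,C:100):50,D:150):50,E:200):50,F:250);")

ladder7 <- function()
  ape::read.tree(
    text = "((((((A:1,B:1):1,C:2):1,D:3):1,E:4):1,F:5):1,G:6);")

## ---- DFS connected components -----------------------------------------

# iterative depth-first search over an adjacency list; returns a list of
# sorted character vectors, ordered by smallest member
oracleComponents <- function(pairs) {
  verts <- sort(unique(c(pairs$geneA, pairs$geneB)))
  adj <- lapply(stats::setNames(vector("list", length(verts)), verts),
                function(x) character(0))
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$geneA[i]; b <- pairs$geneB[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- stats::setNames(rep(FALSE, length(verts)), verts)
  comps <- list()
  for (v in verts) {
    if (seen[v]) next
    stack <- v
    members <- character(0)
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (seen[cur]) next
      seen[cur] <- TRUE
      members <- c(members, cur)
      stack <- c(stack, adj[[cur]][!seen[adj[[cur]]]])
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  first <- vapply(comps, `[`, "", 1)
  comps[order(first)]
}

## ---- codon-level NG86 oracle ------------------------------------------

# genetic code rebuilt from the classic 64-character translation string
# (codon order: first base slowest, bases in T, C, A, G order)
.oracleCode <- local({
  bases <- c("T", "C", "A", "G")
  aa <- strsplit(paste0("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
                        "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
  codons <- character(64)
  k <- 0L
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aa, codons)
})

oracleTranslate <- function(codon) unname(.oracleCode[codon])

# synonymous site fraction of one codon: 1/3 per single-base change that
# preserves the amino acid without creating a stop
oracleSynFrac <- function(codon) {
  aa0 <- oracleTranslate(codon)
  tot <- 0
  for (pos in 1:3) for (b in c("T", "C", "A", "G")) {
    if (substr(codon, pos, pos) == b) next
    alt <- codon
    substr(alt, pos, pos) <- b
    aaA <- oracleTranslate(alt)
    if (aaA != "*" && aaA == aa0) tot <- tot + 1 / 3
  }
  tot
}

# recursive enumeration of all mutational pathways between two codons;
# each complete path yields (synonymous steps, nonsynonymous steps,
# passed-through-stop flag); stop-free paths are averaged, falling back
# to all paths when every pathway hits a stop
oraclePathDiffs <- function(c1, c2) {
  rec <- function(cur, remaining) {
    if (!length(remaining)) return(list(c(0, 0, 0)))
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      syn <- oracleTranslate(nxt) == oracleTranslate(cur)
      hitStop <- oracleTranslate(nxt) == "*"
      for (tail in rec(nxt, setdiff(remaining, p)))
        out[[length(out) + 1L]] <-
          c(syn, !syn, hitStop) + tail
    }
    out
  }
  diffPos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(diffPos)) return(c(0, 0))
  paths <- do.call(rbind, rec(c1, diffPos))
  ok <- paths[, 3] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(paths))
  c(mean(paths[ok, 1]), mean(paths[ok, 2]))
}

# full NG86 Ks recomputation for two aligned coding sequences
oracleKs <- function(seqA, seqB) {
  toCodons <- function(s) {
    s <- toupper(chartr("u", "T", chartr("U", "T", s)))
    n <- nchar(s)
    vapply(seq_len(n / 3), function(i)
      substr(s, 3 * i - 2, 3 * i), "")
  }
  ca <- toCodons(seqA)
  cb <- toCodons(seqB)
  ok <- ca %in% names(.oracleCode) & cb %in% names(.oracleCode) &
    oracleTranslate(ca) != "*" & oracleTranslate(cb) != "*"
  ca <- ca[ok]; cb <- cb[ok]
  S <- (sum(vapply(ca, oracleSynFrac, 0)) +
          sum(vapply(cb, oracleSynFrac, 0))) / 2
  d <- vapply(seq_along(ca), function(i) oraclePathDiffs(ca[i], cb[i]),
              numeric(2))
  Sd <- sum(d[1, ]); Nd <- sum(d[2, ])
  pS <- Sd / S
  list(ks = -0.75 * log(1 - 4 * pS / 3), S = S, N = 3 * length(ca) - S,
       Sd = Sd, Nd = Nd, pS = pS)
}

# random in-frame coding sequence without stop codons (uses current RNG)
randCds <- function(nCodons) {
  pool <- names(.oracleCode)[.oracleCode != "*"]
  paste(sample(pool, nCodons, replace = TRUE), collapse = "")
}

# mutate random positions of a sequence (uses current RNG)
mutateSeq <- function(seq, nMut) {
  s <- strsplit(seq, "")[[1]]
  pos <- sample(length(s), nMut)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1)
  paste(s, collapse = "")
}

## ---- duplication-mapping oracles --------------------------------------

# children list computed directly from the edge matrix
.oracleKids <- function(tree) {
  kids <- vector("list", length(tree$tip.label) + tree$Nnode)
  for (i in seq_len(nrow(tree$edge)))
    kids[[tree$edge[i, 1]]] <- c(kids[[tree$edge[i, 1]]], tree$edge[i, 2])
  kids
}

# taxon set below each node, by plain recursion on the edge matrix
.oracleTaxaBelow <- function(tree, delimiter = "_") {
  nt <- length(tree$tip.label)
  kids <- .oracleKids(tree)
  taxa <- sub(paste0(delimiter, ".*$"), "", tree$tip.label)
  below <- vector("list", nt + tree$Nnode)
  rec <- function(node) {
    if (node <= nt) {
      below[[node]] <<- taxa[node]
    } else {
      below[[node]] <<- sort(unique(unlist(lapply(kids[[node]], rec))))
    }
    below[[node]]
  }
  rec(nt + 1L)
  below
}

# specialised oracle for the 4-taxon ladder (((A,B),C),D): apparent
# duplications by species overlap with a direct MRCA rule
oracleDupLadder4 <- function(gene, delimiter = "_") {
  nt <- length(gene$tip.label)
  kids <- .oracleKids(gene)
  below <- .oracleTaxaBelow(gene, delimiter)
  mrca <- function(u) {
    if (length(u) == 1) u
    else if (all(u %in% c("A", "B"))) "N1"
    else if (all(u %in% c("A", "B", "C"))) "N2"
    else "N3"
  }
  geneNode <- integer(0)
  speciesNode <- character(0)
  for (nd in (nt + 1L):(nt + gene$Nnode)) {
    ch <- kids[[nd]]
    L <- below[[ch[1]]]; R <- below[[ch[2]]]
    if (!length(intersect(L, R))) next
    geneNode <- c(geneNode, nd)
    speciesNode <- c(speciesNode, mrca(union(L, R)))
  }
  structure(list(geneNode = geneNode, speciesNode = speciesNode),
            class = "data.frame",
            row.names = c(NA_integer_, -length(geneNode)))
}

# general LCA-reconciliation oracle over any ladder species tree, using
# phangorn::Descendants and ape::getMRCA (machinery disjoint from the
# package's bitmask implementation)
oracleDupMap <- function(gene, species, delimiter = "_") {
  nt <- length(gene$tip.label)
  spNt <- length(species$tip.label)
  spClades <- phangorn::Descendants(species, (spNt + 1L):(spNt +
                                                            species$Nnode),
                                    type = "tips")
  sizes <- lengths(spClades)
  # ladder internal nodes labelled N1 (smallest clade) .. Nk (root)
  labelOfApe <- character(spNt + species$Nnode)
  labelOfApe[seq_len(spNt)] <- species$tip.label
  labelOfApe[(spNt + 1L):(spNt + species$Nnode)] <-
    paste0("N", rank(sizes))
  kids <- .oracleKids(gene)
  below <- .oracleTaxaBelow(gene, delimiter)
  rows <- list()
  for (nd in (nt + 1L):(nt + gene$Nnode)) {
    ch <- kids[[nd]]
    L <- below[[ch[1]]]; R <- below[[ch[2]]]
    if (!length(intersect(L, R))) next
    u <- union(L, R)
    spNode <- if (length(u) == 1) match(u, species$tip.label)
              else ape::getMRCA(species, u)
    rows[[length(rows) + 1L]] <-
      data.frame(geneNode = nd, speciesNode = labelOfApe[spNode],
                 stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(geneNode = integer(0), speciesNode = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

## ---- Fisher exact oracle ----------------------------------------------

# one-sided (greater) p-value of the 2x2 table [a b; c d] by direct
# hypergeometric enumeration with binomial coefficients
oracleFisherGreater <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; k <- a + c
  lo <- max(0, k - r2); hi <- min(k, r1)
  xs <- lo:hi
  probs <- exp(lchoose(r1, xs) + lchoose(r2, k - xs) -
                 lchoose(r1 + r2, k))
  sum(probs[xs >= a])
}

## ---- BLAST-table oracles ----------------------------------------------

# brute-force duplicate-pair filter: qualifying unordered pairs with the
# best identity (ties: longest alignment) among their qualifying rows
oracleFilterPairs <- function(hits, minIdentity = 40, minLength = 300) {
  best <- list()
  for (i in seq_len(nrow(hits))) {
    if (hits$query[i] == hits$subject[i]) next
    if (hits$identity[i] < minIdentity || hits$length[i] < minLength) next
    key <- paste(min(hits$query[i], hits$subject[i]),
                 max(hits$query[i], hits$subject[i]), sep = "\r")
    cand <- c(identity = hits$identity[i], length = hits$length[i])
    old <- best[[key]]
    if (is.null(old) || cand["identity"] > old["identity"] ||
        (cand["identity"] == old["identity"] &&
           cand["length"] > old["length"]))
      best[[key]] <- cand
  }
  if (!length(best))
    return(data.frame(geneA = character(0), geneB = character(0),
                      identity = numeric(0), length = numeric(0),
                      stringsAsFactors = FALSE))
  keys <- sort(names(best))
  ab <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  data.frame(geneA = ab[, 1], geneB = ab[, 2],
             identity = vapply(best[keys], `[[`, 0, "identity"),
             length = vapply(best[keys], `[[`, 0, "length"),
             row.names = NULL, stringsAsFactors = FALSE)
}

# brute-force reciprocal best hits with the bitscore/identity/subject
# tie-break, by explicit per-query scans
oracleRbh <- function(hitsAB, hitsBA) {
  bestOf <- function(hits) {
    out <- character(0)
    for (q in sort(unique(hits$query))) {
      h <- hits[hits$query == q, , drop = FALSE]
      h <- h[h$bitscore == max(h$bitscore), , drop = FALSE]
      h <- h[h$identity == max(h$identity), , drop = FALSE]
      out[q] <- min(h$subject)
    }
    out
  }
  bAB <- bestOf(hitsAB)
  bBA <- bestOf(hitsBA)
  keep <- !is.na(bBA[bAB]) & bBA[bAB] == names(bAB)
  keep[is.na(keep)] <- FALSE
  data.frame(geneA = names(bAB)[keep], geneB = unname(bAB[keep]),
             row.names = NULL, stringsAsFactors = FALSE)
}

# random BLAST-style hit table over given gene pools (uses current RNG)
randHits <- function(queries, subjects, n) {
  data.frame(query = sample(queries, n, replace = TRUE),
             subject = sample(subjects, n, replace = TRUE),
             identity = round(stats::runif(n, 20, 100), 1),
             length = sample(100:900, n, replace = TRUE),
             mismatch = 0L, gapopen = 0L, qstart = 1L, qend = 1L,
             sstart = 1L, send = 1L, evalue = 1e-20,
             bitscore = sample(50:500, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

## ---- misc --------------------------------------------------------------

# topology equality for rooted trees, via ape's canonical comparison
sameTopology <- function(a, b) {
  isTRUE(ape::all.equal.phylo(a, b, use.edge.length = FALSE))
}

# random gene tree with taxon_gene labels drawn from `taxa` (current RNG)
randGeneTree <- function(nLeaves, taxa) {
  tr <- ape::rtree(nLeaves, rooted = TRUE)
  tr$tip.label <- paste0(sample(taxa, nLeaves, replace = TRUE), "_",
                         seq_len(nLeaves))
  tr
}
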