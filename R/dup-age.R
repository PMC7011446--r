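## Duplicate-pair filtering, single-linkage gene families, NG86 Ks
## estimation and node-Ks age distributions.

#' Filter BLAST hits down to duplicate pairs
#'
#' Applies the duplicate-pair criterion used to seed gene families: a pair
#' of distinct sequences with at least `minIdentity` percent identity over
#' an alignment of at least `minLength` base pairs. Self-hits are dropped
#' and reciprocal rows (a,b)/(b,a) are collapsed, keeping the best identity
#' (then the longest alignment).
#'
#' @param hits data.frame from [readBlastTab()].
#' @param minIdentity minimum percent identity (default 40).
#' @param minLength minimum alignment length in bp (default 300).
#' @return data.frame with columns geneA, geneB (geneA < geneB), identity,
#'   length, sorted lexicographically; zero rows allowed.
#' @export
filterDuplicatePairs <- function(hits, minIdentity = 40, minLength = 300) {
  keep <- hits$query != hits$subject &
    hits$identity >= minIdentity & hits$length >= minLength
  h <- hits[keep, , drop = FALSE]
  out <- data.frame(geneA = pmin(h$query, h$subject),
                    geneB = pmax(h$query, h$subject),
                    identity = h$identity, length = h$length,
                    stringsAsFactors = FALSE)
  if (nrow(out)) {
    ord <- order(out$geneA, out$geneB, -out$identity, -out$length,
                 method = "radix")
    out <- out[ord, , drop = FALSE]
    out <- out[!duplicated(paste0(out$geneA, "\r", out$geneB)), ,
               drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Build gene families by single-linkage clustering
#'
#' Families are the connected components of the duplicate-pair graph: any
#' chain of pairs joins genes into one family.
#'
#' @param pairs data.frame from [filterDuplicatePairs()].
#' @return named list of character vectors (sorted member ids); the name of
#'   each family is `fam.<smallest member>`, and families are ordered by
#'   smallest member. Empty input gives an empty list.
#' @export
singleLinkageFamilies <- function(pairs) {
  if (!nrow(pairs)) return(stats::setNames(list(), character(0)))
  g <- igraph::graph_from_data_frame(pairs[, c("geneA", "geneB")],
                                     directed = FALSE)
  comp <- igraph::components(g)
  fams <- split(names(comp$membership), comp$membership)
  fams <- lapply(fams, function(x) sort(unname(x)))
  key <- vapply(fams, `[`, "", 1)
  fams <- fams[order(key, method = "radix")]
  names(fams) <- paste0("fam.", vapply(fams, `[`, "", 1))
  fams
}

## ---- NG86 codon machinery --------------------------------------------

# standard genetic code, codons in TCAG x TCAG x TCAG order
.ng86 <- local({
  bases <- c("T", "C", "A", "G")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases,
                            function(a, b) paste0(a, b)))
  codons <- sort(codons)
  aaStr <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L",
    CTT = "L", CTC = "L", CTA = "L", CTG = "L",
    ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V",
    TCT = "S", TCC = "S", TCA = "S", TCG = "S",
    CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T",
    GCT = "A", GCC = "A", GCA = "A", GCG = "A",
    TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
    CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
    AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E",
    TGT = "C", TGC = "C", TGA = "*", TGG = "W",
    CGT = "R", CGC = "R", CGA = "R", CGG = "R",
    AGT = "S", AGC = "S", AGA = "R", AGG = "R",
    GGT = "G", GGC = "G", GGA = "G", GGG = "G")
  aa <- aaStr[codons]
  isStop <- aa == "*"

  mutate <- function(codon, pos, base) {
    s <- strsplit(codon, "")[[1]]
    s[pos] <- base
    paste(s, collapse = "")
  }

  # synonymous site fraction per codon (changes to stop count nonsynonymous)
  synSites <- vapply(codons, function(cd) {
    if (aa[cd] == "*") return(NA_real_)
    tot <- 0
    for (pos in 1:3) {
      cur <- substr(cd, pos, pos)
      for (b in setdiff(bases, cur)) {
        alt <- mutate(cd, pos, b)
        if (aa[alt] != "*" && aa[alt] == aa[cd]) tot <- tot + 1 / 3
      }
    }
    tot
  }, numeric(1))

  # per ordered codon pair: mean synonymous / nonsynonymous differences over
  # mutational pathways (pathways through stop codons excluded; if none
  # avoid a stop, all pathways are averaged)
  pathDiffs <- function(c1, c2) {
    pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
    k <- length(pos)
    if (k == 0L) return(c(0, 0))
    perms <- if (k == 1L) list(pos)
             else if (k == 2L) list(pos, pos[2:1])
             else {
               idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                           c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
               lapply(idx, function(i) pos[i])
             }
    walk <- function(ord) {
      cur <- c1
      sd <- nd <- 0
      hitStop <- FALSE
      for (p in ord) {
        nxt <- mutate(cur, p, substr(c2, p, p))
        if (aa[nxt] == "*") hitStop <- TRUE
        if (aa[nxt] == aa[cur]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd, as.numeric(hitStop))
    }
    res <- vapply(perms, walk, numeric(3))
    ok <- res[3, ] == 0
    if (!any(ok)) ok <- rep(TRUE, ncol(res))
    c(mean(res[1, ok]), mean(res[2, ok]))
  }

  n <- length(codons)
  Sd <- Nd <- matrix(NA_real_, n, n, dimnames = list(codons, codons))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (isStop[i] || isStop[j]) next
    d <- pathDiffs(codons[i], codons[j])
    Sd[i, j] <- d[1]
    Nd[i, j] <- d[2]
  }
  list(codons = codons, aa = aa, isStop = isStop,
       synSites = synSites, Sd = Sd, Nd = Nd)
})

.splitCodons <- function(seq) {
  seq <- toupper(gsub("U", "T", seq, ignore.case = TRUE))
  n <- nchar(seq)
  if (n %% 3L != 0L)
    stop("aligned sequence length (", n, ") is not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Pairwise synonymous divergence (Ks) by codon counting
#'
#' Estimates Ks between two aligned in-frame coding sequences with the
#' Nei-Gojobori counting method: synonymous and nonsynonymous site fractions
#' are computed per codon and averaged over both sequences; observed
#' differences are classified by averaging over all minimal mutational
#' pathways between the two codons (pathways through stop codons excluded);
#' the proportion of synonymous differences is corrected for multiple hits
#' with the single-parameter (Jukes-Cantor-style) formula
#' `Ks = -3/4 log(1 - 4 pS / 3)`.
#'
#' Codons containing gaps or ambiguity characters in either sequence, and
#' stop codons, are skipped. At least `minCodons` comparable codons are
#' required. A corrected proportion `pS >= 3/4` cannot be corrected and
#' raises a saturation error of condition class `"wgdinfer_saturated"`;
#' too little data raises `"wgdinfer_insufficient"`.
#'
#' @param seqA,seqB character strings, aligned sequences of equal length
#'   divisible by 3 (`-` for gaps; `U` accepted for RNA).
#' @param minCodons minimum number of comparable codons (default 30).
#' @return a single numeric Ks value (>= 0), with attributes `S`, `N`,
#'   `Sd`, `Nd` (site and difference counts).
#' @examples
#' a <- strrep("ATGGCT", 50)
#' estimateKsPair(a, a)  # 0
#' @export
estimateKsPair <- function(seqA, seqB, minCodons = 30) {
  ca <- .splitCodons(seqA)
  cb <- .splitCodons(seqB)
  if (length(ca) != length(cb))
    stop("aligned sequences differ in length")
  ia <- match(ca, .ng86$codons)
  ib <- match(cb, .ng86$codons)
  ok <- !is.na(ia) & !is.na(ib) &
    !.ng86$isStop[ifelse(is.na(ia), 1L, ia)] &
    !.ng86$isStop[ifelse(is.na(ib), 1L, ib)]
  ia <- ia[ok]; ib <- ib[ok]
  if (length(ia) < minCodons)
    stop(errorCondition(
      paste0("only ", length(ia), " comparable codons (need ",
             minCodons, ")"),
      class = c("wgdinfer_insufficient", "error", "condition")))
  sA <- .ng86$synSites[ia]
  sB <- .ng86$synSites[ib]
  S <- (sum(sA) + sum(sB)) / 2
  N <- 3 * length(ia) - S
  idx <- cbind(ia, ib)
  Sd <- sum(.ng86$Sd[idx])
  Nd <- sum(.ng86$Nd[idx])
  pS <- Sd / S
  if (pS >= 0.75)
    stop(errorCondition(
      sprintf("synonymous proportion %.3f is saturated (>= 3/4)", pS),
      class = c("wgdinfer_saturated", "error", "condition")))
  ks <- -0.75 * log(1 - 4 * pS / 3)
  structure(max(ks, 0), S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Pairwise Ks matrix over a set of aligned sequences
#'
#' Applies [estimateKsPair()] to every pair; saturated or data-poor pairs
#' are recorded as NA and flagged.
#'
#' @param seqs named character vector of aligned, equal-length, in-frame
#'   sequences.
#' @param minCodons passed to [estimateKsPair()].
#' @return symmetric numeric matrix (diagonal 0, NA for unusable pairs)
#'   with a logical attribute `saturated` marking saturated pairs.
#' @export
ksMatrix <- function(seqs, minCodons = 30) {
  n <- length(seqs)
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  m <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  sat <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  diag(m) <- 0
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    v <- tryCatch(as.numeric(estimateKsPair(seqs[[i]], seqs[[j]],
                                            minCodons)),
                  wgdinfer_saturated = function(e) {
                    sat[i, j] <<- sat[j, i] <<- TRUE
                    NA_real_
                  },
                  wgdinfer_insufficient = function(e) NA_real_)
    m[i, j] <- m[j, i] <- v
  }
  attr(m, "saturated") <- sat
  m
}

#' Read a precomputed pairwise Ks table
#'
#' Pass-through for synonymous divergences estimated externally (e.g. by a
#' maximum-likelihood codon model): a TSV with columns gene_a, gene_b, ks.
#' Values < 0 are rejected; the string `"saturated"` (or NA) marks pairs to
#' exclude from distributions.
#'
#' @param path path to the TSV (header required).
#' @return symmetric Ks matrix over the union of gene ids, NA for saturated
#'   or missing pairs, with attribute `saturated`.
#' @export
readKsTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(tab) < 3)
    stop("Ks table needs at least 3 columns: gene_a, gene_b, ks")
  names(tab)[1:3] <- c("geneA", "geneB", "ks")
  ids <- sort(unique(c(tab$geneA, tab$geneB)))
  m <- matrix(NA_real_, length(ids), length(ids),
              dimnames = list(ids, ids))
  sat <- matrix(FALSE, length(ids), length(ids),
                dimnames = list(ids, ids))
  diag(m) <- 0
  isSat <- is.na(suppressWarnings(as.numeric(tab$ks)))
  ksNum <- suppressWarnings(as.numeric(tab$ks))
  if (any(ksNum[!isSat] < 0)) stop("negative Ks in table")
  idx <- cbind(match(tab$geneA, ids), match(tab$geneB, ids))
  m[idx] <- ksNum
  m[idx[, 2:1, drop = FALSE]] <- ksNum
  sat[idx] <- isSat
  sat[idx[, 2:1, drop = FALSE]] <- isSat
  attr(m, "saturated") <- sat
  m
}

#' Node Ks values from a gene-family tree
#'
#' Assigns each internal node of a family tree the age of the duplication it
#' represents: the median of the pairwise Ks values between the leaves of
#' its two child clades. Saturated (NA) pairs are ignored; a node with no
#' usable cross-pair is skipped.
#'
#' @param tree a rooted binary `phylo` over the family's genes.
#' @param ks symmetric Ks matrix covering all leaf pairs (from [ksMatrix()]
#'   or [readKsTable()]).
#' @return data.frame with columns node (ape node number), ks, nPairs.
#' @export
nodeKsFromTree <- function(tree, ks) {
  if (!all(tree$tip.label %in% rownames(ks)))
    stop("Ks matrix does not cover all leaves of the tree")
  nt <- length(tree$tip.label)
  nodes <- (nt + 1L):(nt + tree$Nnode)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  leafSet <- function(node) {
    if (node <= nt) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], leafSet))
  }
  out <- lapply(nodes, function(nd) {
    ch <- kids[[as.character(nd)]]
    if (length(ch) != 2L)
      stop("tree is not binary at node ", nd)
    left <- leafSet(ch[1])
    right <- leafSet(ch[2])
    vals <- as.vector(ks[left, right, drop = FALSE])
    vals <- vals[!is.na(vals)]
    if (!length(vals)) return(NULL)
    data.frame(node = nd, ks = stats::median(vals), nPairs = length(vals))
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(node = integer(0), ks = numeric(0),
                      nPairs = integer(0))
  rownames(out) <- NULL
  out
}

#' Construct an AgeDistribution
#'
#' @param species species identifier.
#' @param ks numeric vector of node Ks values.
#' @param familyId,nodeId optional character vectors parallel to `ks`.
#' @param nSaturated number of duplication nodes excluded as saturated.
#' @param estimator label of the Ks estimator used.
#' @param filters named list of upstream filter settings.
#' @return an [AgeDistribution-class] object.
#' @export
ageDistribution <- function(species, ks, familyId = character(0),
                            nodeId = character(0), nSaturated = 0L,
                            estimator = "NG86", filters = list()) {
  new("AgeDistribution", species = as.character(species),
      ks = as.numeric(ks), familyId = as.character(familyId),
      nodeId = as.character(nodeId), nSaturated = as.integer(nSaturated),
      estimator = estimator, filters = filters)
}

#' Write / read a node-Ks age distribution as TSV
#'
#' The on-disk form mirrors the released DupPipe output: a tab-delimited
#' file with one row per duplication node (family_id, node_id, ks), Ks
#' written with full precision.
#'
#' @param ages an [AgeDistribution-class] object.
#' @param path output (input) path.
#' @param species species id to attach on reading.
#' @return `writeAgeDistribution` returns `path` invisibly;
#'   `readAgeDistribution` returns an [AgeDistribution-class].
#' @export
writeAgeDistribution <- function(ages, path) {
  n <- length(ages@ks)
  fam <- if (length(ages@familyId)) ages@familyId else rep(NA_character_, n)
  nid <- if (length(ages@nodeId)) ages@nodeId else rep(NA_character_, n)
  tab <- data.frame(family_id = fam, node_id = nid,
                    ks = formatC(ages@ks, digits = 10, format = "g"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeAgeDistribution
#' @export
readAgeDistribution <- function(path, species = NA_character_) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("family_id", "node_id", "ks") %in% names(tab)))
    stop("not an age-distribution TSV (need family_id, node_id, ks): ",
         path)
  ageDistribution(species, ks = as.numeric(tab$ks),
                  familyId = as.character(tab$family_id),
                  nodeId = as.character(tab$node_id),
                  estimator = "file")
}

#' Gene-age distribution from hits, sequences and family trees
#'
#' End-to-end DupPipe-style construction: duplicate pairs are filtered from
#' the hit table, single-linkage families built, Ks estimated for every
#' within-family pair (or taken from `ksTable`), and node Ks values read off
#' each family's tree. Two-member families need no tree (the single pair is
#' the duplication node); larger families use the supplied tree whose leaf
#' set matches, and are skipped with a warning when none matches.
#'
#' @param hits BLAST tabular data.frame ([readBlastTab()]).
#' @param sequences named character vector of aligned in-frame CDS (may be
#'   NULL when `ksTable` is given).
#' @param species species identifier for the result.
#' @param trees optional list of `phylo` family trees.
#' @param ksTable optional precomputed Ks matrix ([readKsTable()]).
#' @param minIdentity,minLength duplicate-pair thresholds.
#' @param minCodons passed to [estimateKsPair()].
#' @return an [AgeDistribution-class] object.
#' @export
dupPipe <- function(hits, sequences = NULL, species = "sample",
                    trees = NULL, ksTable = NULL,
                    minIdentity = 40, minLength = 300, minCodons = 30) {
  pairs <- filterDuplicatePairs(hits, minIdentity, minLength)
  fams <- singleLinkageFamilies(pairs)
  ksAll <- numeric(0); famAll <- character(0); nodeAll <- character(0)
  nSat <- 0L
  treeKey <- if (!is.null(trees))
    vapply(trees, function(t) paste(sort(t$tip.label), collapse = "|"), "")
  for (fid in names(fams)) {
    members <- fams[[fid]]
    km <- if (!is.null(ksTable)) {
      if (!all(members %in% rownames(ksTable))) next
      ksTable[members, members, drop = FALSE]
    } else {
      if (!all(members %in% names(sequences))) next
      ksMatrix(sequences[members], minCodons)
    }
    satM <- attr(km, "saturated")
    if (length(members) == 2L) {
      v <- km[1, 2]
      if (is.na(v)) {
        if (!is.null(satM) && isTRUE(satM[1, 2])) nSat <- nSat + 1L
        next
      }
      ksAll <- c(ksAll, v); famAll <- c(famAll, fid)
      nodeAll <- c(nodeAll, "1")
    } else {
      key <- paste(members, collapse = "|")
      hit <- if (!is.null(trees)) which(treeKey == key) else integer(0)
      if (!length(hit)) {
        warning("no family tree for ", fid, " (", length(members),
                " members); skipped")
        next
      }
      nk <- nodeKsFromTree(trees[[hit[1]]], km)
      if (!is.null(satM)) nSat <- nSat + sum(satM[upper.tri(satM)])
      if (nrow(nk)) {
        ksAll <- c(ksAll, nk$ks); famAll <- c(famAll, rep(fid, nrow(nk)))
        nodeAll <- c(nodeAll, as.character(nk$node))
      }
    }
  }
  ageDistribution(species, ksAll, famAll, nodeAll, nSat,
                  estimator = if (is.null(ksTable)) "NG86" else "external",
                  filters = list(minIdentity = minIdentity,
                                 minLength = minLength))
}
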