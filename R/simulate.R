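## Birth-death gene-family simulation along the species tree (guest trees
## in a host tree), optional WGD injection, background-rate estimation from
## gene counts, and generators for the synthetic fixtures used throughout.

## ---- linear birth-death closed forms ---------------------------------

# alpha = extinction prob of one lineage after time t; beta = geometric
# parameter of the surviving-copy-number distribution
.bdAlphaBeta <- function(lambda, mu, t) {
  if (lambda == 0 && mu == 0) return(c(0, 0))
  if (abs(lambda - mu) < 1e-12) {
    a <- lambda * t / (1 + lambda * t)
    return(c(a, a))
  }
  E <- exp((lambda - mu) * t)
  denom <- lambda * E - mu
  c(mu * (E - 1) / denom, lambda * (E - 1) / denom)
}

# P(1 -> j) for j = 0..M
.bdSingle <- function(lambda, mu, t, M) {
  ab <- .bdAlphaBeta(lambda, mu, t)
  a <- ab[1]; b <- ab[2]
  p <- numeric(M + 1)
  p[1] <- a
  j <- seq_len(M)
  p[j + 1] <- (1 - a) * (1 - b) * b^(j - 1)
  p
}

# transition matrix P(i -> j), i,j = 0..M (independent-lineage convolution)
.bdTrans <- function(lambda, mu, t, M) {
  p1 <- .bdSingle(lambda, mu, t, M)
  P <- matrix(0, M + 1, M + 1)
  P[1, 1] <- 1
  P[2, ] <- p1
  if (M >= 2) for (i in 2:M) {
    prev <- P[i, ]
    row <- numeric(M + 1)
    for (j in 0:M) {
      # convolution of prev with p1, truncated at M
      row[j + 1] <- sum(prev[seq_len(j + 1)] * p1[(j + 1):1])
    }
    P[i + 1, ] <- row
  }
  P
}

# probability generating function of the copy-number distribution
.bdPgf <- function(lambda, mu, t, s) {
  ab <- .bdAlphaBeta(lambda, mu, t)
  a <- ab[1]; b <- ab[2]
  a + (1 - a) * (1 - b) * s / (1 - b * s)
}

## ---- background rate estimation --------------------------------------

# P(at least one copy at every tip | 1 gene at the root node), by
# inclusion-exclusion over subsets of tips required to be empty
.bdSurvivalAllTips <- function(tree, lambda, mu) {
  nt <- length(tree$tip.label)
  kids <- .childrenList(tree)
  root <- nt + 1L
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2])
  noDesc <- function(node, inS) {
    # prob one lineage AT node leaves no descendants at tips flagged inS
    if (node <= nt) return(if (inS[node]) 0 else 1)
    prod(vapply(kids[[as.character(node)]], function(ch)
      .bdPgf(lambda, mu, elen[as.character(ch)], noDesc(ch, inS)),
      numeric(1)))
  }
  total <- 0
  for (code in 0:(2^nt - 1)) {
    inS <- bitwAnd(bitwShiftR(code, seq_len(nt) - 1L), 1L) == 1L
    total <- total + (-1)^sum(inS) * noDesc(root, inS)
  }
  min(max(total, 1e-300), 1)
}

# conditional log-likelihood of a family x taxon count matrix
.bdCountLogLik <- function(counts, tree, lambda, mu, M) {
  nt <- length(tree$tip.label)
  kids <- .childrenList(tree)
  root <- nt + 1L
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2])
  Pm <- lapply(elen, function(t) .bdTrans(lambda, mu, t, M))
  names(Pm) <- names(elen)
  F <- nrow(counts)
  prune <- function(node) {
    # returns (M+1) x F matrix: P(data below node | n genes at node)
    if (node <= nt) {
      L <- matrix(0, M + 1, F)
      cnt <- pmin(counts[, tree$tip.label[node]], M)
      L[cbind(cnt + 1L, seq_len(F))] <- 1
      return(L)
    }
    L <- matrix(1, M + 1, F)
    for (ch in kids[[as.character(node)]])
      L <- L * (Pm[[as.character(ch)]] %*% prune(ch))
    L
  }
  Lroot <- prune(root)
  lik <- Lroot[2, ]  # one gene at the root
  lik[lik < 1e-300] <- 1e-300
  cond <- .bdSurvivalAllTips(tree, lambda, mu)
  sum(log(lik)) - F * log(cond)
}

#' Estimate background gene birth and loss rates
#'
#' Maximum-likelihood estimation of a single (lambda, mu) pair under a
#' linear birth-death process along the species tree: one gene at the root,
#' standard closed-form copy-number transition probabilities per branch
#' combined by pruning, conditioned on at least one surviving copy at every
#' tip (matching the family filter applied to observed gene families).
#'
#' @param counts integer matrix, families x taxa (colnames must match the
#'   species-tree tip labels).
#' @param tree rooted `phylo` species tree with positive branch lengths.
#' @param constrainEqual fit a single rate lambda = mu (default FALSE).
#' @param minFamilies minimum number of families (default 50).
#' @return list with `lambda`, `mu`, `logLik`, `identifiable` (FALSE when
#'   every family has exactly one copy per taxon, for which zero rates are
#'   the degenerate optimum), `convergence` (optimizer code).
#' @export
estimateRates <- function(counts, tree, constrainEqual = FALSE,
                          minFamilies = 50) {
  counts <- as.matrix(counts)
  if (nrow(counts) < minFamilies)
    stop(errorCondition(
      paste0("only ", nrow(counts), " families; need ", minFamilies),
      class = c("wgdinfer_insufficient", "error", "condition")))
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("species tree needs positive branch lengths")
  if (!all(tree$tip.label %in% colnames(counts)))
    stop("count matrix must have a column per species-tree tip")
  if (all(counts == 1L))
    return(list(lambda = 0, mu = 0, logLik = 0, identifiable = FALSE,
                convergence = 0L))
  M <- max(8L, 2L * max(counts) + 3L)
  nll <- function(par) {
    l <- exp(par[1])
    m <- if (constrainEqual) l else exp(par[2])
    -.bdCountLogLik(counts, tree, l, m, M)
  }
  init <- if (constrainEqual) log(0.01) else c(log(0.01), log(0.01))
  opt <- stats::optim(init, nll, method = if (constrainEqual) "Brent"
                      else "Nelder-Mead",
                      lower = if (constrainEqual) log(1e-8) else -Inf,
                      upper = if (constrainEqual) log(10) else Inf,
                      control = list(maxit = 500, reltol = 1e-10))
  l <- exp(opt$par[1])
  m <- if (constrainEqual) l else exp(opt$par[2])
  list(lambda = l, mu = m, logLik = -opt$value, identifiable = TRUE,
       convergence = opt$convergence)
}

## ---- guest-tree simulation -------------------------------------------

# nested gene-tree representation: extinct = NULL;
# pending survivor within a branch = list(pend = TRUE, len);
# leaf = list(taxon =, len); internal = list(children = list(a, b), len)
.addLen <- function(x, w) {
  if (is.null(x)) return(NULL)
  x$len <- x$len + w
  x
}

.join2 <- function(a, b, len) {
  if (is.null(a) && is.null(b)) return(NULL)
  if (is.null(a)) return(.addLen(b, len))
  if (is.null(b)) return(.addLen(a, len))
  list(children = list(a, b), len = len)
}

#' Simulate one guest gene tree along the species tree
#'
#' A single gene lineage starts at the species-tree root and evolves by a
#' linear birth-death process (per-lineage exponential waiting times with
#' birth rate `lambda` and loss rate `mu` per unit branch length). At each
#' speciation every surviving lineage enters both daughter branches. At a
#' WGD event every extant lineage duplicates instantaneously and each
#' newly created copy is retained with probability `r` (otherwise removed
#' at once). Extinct lineages are pruned; by default the draw is rejected
#' and repeated until the resulting family has at least one copy of every
#' taxon, mirroring the family filter applied to observed data.
#'
#' @param species rooted binary `phylo` species tree with branch lengths.
#' @param lambda,mu birth and loss rates per gene per unit branch length.
#' @param wgd list of WGD events, each `list(node =, pos =, r =)`: `node`
#'   is an internal node label `"Ni"` (see [validateSpeciesTree()]) or a
#'   tip taxon name; `pos` is the position on that node's stem branch as a
#'   fraction from the parent (default 0.5); `r` the retention
#'   probability. An event at the root node duplicates the starting
#'   lineage itself.
#' @param requireAllTaxa redraw until every taxon is present (default
#'   TRUE). With `requireAllTaxa = FALSE` no draw is rejected: a family
#'   that loses all its copies is returned as `NULL`, so ensembles of
#'   unconditioned draws keep the exact birth-death expectations (mean
#'   copy number 1 per tip when lambda = mu).
#' @param maxTries rejection limit before aborting (default 10000).
#' @param delimiter separator in `taxon<delimiter>counter` leaf labels.
#' @return a `phylo` gene tree (or `NULL` for an extinct family when
#'   `requireAllTaxa = FALSE`); attribute `rejections` counts redraws.
#' @export
simulateGuestTree <- function(species, lambda, mu, wgd = list(),
                              requireAllTaxa = TRUE, maxTries = 10000,
                              delimiter = "_") {
  idx <- speciesIndex(species)
  tree <- idx$tree
  nt <- length(tree$tip.label)
  kids <- .childrenList(tree)
  root <- nt + 1L
  elen <- stats::setNames(tree$edge.length, tree$edge[, 2])
  if (is.null(tree$edge.length))
    stop("species tree needs branch lengths")
  labelToNode <- c(stats::setNames(idx$nodeIds, idx$nodeLabels),
                   stats::setNames(seq_len(nt), idx$taxa))
  wgdByNode <- list()
  rootWgd <- list()
  for (ev in wgd) {
    if (is.null(ev$pos)) ev$pos <- 0.5
    if (is.null(ev$r)) stop("WGD event needs a retention probability 'r'")
    if (ev$r < 0 || ev$r > 1) stop("retention probability must be in [0,1]")
    nd <- unname(labelToNode[ev$node])
    if (length(nd) != 1L || is.na(nd))
      stop("unknown species-tree node in WGD event: ", ev$node)
    if (nd == root) rootWgd <- c(rootWgd, list(ev))
    else wgdByNode[[as.character(nd)]] <-
        c(wgdByNode[[as.character(nd)]], list(ev))
  }

  rate <- lambda + mu
  # one lineage evolving for tRem along a branch segment; survivors become
  # pend markers whose continuation is grafted in by the caller
  evolveSeg <- function(tRem) {
    if (rate == 0) return(list(pend = TRUE, len = tRem))
    wait <- stats::rexp(1, rate)
    if (wait >= tRem) return(list(pend = TRUE, len = tRem))
    if (stats::runif(1) * rate < lambda) {
      .join2(evolveSeg(tRem - wait), evolveSeg(tRem - wait), wait)
    } else NULL
  }
  # replace every pend leaf by continue(), adding its pending length
  graft <- function(x, continue) {
    if (is.null(x)) return(NULL)
    if (isTRUE(x$pend)) return(.addLen(continue(), x$len))
    a <- graft(x$children[[1]], continue)
    b <- graft(x$children[[2]], continue)
    .join2(a, b, x$len)
  }
  atNode <- function(spNode) {
    if (spNode <= nt)
      return(list(taxon = tree$tip.label[spNode], len = 0))
    ch <- kids[[as.character(spNode)]]
    .join2(enterBranch(ch[1]), enterBranch(ch[2]), 0)
  }
  wgdHit <- function(continue, r) {
    keepNew <- stats::runif(1) < r
    if (keepNew) .join2(continue(), continue(), 0) else continue()
  }
  enterBranch <- function(spNode) {
    t <- elen[as.character(spNode)]
    evs <- wgdByNode[[as.character(spNode)]]
    if (is.null(evs)) {
      seg <- evolveSeg(t)
      return(graft(seg, function() atNode(spNode)))
    }
    evs <- evs[order(vapply(evs, `[[`, 0, "pos"))]
    phase <- function(i, tDone) {
      if (i > length(evs)) {
        seg <- evolveSeg(t - tDone)
        return(graft(seg, function() atNode(spNode)))
      }
      tEv <- t * evs[[i]]$pos
      seg <- evolveSeg(tEv - tDone)
      graft(seg, function()
        wgdHit(function() phase(i + 1, tEv), evs[[i]]$r))
    }
    phase(1, 0)
  }
  simOnce <- function() {
    top <- function() atNode(root)
    for (ev in rev(rootWgd)) {
      top <- local({
        nxt <- top
        rr <- ev$r
        function() wgdHit(nxt, rr)
      })
    }
    top()
  }
  nestedTaxa <- function(x) {
    if (!is.null(x$taxon)) return(x$taxon)
    c(nestedTaxa(x$children[[1]]), nestedTaxa(x$children[[2]]))
  }
  rejections <- 0L
  repeat {
    g <- simOnce()
    ok <- !requireAllTaxa ||
      (!is.null(g) && setequal(unique(nestedTaxa(g)), idx$taxa))
    if (ok) break
    rejections <- rejections + 1L
    if (rejections >= maxTries)
      stop("guest-tree survival too improbable: ", maxTries,
           " consecutive draws failed the all-taxa filter ",
           "(lambda = ", lambda, ", mu = ", mu, ")")
  }
  if (is.null(g)) return(NULL)
  counters <- new.env(parent = emptyenv())
  toNewick <- function(x) {
    if (!is.null(x$taxon)) {
      k <- (if (is.null(counters[[x$taxon]])) 0L
            else counters[[x$taxon]]) + 1L
      counters[[x$taxon]] <- k
      return(paste0(x$taxon, delimiter, k, ":",
                    format(x$len, digits = 12)))
    }
    paste0("(", toNewick(x$children[[1]]), ",", toNewick(x$children[[2]]),
           "):", format(x$len, digits = 12))
  }
  # a single surviving lineage yields a one-leaf family: not a usable tree
  if (is.null(g$children)) {
    txt <- paste0("(", toNewick(g), ");")
  } else txt <- paste0(toNewick(g), ";")
  out <- ape::read.tree(text = txt)
  attr(out, "rejections") <- rejections
  out
}

#' Build a null simulation set
#'
#' Simulates `n` gene trees under the background birth-death rates with no
#' WGD, then stores a plan of `nResamples` without-replacement resamples of
#' `subset` trees each, used downstream to express uncertainty in the
#' per-node subtree percentages.
#'
#' @param species rooted `phylo` species tree with branch lengths.
#' @param lambda,mu background rates.
#' @param n number of trees (default 3000).
#' @param subset resample size (default 1000).
#' @param nResamples number of resamples (default 100).
#' @param seed integer master seed; the whole set is reproducible from it.
#' @param wgd optional list of WGD events (used by
#'   [buildPositiveSet()]).
#' @return a [SimulationSet-class].
#' @export
buildNullSet <- function(species, lambda, mu, n = 3000, subset = 1000,
                         nResamples = 100, seed = 1, wgd = list()) {
  if (subset > n) stop("resample size (", subset,
                       ") cannot exceed the pool size (", n, ")")
  seeds <- deriveSeeds(seed, n + 1L)
  trees <- vector("list", n)
  rej <- 0L
  for (i in seq_len(n)) {
    trees[[i]] <- .withSeed(seeds[i],
                            simulateGuestTree(species, lambda, mu, wgd))
    rej <- rej + attr(trees[[i]], "rejections")
  }
  resamples <- .withSeed(seeds[n + 1L],
                         lapply(seq_len(nResamples),
                                function(j) sort(sample.int(n, subset))))
  new("SimulationSet", trees = trees,
      config = list(lambda = lambda, mu = mu, n = n, subset = subset,
                    nResamples = nResamples, seed = seed, wgd = wgd,
                    rejections = rej),
      resamples = resamples)
}

#' Build a positive simulation set with an injected WGD
#'
#' Identical to [buildNullSet()] but with one WGD event inserted at a
#' given species-tree node.
#'
#' @inheritParams buildNullSet
#' @param wgdNode internal node label (`"Ni"`) or taxon name.
#' @param r retention probability of each WGD-created copy (default 0.2).
#' @param pos position of the event on the node's stem branch (default
#'   0.5).
#' @return a [SimulationSet-class].
#' @export
buildPositiveSet <- function(species, lambda, mu, wgdNode, r = 0.2,
                             pos = 0.5, n = 3000, subset = 1000,
                             nResamples = 100, seed = 1) {
  buildNullSet(species, lambda, mu, n = n, subset = subset,
               nResamples = nResamples, seed = seed,
               wgd = list(list(node = wgdNode, pos = pos, r = r)))
}

#' Per-family per-taxon copy counts of a tree set
#'
#' @param trees list of `phylo` gene trees.
#' @param taxa character vector of taxa (column order).
#' @param delimiter taxon prefix delimiter.
#' @return integer matrix, trees x taxa.
#' @export
copyCounts <- function(trees, taxa, delimiter = "_") {
  m <- t(vapply(trees, function(tr) {
    tx <- taxonFromLabel(tr$tip.label, delimiter)
    vapply(taxa, function(a) sum(tx == a), integer(1))
  }, integer(length(taxa))))
  colnames(m) <- taxa
  m
}

## ---- synthetic fixtures ----------------------------------------------

#' Synthesize a Ks age distribution
#'
#' Truncated-exponential background of paralog ages plus optional Gaussian
#' WGD peaks, all confined to the analysis window.
#'
#' @param n total number of values.
#' @param rate background exponential decay rate (default 1.5).
#' @param peaks list of `list(mean =, sd =, weight =)`; weights must sum
#'   to at most 1, the remainder is background.
#' @param window analysis window (default `c(0.01, 2)`).
#' @param seed integer seed.
#' @param species species id for the result.
#' @return an [AgeDistribution-class].
#' @export
synthKsSample <- function(n, rate = 1.5, peaks = list(),
                          window = c(0.01, 2), seed = 1,
                          species = "synthetic") {
  w <- vapply(peaks, `[[`, 0, "weight")
  if (sum(w) > 1) stop("peak weights exceed 1")
  ks <- .withSeed(seed, {
    if (n == 0) numeric(0) else {
      comp <- sample.int(length(peaks) + 1L, n, replace = TRUE,
                         prob = c(1 - sum(w), w))
      vals <- numeric(n)
      bg <- comp == 1L
      vals[bg] <- rNullKs(sum(bg), rate = rate, window = window)
      for (j in seq_along(peaks)) {
        sel <- comp == j + 1L
        m <- sum(sel)
        if (!m) next
        draw <- numeric(0)
        while (length(draw) < m) {
          d <- stats::rnorm(2 * m, peaks[[j]]$mean, peaks[[j]]$sd)
          draw <- c(draw, d[d > window[1] & d <= window[2]])
        }
        vals[sel] <- draw[seq_len(m)]
      }
      vals
    }
  })
  ageDistribution(species, ks, estimator = "synthetic",
                  filters = list(rate = rate, window = window,
                                 seed = seed))
}

#' Synthesize a BLAST tabular hit table realizing given gene families
#'
#' Produces a hit table whose duplicate pairs, after the standard
#' identity/length filter, single-linkage-cluster into exactly the
#' requested families: a spanning chain of strong hits within each family,
#' plus self-hits and sub-threshold noise hits between families that the
#' filter must remove.
#'
#' @param families list of character vectors of gene ids (each length >=
#'   2, pairwise disjoint).
#' @param seed integer seed.
#' @param noise number of sub-threshold cross-family hits (default 5).
#' @return data.frame in the 12-column BLAST tabular layout of
#'   [readBlastTab()].
#' @export
synthHitTable <- function(families, seed = 1, noise = 5) {
  .withSeed(seed, {
    rows <- list()
    addHit <- function(q, s, ident, len) {
      rows[[length(rows) + 1L]] <<- data.frame(
        query = q, subject = s, identity = ident, length = len,
        mismatch = round(len * (100 - ident) / 100), gapopen = 0L,
        qstart = 1L, qend = len, sstart = 1L, send = len,
        evalue = 10^(-stats::runif(1, 20, 120)),
        bitscore = round(len * ident / 50),
        stringsAsFactors = FALSE)
    }
    for (fam in families) {
      fam <- sort(fam)
      for (g in fam) addHit(g, g, 100, 600)  # self-hits, filtered later
      if (length(fam) >= 2)
        for (i in seq_len(length(fam) - 1L))
          addHit(fam[i], fam[i + 1L],
                 stats::runif(1, 45, 95),
                 round(stats::runif(1, 320, 900)))
    }
    allGenes <- unlist(families)
    if (length(families) >= 2 && noise > 0) {
      for (k in seq_len(noise)) {
        f2 <- sample.int(length(families), 2)
        g1 <- sample(families[[f2[1]]], 1)
        g2 <- sample(families[[f2[2]]], 1)
        if (stats::runif(1) < 0.5)
          addHit(g1, g2, stats::runif(1, 20, 39), 500)   # identity fails
        else
          addHit(g1, g2, stats::runif(1, 45, 80), 150)   # length fails
      }
    }
    do.call(rbind, rows)
  })
}
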