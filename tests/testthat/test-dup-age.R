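test_that("filterDuplicatePairs matches a brute-force filter", {
  set.seed(101)
  genes <- paste0("g", 1:12)
  for (rep in 1:15) {
    hits <- randHits(genes, genes, 40)
    got <- filterDuplicatePairs(hits)
    want <- oracleFilterPairs(hits)
    expect_identical(got$geneA, want$geneA)
    expect_identical(got$geneB, want$geneB)
    expect_equal(got$identity, want$identity, ignore_attr = TRUE)
    expect_equal(got$length, want$length, ignore_attr = TRUE)
  }
})

test_that("filterDuplicatePairs applies the 40%/300bp thresholds", {
  hits <- data.frame(
    query = c("a", "a", "a", "a"), subject = c("b", "c", "d", "a"),
    identity = c(40, 39.9, 80, 100), length = c(300, 400, 299, 500),
    bitscore = 100, stringsAsFactors = FALSE)
  p <- filterDuplicatePairs(hits)
  expect_identical(p$geneA, "a")   # only a-b passes; self-hit dropped
  expect_identical(p$geneB, "b")
})

test_that("singleLinkageFamilies equals DFS connected components", {
  set.seed(102)
  for (rep in 1:20) {
    genes <- paste0("g", seq_len(sample(10:30, 1)))
    n <- sample(5:60, 1)
    pairs <- data.frame(geneA = sample(genes, n, replace = TRUE),
                        geneB = sample(genes, n, replace = TRUE),
                        stringsAsFactors = FALSE)
    pairs <- pairs[pairs$geneA != pairs$geneB, , drop = FALSE]
    if (!nrow(pairs)) next
    fams <- singleLinkageFamilies(pairs)
    want <- oracleComponents(pairs)
    expect_identical(unname(fams), want)
    expect_identical(names(fams),
                     paste0("fam.", vapply(want, `[`, "", 1)))
  }
  expect_identical(length(singleLinkageFamilies(
    data.frame(geneA = character(0), geneB = character(0)))), 0L)
})

test_that("estimateKsPair is zero for identical sequences", {
  a <- strrep("ATGGCTCATAAG", 20)
  ks <- estimateKsPair(a, a)
  expect_equal(as.numeric(ks), 0)
  expect_equal(attr(ks, "Sd") + attr(ks, "Nd"), 0)
  expect_equal(attr(ks, "S") + attr(ks, "N"), 3 * 80)
})

test_that("estimateKsPair matches a hand-computed single difference", {
  # GGT -> GGC is synonymous (Gly); pad with identical AAA codons
  a <- paste0("GGT", strrep("AAA", 49))
  b <- paste0("GGC", strrep("AAA", 49))
  ks <- estimateKsPair(a, b)
  # sites: syn(GGT) = 1 (third position fourfold degenerate),
  # syn(GGC) = 1, syn(AAA) = 1/3 (AAG only; TAA is a stop); S = 1 + 49/3
  S <- 1 + 49 / 3
  pS <- 1 / S
  expect_equal(attr(ks, "S"), S)
  expect_equal(attr(ks, "Sd"), 1)
  expect_equal(attr(ks, "Nd"), 0)
  expect_equal(as.numeric(ks), -0.75 * log(1 - 4 * pS / 3))
})

test_that("estimateKsPair averages pathways through two-step changes", {
  # TTT (Phe) -> GTA (Val): positions 1 and 3 differ.
  # path 1: TTT -> GTT (F->V, nonsyn) -> GTA (V->V, syn)
  # path 2: TTT -> TTA (F->L, nonsyn) -> GTA (L->V, nonsyn)
  # average over both: Sd = 0.5, Nd = 1.5 (GGC padding keeps pS < 3/4)
  a <- paste0("TTT", strrep("GGC", 49))
  b <- paste0("GTA", strrep("GGC", 49))
  ks <- estimateKsPair(a, b)
  expect_equal(attr(ks, "Sd"), 0.5)
  expect_equal(attr(ks, "Nd"), 1.5)
})

test_that("estimateKsPair is symmetric and skips gapped codons", {
  set.seed(103)
  a <- randCds(60)
  b <- mutateSeq(a, 12)
  expect_equal(as.numeric(estimateKsPair(a, b)),
               as.numeric(estimateKsPair(b, a)))
  a2 <- a
  substr(a2, 1, 3) <- "---"
  ks2 <- estimateKsPair(a2, b)
  expect_equal(attr(ks2, "S") + attr(ks2, "N"), 3 * 59)
})

test_that("estimateKsPair raises typed insufficient/saturated errors", {
  expect_error(estimateKsPair("ATGATG", "ATGATG"),
               class = "wgdinfer_insufficient")
  expect_error(estimateKsPair("ATGGCTA", "ATGGCTA"), "divisible by 3")
  expect_error(estimateKsPair(strrep("ATG", 40), strrep("ATG", 41)),
               "differ in length")
  # every codon differs synonymously -> pS = 1 -> saturated
  expect_error(estimateKsPair(strrep("GGT", 40), strrep("GGC", 40)),
               class = "wgdinfer_saturated")
})

test_that("RNA input (U) is accepted", {
  a <- strrep("ATGGCT", 30)
  expect_equal(as.numeric(estimateKsPair(gsub("T", "U", a), a)), 0)
})

test_that("NG86 matches the site-enumeration oracle on random pairs", {
  set.seed(104)
  for (rep in 1:8) {
    a <- randCds(45)
    b <- mutateSeq(a, sample(3:18, 1))
    got <- tryCatch(estimateKsPair(a, b), error = function(e) NULL)
    want <- oracleKs(a, b)
    if (is.null(got)) {
      expect_gte(want$pS, 0.75)
      next
    }
    expect_equal(as.numeric(got), want$ks, tolerance = 1e-12)
    expect_equal(attr(got, "S"), want$S, tolerance = 1e-12)
    expect_equal(attr(got, "Sd"), want$Sd, tolerance = 1e-12)
    expect_equal(attr(got, "Nd"), want$Nd, tolerance = 1e-12)
  }
})

test_that("ksMatrix flags saturated and insufficient pairs as NA", {
  set.seed(105)
  base <- randCds(40)
  seqs <- c(s1 = strrep("GGT", 40),
            s2 = strrep("GGC", 40),
            s3 = base,
            s4 = mutateSeq(base, 5),
            s5 = paste0(strrep("---", 35), substr(base, 106, 120)))
  m <- ksMatrix(seqs)
  expect_true(is.na(m["s1", "s2"]))                    # saturated
  expect_true(attr(m, "saturated")["s1", "s2"])
  expect_true(attr(m, "saturated")["s2", "s1"])
  expect_true(is.na(m["s3", "s5"]))                    # too few codons
  expect_false(attr(m, "saturated")["s3", "s5"])
  expect_false(is.na(m["s3", "s4"]))
  expect_identical(m["s3", "s4"], m["s4", "s3"])       # symmetric
  expect_identical(unname(diag(m)), rep(0, 5))
})

test_that("nodeKsFromTree takes medians of cross-child pairs", {
  tree <- ape::read.tree(text = "((a,b),(c,d));")
  ids <- c("a", "b", "c", "d")
  ks <- matrix(0, 4, 4, dimnames = list(ids, ids))
  ks["a", "b"] <- ks["b", "a"] <- 0.1
  ks["c", "d"] <- ks["d", "c"] <- 0.3
  ks["a", "c"] <- ks["c", "a"] <- 1.0
  ks["a", "d"] <- ks["d", "a"] <- 1.2
  ks["b", "c"] <- ks["c", "b"] <- 1.4
  ks["b", "d"] <- ks["d", "b"] <- 1.6
  nk <- nodeKsFromTree(tree, ks)
  expect_identical(nrow(nk), 3L)
  root <- nk[nk$nPairs == 4, ]
  expect_equal(root$ks, stats::median(c(1.0, 1.2, 1.4, 1.6)))
  expect_setequal(nk$ks[nk$nPairs == 1], c(0.1, 0.3))
})

test_that("nodeKsFromTree ignores NA pairs and skips empty nodes", {
  tree <- ape::read.tree(text = "((a,b),c);")
  ids <- c("a", "b", "c")
  ks <- matrix(NA_real_, 3, 3, dimnames = list(ids, ids))
  diag(ks) <- 0
  ks["a", "b"] <- ks["b", "a"] <- 0.5
  nk <- nodeKsFromTree(tree, ks)   # root has no usable cross-pair
  expect_identical(nrow(nk), 1L)
  expect_equal(nk$ks, 0.5)
  expect_error(nodeKsFromTree(ape::read.tree(text = "((a,x),c);"), ks),
               "does not cover")
})

test_that("node-Ks matches brute-force enumeration on random families", {
  set.seed(106)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    tree <- ape::rtree(n, rooted = TRUE)
    tree$tip.label <- paste0("g", seq_len(n))
    ks <- matrix(stats::runif(n * n, 0, 3), n, n,
                 dimnames = list(tree$tip.label, tree$tip.label))
    ks[lower.tri(ks)] <- t(ks)[lower.tri(ks)]
    diag(ks) <- 0
    nk <- nodeKsFromTree(tree, ks)
    kids <- .oracleKids(tree)
    below <- vector("list", n + tree$Nnode)
    rec <- function(nd) {
      below[[nd]] <<- if (nd <= n) tree$tip.label[nd]
                      else unlist(lapply(kids[[nd]], rec))
      below[[nd]]
    }
    rec(n + 1L)
    for (i in seq_len(nrow(nk))) {
      nd <- nk$node[i]
      L <- below[[kids[[nd]][1]]]
      R <- below[[kids[[nd]][2]]]
      vals <- as.vector(ks[L, R, drop = FALSE])
      expect_equal(nk$ks[i], stats::median(vals))
      expect_identical(nk$nPairs[i], length(vals))
    }
  }
})

test_that("age distributions round-trip through TSV", {
  ages <- ageDistribution("sp", ks = c(0.123456789, 1.5, 2 / 3),
                          familyId = c("f1", "f1", "f2"),
                          nodeId = c("5", "6", "3"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeAgeDistribution(ages, path)
  back <- readAgeDistribution(path, species = "sp")
  expect_equal(ksValues(back), ksValues(ages), tolerance = 1e-9)
  expect_identical(back@familyId, ages@familyId)
  expect_identical(back@nodeId, ages@nodeId)
  expect_identical(speciesId(back), "sp")
  writeLines("a\tb\n1\t2", path)
  expect_error(readAgeDistribution(path), "family_id")
})

test_that("readKsTable builds a symmetric matrix with saturation marks", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tks",
               "g1\tg2\t0.25",
               "g1\tg3\tsaturated",
               "g2\tg3\t1.75"), path)
  m <- readKsTable(path)
  expect_identical(m["g1", "g2"], 0.25)
  expect_identical(m["g2", "g1"], 0.25)
  expect_true(is.na(m["g1", "g3"]))
  expect_true(attr(m, "saturated")["g3", "g1"])
  writeLines(c("gene_a\tgene_b\tks", "g1\tg2\t-0.5"), path)
  expect_error(readKsTable(path), "negative")
  writeLines(c("gene_a\tgene_b", "g1\tg2"), path)
  expect_error(readKsTable(path), "3 columns")
})

test_that("dupPipe reconstructs node ages end to end", {
  fams <- list(c("g1", "g2"), c("h1", "h2", "h3"))
  hits <- synthHitTable(fams, seed = 9)
  ids <- c("g1", "g2", "h1", "h2", "h3")
  km <- matrix(NA_real_, 5, 5, dimnames = list(ids, ids))
  diag(km) <- 0
  km["g1", "g2"] <- km["g2", "g1"] <- 0.4
  km["h1", "h2"] <- km["h2", "h1"] <- 0.2
  km["h1", "h3"] <- km["h3", "h1"] <- 0.9
  km["h2", "h3"] <- km["h3", "h2"] <- 1.1
  tree <- ape::read.tree(text = "((h1,h2),h3);")
  ages <- dupPipe(hits, species = "toy", trees = list(tree),
                  ksTable = km)
  expect_s4_class(ages, "AgeDistribution")
  # fam g: the single pair; fam h: node (h1,h2) = 0.2, root = median(0.9, 1.1)
  expect_setequal(round(ksValues(ages), 6), c(0.4, 0.2, 1.0))
  expect_identical(speciesId(ages), "toy")
  expect_identical(ages@estimator, "external")
})

test_that("dupPipe warns and skips families without a matching tree", {
  fams <- list(c("g1", "g2"), c("h1", "h2", "h3"))
  hits <- synthHitTable(fams, seed = 10)
  ids <- c("g1", "g2", "h1", "h2", "h3")
  km <- matrix(0.5, 5, 5, dimnames = list(ids, ids))
  diag(km) <- 0
  expect_warning(ages <- dupPipe(hits, species = "toy", ksTable = km),
                 "no family tree")
  expect_identical(length(ksValues(ages)), 1L)   # only the 2-member family
})
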