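test_that("with zero rates the guest tree is congruent with the host", {
  sp <- ladder6()
  g <- simulateGuestTree(sp, 0, 0)
  expect_identical(sort(taxonFromLabel(g$tip.label)), sort(sp$tip.label))
  ref <- sp
  ref$tip.label <- paste0(ref$tip.label, "_1")
  expect_true(sameTopology(g, ref))
  # leaf depths equal the species tree's tip depths
  gd <- ape::node.depth.edgelength(g)[seq_len(6)]
  sd <- ape::node.depth.edgelength(sp)[seq_len(6)]
  expect_equal(sort(gd), sort(sd))
  expect_identical(nrow(mapDuplications(g, sp)), 0L)
})

test_that("a fully retained root WGD doubles every taxon exactly once", {
  sp <- ladder6()
  g <- simulateGuestTree(sp, 0, 0,
                         wgd = list(list(node = "N5", pos = 0.5, r = 1)))
  cc <- copyCounts(list(g), sp$tip.label)
  expect_true(all(cc == 2L))
  d <- mapDuplications(g, sp)
  expect_identical(nrow(d), 1L)
  expect_identical(d$speciesNode, "N5")
})

test_that("a retained WGD on an internal stem maps to that node", {
  sp <- ladder6()
  g <- simulateGuestTree(sp, 0, 0,
                         wgd = list(list(node = "N3", pos = 0.5, r = 1)))
  cc <- copyCounts(list(g), sp$tip.label)
  # N3's clade {A, B, C, D} is doubled, E and F are single copy
  expect_identical(unname(cc[1, c("A", "B", "C", "D")]), rep(2L, 4))
  expect_identical(unname(cc[1, c("E", "F")]), c(1L, 1L))
  d <- mapDuplications(g, sp)
  expect_identical(d$speciesNode, "N3")
  # with r = 0 the event never fires
  g0 <- simulateGuestTree(sp, 0, 0,
                          wgd = list(list(node = "N3", r = 0)))
  expect_true(all(copyCounts(list(g0), sp$tip.label) == 1L))
})

test_that("a WGD on a terminal branch doubles only that taxon", {
  sp <- ladder6()
  g <- simulateGuestTree(sp, 0, 0,
                         wgd = list(list(node = "C", pos = 0.5, r = 1)))
  cc <- copyCounts(list(g), sp$tip.label)
  expect_identical(unname(cc[1, "C"]), 2L)
  expect_identical(sum(cc), 7L)
  expect_identical(mapDuplications(g, sp)$speciesNode, "C")
})

test_that("WGD event validation", {
  sp <- ladder6()
  expect_error(simulateGuestTree(sp, 0, 0,
                                 wgd = list(list(node = "N9", r = 1))),
               "unknown species-tree node")
  expect_error(simulateGuestTree(sp, 0, 0,
                                 wgd = list(list(node = "N3"))),
               "retention probability")
  expect_error(simulateGuestTree(sp, 0, 0,
                                 wgd = list(list(node = "N3", r = 1.5))),
               "in \\[0,1\\]")
})

test_that("pure-birth copies grow at the expected exponential rate", {
  # two-taxon ladder, tip depth 2; with mu = 0 every tip keeps >= 1 copy
  sp <- ape::read.tree(text = "(A:2,B:2);")
  lambda <- 0.4
  set.seed(501)
  counts <- vapply(1:800, function(i) {
    g <- simulateGuestTree(sp, lambda, 0)
    as.integer(copyCounts(list(g), c("A", "B")))
  }, integer(2))
  expect_true(all(counts >= 1L))
  m <- mean(counts)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(m - exp(lambda * 2)), 3 * se)
})

test_that("unconditioned birth-death draws keep mean copy number one", {
  sp <- ape::read.tree(text = "(A:3,B:3);")
  set.seed(502)
  counts <- vapply(1:1500, function(i) {
    g <- simulateGuestTree(sp, 0.2, 0.2, requireAllTaxa = FALSE)
    if (is.null(g)) c(0L, 0L)
    else as.integer(copyCounts(list(g), c("A", "B")))
  }, integer(2))
  expect_true(any(colSums(counts) == 0L))   # extinction does occur
  m <- mean(counts)
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(m - 1), 3 * se)
})

test_that("simulation sets are reproducible and well formed", {
  sp <- ladder6()
  s1 <- buildNullSet(sp, 0.05, 0.05, n = 25, subset = 10,
                     nResamples = 4, seed = 77)
  s2 <- buildNullSet(sp, 0.05, 0.05, n = 25, subset = 10,
                     nResamples = 4, seed = 77)
  expect_identical(lapply(simTrees(s1), ape::write.tree),
                   lapply(simTrees(s2), ape::write.tree))
  expect_identical(simResamples(s1), simResamples(s2))
  s3 <- buildNullSet(sp, 0.05, 0.05, n = 25, subset = 10,
                     nResamples = 4, seed = 78)
  expect_false(identical(lapply(simTrees(s1), ape::write.tree),
                         lapply(simTrees(s3), ape::write.tree)))
  # every tree passes the family filter; resamples are valid plans
  expect_identical(length(familyFilter(simTrees(s1), sp$tip.label)), 25L)
  for (r in simResamples(s1)) {
    expect_identical(length(r), 10L)
    expect_identical(anyDuplicated(r), 0L)
  }
  expect_error(buildNullSet(sp, 0.05, 0.05, n = 10, subset = 20),
               "cannot exceed")
})

test_that("positive sets carry their WGD in the config", {
  sp <- ladder6()
  s <- buildPositiveSet(sp, 0, 0, wgdNode = "N3", r = 1,
                        n = 10, subset = 5, nResamples = 2, seed = 5)
  expect_identical(s@config$wgd[[1]]$node, "N3")
  prof <- mapsProfile(simTrees(s), sp)
  # r = 1, no births/losses: every tree has a shared duplication at N3
  pt <- profileTable(prof)
  expect_identical(pt$nDup[pt$node == "N3"], 10L)
  expect_identical(pt$nSubtrees[pt$node == "N3"], 10L)
})

test_that("copyCounts tallies gene copies per taxon", {
  g <- readNewick("(((A_1,A_2),B_1),C_1);")
  cc <- copyCounts(list(g, g), c("A", "B", "C", "D"))
  expect_identical(dim(cc), c(2L, 4L))
  expect_identical(unname(cc[1, ]), c(2L, 1L, 1L, 0L))
})

test_that("estimateRates flags the degenerate all-single-copy case", {
  counts <- matrix(1L, 60, 6,
                   dimnames = list(NULL, ladder6()$tip.label))
  est <- estimateRates(counts, ladder6())
  expect_identical(est$lambda, 0)
  expect_identical(est$mu, 0)
  expect_false(est$identifiable)
  expect_error(estimateRates(counts[1:10, ], ladder6()),
               class = "wgdinfer_insufficient")
})

test_that("estimateRates recovers simulation rates", {
  sp <- ladder6deep()
  set.seed(503)
  trees <- replicate(400,
                     simulateGuestTree(sp, 0.002, 0.002, maxTries = 1e5),
                     simplify = FALSE)
  cc <- copyCounts(trees, sp$tip.label)
  est <- estimateRates(cc, sp)
  expect_true(est$identifiable)
  expect_equal(est$lambda, 0.002, tolerance = 0.4)
  expect_equal(est$mu, 0.002, tolerance = 0.4)
  # constrained single-rate fit lands in the same region
  estEq <- estimateRates(cc, sp, constrainEqual = TRUE)
  expect_identical(estEq$lambda, estEq$mu)
  expect_equal(estEq$lambda, 0.002, tolerance = 0.4)
})

test_that("estimateRates validates its inputs", {
  counts <- matrix(1L, 60, 3, dimnames = list(NULL, c("A", "B", "X")))
  counts[1, 1] <- 2L
  sp <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_error(estimateRates(counts, sp), "column per species-tree tip")
  spNoLen <- ape::read.tree(text = "((A,B),C);")
  colnames(counts) <- c("A", "B", "C")
  expect_error(estimateRates(counts, spNoLen), "branch lengths")
})

test_that("synthKsSample respects window, weights and determinism", {
  ages <- synthKsSample(4000, rate = 1.5,
                        peaks = list(list(mean = 0.6, sd = 0.05,
                                          weight = 0.3)),
                        seed = 13)
  ks <- ksValues(ages)
  expect_identical(length(ks), 4000L)
  expect_true(all(ks > 0.01 & ks <= 2))
  nearPeak <- mean(abs(ks - 0.6) < 0.15)
  expect_gt(nearPeak, 0.25)   # ~30% peak + some background
  ages2 <- synthKsSample(4000, rate = 1.5,
                         peaks = list(list(mean = 0.6, sd = 0.05,
                                           weight = 0.3)),
                         seed = 13)
  expect_identical(ks, ksValues(ages2))
  expect_error(synthKsSample(10, peaks = list(list(mean = 1, sd = 1,
                                                   weight = 1.2))),
               "exceed 1")
})

test_that("synthHitTable realizes exactly the requested families", {
  fams <- list(c("a1", "a2", "a3"), c("b1", "b2"), c("c1", "c2", "c3",
                                                     "c4"))
  hits <- synthHitTable(fams, seed = 3, noise = 8)
  got <- singleLinkageFamilies(filterDuplicatePairs(hits))
  expect_identical(unname(got), lapply(fams, sort))
  # the noise rows really are sub-threshold
  expect_gt(nrow(hits), sum(lengths(fams)) * 2 - length(fams))
})
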