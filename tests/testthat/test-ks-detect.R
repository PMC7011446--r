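test_that("rNullKs stays inside the window and matches the density", {
  null <- ksNullModel(rate = 1.5)
  set.seed(201)
  x <- rNullKs(20000, null)
  expect_true(all(x > 0.01 & x <= 2))
  # truncated-exponential mean on (a, b]
  a <- 0.01; b <- 2; r <- 1.5
  Z <- exp(-r * a) - exp(-r * b)
  mth <- ((a + 1 / r) * exp(-r * a) - (b + 1 / r) * exp(-r * b)) / Z
  expect_equal(mean(x), mth, tolerance = 0.02)
})

test_that("fitNull recovers a known decay rate", {
  set.seed(202)
  x <- rNullKs(5000, rate = 1.2, window = c(0.01, 2))
  null <- fitNull(x)
  expect_s4_class(null, "KsNullModel")
  expect_equal(nullRate(null), 1.2, tolerance = 0.1)
  expect_identical(null@n, 5000L)
  x2 <- rNullKs(5000, rate = 0.6, window = c(0.01, 5))
  null2 <- fitNull(x2, ksMax = 5)
  expect_equal(nullRate(null2), 0.6, tolerance = 0.1)
})

test_that("fitNull raises a typed error on too little data", {
  expect_error(fitNull(runif(50, 0.02, 1.9)),
               class = "wgdinfer_insufficient")
  # values outside the window do not count
  expect_error(fitNull(c(runif(99, 0.02, 1.9), rep(3, 500))),
               class = "wgdinfer_insufficient")
})

test_that("ksGoodnessOfFit accepts null data and rejects peaked data", {
  null <- ksNullModel(rate = 1.5)
  set.seed(203)
  pure <- rNullKs(3000, null)
  gf <- ksGoodnessOfFit(pure, null, seed = 11)
  expect_gt(gf$p.value, 0.05)
  expect_identical(gf$nObs, 3000L)
  peaked <- synthKsSample(3000, rate = 1.5,
                          peaks = list(list(mean = 0.6, sd = 0.08,
                                            weight = 0.35)),
                          seed = 12)
  gf2 <- ksGoodnessOfFit(peaked, null, seed = 11)
  expect_lt(gf2$p.value, 1e-6)
  # deterministic given the seed
  gf3 <- ksGoodnessOfFit(peaked, null, seed = 11)
  expect_identical(gf2$p.value, gf3$p.value)
})

test_that("EM log-likelihood is non-decreasing across iterations", {
  set.seed(204)
  x <- c(rnorm(300, 0.4, 0.05), rnorm(300, 1.2, 0.1))
  for (k in 1:3) {
    fit <- wgdinfer:::.emFit(x, k, tol = 1e-8, maxIter = 300,
                             trace = TRUE)
    expect_gte(min(diff(fit$llTrace)), -1e-8)
  }
})

test_that("the mixture fit recovers well-separated components", {
  set.seed(205)
  x <- c(rnorm(1500, 0.4, 0.05), rnorm(500, 1.3, 0.08))
  x <- x[x > 0.01 & x <= 2]
  fit <- fitKsMixture(x, seed = 21)
  expect_s4_class(fit, "KsMixtureFit")
  expect_identical(fit@k, 2L)
  expect_equal(fit@mean, c(0.4, 1.3), tolerance = 0.05)
  expect_equal(fit@weight, c(0.75, 0.25), tolerance = 0.05)
  expect_equal(sum(fit@weight), 1)
  expect_true(all(diff(fit@mean) > 0))   # components sorted by mean
})

test_that("the mixture fit agrees with an independent EM (mclust)", {
  set.seed(206)
  x <- c(rnorm(1200, 0.5, 0.06), rnorm(800, 1.4, 0.1))
  x <- x[x > 0.01 & x <= 2]
  fit <- fitKsMixture(x, kRange = 2, seed = 22)
  suppressPackageStartupMessages(library(mclust))
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit@mean), sort(as.numeric(mc$parameters$mean)),
               tolerance = 0.02)
  expect_equal(fit@logLik, mc$loglik, tolerance = 1)
})

test_that("fitKsMixture is deterministic in its seed", {
  set.seed(207)
  x <- c(rnorm(600, 0.5, 0.1), rnorm(400, 1.2, 0.15))
  x <- x[x > 0.01 & x <= 2]
  f1 <- fitKsMixture(x, seed = 31)
  f2 <- fitKsMixture(x, seed = 31)
  expect_identical(mixtureComponents(f1), mixtureComponents(f2))
})

test_that("mixtureAssign picks the maximum-responsibility component", {
  fit <- new("KsMixtureFit", k = 2L, weight = c(0.5, 0.5),
             mean = c(0.4, 1.4), sd = c(0.1, 0.1), logLik = 0,
             bic = 0, converged = TRUE, window = c(0.01, 2), n = 0L)
  expect_identical(mixtureAssign(fit, c(0.35, 1.5, 0.9 - 1e-6)),
                   c(1L, 2L, 1L))
})

test_that("callPeaks flags deep peaks as needs-corroboration", {
  # Ks 2.15 is beyond the Ks <= 2 rule: never auto-promoted to candidate
  set.seed(208)
  x <- c(rNullKs(2000, rate = 0.8, window = c(0.01, 5)),
         rnorm(900, 2.15, 0.1))
  x <- x[x > 0.01 & x <= 5]
  fit <- fitKsMixture(x, seed = 41, window = c(0.01, 5))
  pk <- callPeaks(fit, x, ksSignificant = TRUE, seed = 41)
  deep <- pk[pk$isPeak & abs(pk$median - 2.15) < 0.15, ]
  expect_gte(nrow(deep), 1L)
  expect_true(all(deep$status == "needs-corroboration"))
})

test_that("callPeaks demotes peaks when the K-S gate failed", {
  set.seed(209)
  x <- c(rnorm(800, 0.5, 0.05), rnorm(800, 1.4, 0.08))
  x <- x[x > 0.01 & x <= 2]
  fit <- fitKsMixture(x, kRange = 2, seed = 51)
  pkYes <- callPeaks(fit, x, ksSignificant = TRUE, seed = 51)
  pkNo <- callPeaks(fit, x, ksSignificant = FALSE, seed = 51)
  expect_true(any(pkYes$status == "WGD-candidate"))
  expect_false(any(pkNo$status == "WGD-candidate"))
  expect_identical(pkYes$isPeak, pkNo$isPeak)
})

test_that("callPeaks ignores tiny-weight components", {
  fit <- new("KsMixtureFit", k = 2L, weight = c(0.97, 0.03),
             mean = c(0.5, 1.5), sd = c(0.1, 0.05), logLik = 0,
             bic = 0, converged = TRUE, window = c(0.01, 2), n = 0L)
  set.seed(210)
  x <- c(rnorm(970, 0.5, 0.1), rnorm(30, 1.5, 0.05))
  pk <- callPeaks(fit, x, seed = 61)
  expect_identical(pk$status[2], "background")
  expect_false(pk$isPeak[2])
})

test_that("bootstrap CIs cover the component median", {
  set.seed(211)
  x <- c(rnorm(1000, 0.45, 0.05), rnorm(1000, 1.3, 0.08))
  x <- x[x > 0.01 & x <= 2]
  fit <- fitKsMixture(x, kRange = 2, seed = 71)
  pk <- callPeaks(fit, x, seed = 71)
  for (i in seq_len(nrow(pk))) {
    expect_lte(pk$ciLo[i], pk$median[i])
    expect_gte(pk$ciHi[i], pk$median[i])
  }
})

test_that("detectWgd finds an implanted peak near its true position", {
  ages <- synthKsSample(5000, rate = 1.5,
                        peaks = list(list(mean = 0.6, sd = 0.1,
                                          weight = 0.3)),
                        seed = 81)
  res <- detectWgd(ages, seed = 81)
  expect_lt(res$ks$p.value, 0.05)
  cand <- res$peaks[res$peaks$status == "WGD-candidate", ]
  expect_gte(nrow(cand), 1L)
  expect_lte(min(abs(cand$median - 0.6)), 0.05)
})

test_that("peaks tables round-trip through TSV and plots render", {
  ages <- synthKsSample(1200, rate = 1.5,
                        peaks = list(list(mean = 0.5, sd = 0.08,
                                          weight = 0.3)),
                        seed = 91)
  res <- detectWgd(ages, seed = 91)
  path <- withr::local_tempfile(fileext = ".tsv")
  writePeaks(res$peaks, path)
  back <- utils::read.delim(path)
  expect_identical(nrow(back), nrow(res$peaks))
  expect_equal(back$median, res$peaks$median, tolerance = 1e-9)
  png <- withr::local_tempfile(fileext = ".png")
  plotKs(ages, res$fit, path = png)
  expect_true(file.exists(png) && file.size(png) > 0)
})

test_that("the RNG state of the caller is not disturbed", {
  set.seed(212)
  before <- .Random.seed
  ages <- synthKsSample(500, seed = 1)
  invisible(fitKsMixture(ksValues(ages), kRange = 1:2, seed = 2))
  invisible(ksGoodnessOfFit(ksValues(ages), ksNullModel(1.5), seed = 3))
  expect_identical(.Random.seed, before)
})
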