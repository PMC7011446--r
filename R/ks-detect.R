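## Statistical detection of WGD peaks in gene-age (Ks) distributions:
## truncated-exponential null, K-S goodness of fit, Gaussian mixture EM
## with BIC model choice, and peak calling under the Ks <= 2 rule.

.windowKs <- function(ages, window) {
  ks <- if (is(ages, "AgeDistribution")) ksValues(ages) else as.numeric(ages)
  ks[ks > window[1] & ks <= window[2]]
}

#' Fit the no-WGD null model to an age distribution
#'
#' The null hypothesis is steady gene duplication with exponential survival
#' of paralogs: inside the analysis window the Ks values follow a truncated
#' exponential. The decay rate is fitted by maximum likelihood (1-D
#' numerical optimisation of the truncated-exponential log-likelihood).
#'
#' @param ages an [AgeDistribution-class] or numeric Ks vector.
#' @param ksMax upper window bound (2 or 5; default 2).
#' @param ksMin lower window bound (default 0.01, excluding the pile-up of
#'   near-identical recent duplicates and alleles).
#' @param minN minimum number of in-window values (default 100).
#' @return a [KsNullModel-class] object.
#' @export
fitNull <- function(ages, ksMax = 2, ksMin = 0.01, minN = 100) {
  x <- .windowKs(ages, c(ksMin, ksMax))
  if (length(x) < minN)
    stop(errorCondition(
      paste0("only ", length(x), " Ks values in (", ksMin, ", ", ksMax,
             "]; need ", minN),
      class = c("wgdinfer_insufficient", "error", "condition")))
  ll <- function(delta)
    sum(stats::dexp(x, delta, log = TRUE)) -
      length(x) * log(stats::pexp(ksMax, delta) - stats::pexp(ksMin, delta))
  opt <- stats::optimize(ll, c(1e-4, 200), maximum = TRUE, tol = 1e-9)
  new("KsNullModel", rate = opt$maximum, window = c(ksMin, ksMax),
      n = length(x))
}

#' Construct a null age model directly
#'
#' Builds a [KsNullModel-class] from a known decay rate, e.g. for
#' simulation studies or when the background rate is estimated elsewhere.
#'
#' @param rate positive decay rate per unit Ks.
#' @param window analysis window (default `c(0.01, 2)`).
#' @param n number of observations behind the rate (default 0).
#' @return a [KsNullModel-class].
#' @export
ksNullModel <- function(rate, window = c(0.01, 2), n = 0L) {
  new("KsNullModel", rate = rate, window = as.numeric(window),
      n = as.integer(n))
}

#' Sample from a truncated exponential
#'
#' Inverse-CDF sampling of the null age model on its window.
#'
#' @param n sample size.
#' @param null a [KsNullModel-class], or pass `rate` and `window`.
#' @param rate,window used when `null` is missing.
#' @return numeric vector of length `n`.
#' @export
rNullKs <- function(n, null = NULL, rate = NULL, window = c(0.01, 2)) {
  if (!is.null(null)) {
    rate <- null@rate
    window <- null@window
  }
  u <- stats::runif(n)
  a <- window[1]; b <- window[2]
  ea <- exp(-rate * a); eb <- exp(-rate * b)
  -log(ea - u * (ea - eb)) / rate
}

#' Kolmogorov-Smirnov test of an age distribution against the null
#'
#' Two-sample K-S test of the window-filtered observed Ks values against a
#' large sample simulated from the fitted null; the p-value uses the
#' asymptotic two-sample formula. Rejection indicates duplication-age
#' structure beyond the steady-background model, the first gate before
#' mixture-model peak interpretation.
#'
#' @param ages observed [AgeDistribution-class] or numeric vector.
#' @param null a [KsNullModel-class] from [fitNull()].
#' @param nSim null sample size (default 10000).
#' @param seed integer seed for the null sample.
#' @return list with elements `statistic` (D), `p.value`, `nObs`, `nSim`.
#' @export
ksGoodnessOfFit <- function(ages, null, nSim = 10000, seed = 1) {
  x <- .windowKs(ages, null@window)
  if (!length(x)) stop("no Ks values inside the null model window")
  simVals <- .withSeed(seed, rNullKs(nSim, null))
  kt <- suppressWarnings(stats::ks.test(x, simVals, alternative =
                                          "two.sided", exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = kt$p.value,
       nObs = length(x), nSim = nSim)
}

## ---- Gaussian mixture EM ---------------------------------------------

# k-means++-style spread of initial means
.initMeans <- function(x, k) {
  mu <- sample(x, 1)
  while (length(mu) < k) {
    d2 <- rep(Inf, length(x))
    for (m in mu) d2 <- pmin(d2, (x - m)^2)
    if (all(d2 == 0)) {
      mu <- c(mu, sample(x, k - length(mu), replace = TRUE))
      break
    }
    mu <- c(mu, sample(x, 1, prob = d2))
  }
  mu
}

.emFit <- function(x, k, tol, maxIter, trace = FALSE) {
  llTrace <- if (trace) numeric(0)
  n <- length(x)
  mu <- .initMeans(x, k)
  sd0 <- max(stats::sd(x) / k, 1e-3)
  sigma <- rep(sd0, k)
  w <- rep(1 / k, k)
  prevLL <- -Inf
  converged <- FALSE
  floorSd <- 1e-4
  dens <- matrix(0, n, k)
  invSqrt2Pi <- 1 / sqrt(2 * pi)
  for (iter in seq_len(maxIter)) {
    for (j in seq_len(k)) {
      z <- (x - mu[j]) / sigma[j]
      dens[, j] <- (w[j] * invSqrt2Pi / sigma[j]) * exp(-0.5 * z * z)
    }
    tot <- .rowSums(dens, n, k)
    tot[tot < 1e-300] <- 1e-300
    ll <- sum(log(tot))
    if (trace) llTrace <- c(llTrace, ll)
    resp <- dens / tot
    nk <- .colSums(resp, n, k)
    nk[nk < 1e-10] <- 1e-10
    w <- nk / n
    mu <- .colSums(resp * x, n, k) / nk
    for (j in seq_len(k))
      sigma[j] <- sqrt(sum(resp[, j] * (x - mu[j])^2) / nk[j])
    sigma[sigma < floorSd] <- floorSd
    if (is.finite(prevLL) && abs(ll - prevLL) < tol * (abs(prevLL) + 1)) {
      converged <- TRUE
      prevLL <- ll
      break
    }
    prevLL <- ll
  }
  ord <- order(mu)
  out <- list(w = w[ord], mu = mu[ord], sigma = sigma[ord],
              logLik = prevLL, converged = converged)
  if (trace) out$llTrace <- llTrace
  out
}

#' Fit Gaussian mixture models to an age distribution
#'
#' Expectation-maximisation on untransformed in-window Ks values for each
#' candidate number of components; the model is selected by BIC. Multiple
#' random restarts (k-means++-style initial means) guard against local
#' optima; results are deterministic for a given seed.
#'
#' @param ages observed [AgeDistribution-class] or numeric vector.
#' @param kRange candidate component counts (default 1:4).
#' @param nRestarts EM restarts per K (default 10).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param maxIter maximum EM iterations (default 250; restarts that have
#'   not converged by then are kept at their current log-likelihood, which
#'   only affects overfitted K values that lose the BIC comparison anyway).
#' @param seed integer seed.
#' @param window fitting window (default `c(0.01, 2)`).
#' @return a [KsMixtureFit-class] for the BIC-best K.
#' @export
fitKsMixture <- function(ages, kRange = 1:4, nRestarts = 10, tol = 1e-6,
                         maxIter = 250, seed = 1, window = c(0.01, 2)) {
  x <- .windowKs(ages, window)
  if (length(x) < 10) stop("too few Ks values in window to fit a mixture")
  n <- length(x)
  best <- NULL
  .rngSave()
  on.exit(.rngRestore())
  set.seed(seed)
  anyConverged <- FALSE
  for (k in kRange) {
    bestK <- NULL
    for (r in seq_len(nRestarts)) {
      fit <- .emFit(x, k, tol, maxIter)
      if (is.null(bestK) || fit$logLik > bestK$logLik) bestK <- fit
    }
    p <- 3 * k - 1
    bic <- -2 * bestK$logLik + p * log(n)
    if (is.null(best) || bic < best$bic) {
      best <- bestK
      best$bic <- bic
      best$k <- k
    }
    anyConverged <- anyConverged || bestK$converged
  }
  new("KsMixtureFit", k = as.integer(best$k), weight = best$w,
      mean = best$mu, sd = best$sigma, logLik = best$logLik,
      bic = best$bic, converged = best$converged, window = window,
      n = as.integer(n))
}

.mixtureDensity <- function(fit, grid) {
  rowSums(vapply(seq_len(fit@k), function(j)
    fit@weight[j] * stats::dnorm(grid, fit@mean[j], fit@sd[j]),
    numeric(length(grid))))
}

#' Posterior component assignment of Ks values
#'
#' @param fit a [KsMixtureFit-class].
#' @param x numeric Ks values.
#' @return integer vector of maximum-posterior component indices.
#' @export
mixtureAssign <- function(fit, x) {
  dens <- vapply(seq_len(fit@k), function(j)
    fit@weight[j] * stats::dnorm(x, fit@mean[j], fit@sd[j]),
    numeric(length(x)))
  dens <- matrix(dens, nrow = length(x))
  max.col(dens, ties.method = "first")
}

#' Call WGD peaks from a mixture fit
#'
#' A mixture component is treated as a peak when its weight is at least
#' `minWeight` and the fitted total density has a local maximum within one
#' component sd of the component mean. Each peak's reported median Ks is the
#' median of the observations assigned to the component by maximum
#' posterior responsibility, with a 95% nonparametric-bootstrap CI.
#' Peaks with median Ks > 2 are never promoted to WGD candidates without
#' corroboration (saturation makes deep peaks unreliable); peaks are only
#' labelled `WGD-candidate` when the K-S gate against the null rejected.
#'
#' @param fit a [KsMixtureFit-class].
#' @param ages observed ages used for assignment/bootstrap.
#' @param ksSignificant logical: did the K-S test against the null reject
#'   at alpha = 0.05? (default TRUE).
#' @param nBoot bootstrap replicates for the CI (default 200).
#' @param seed integer seed for the bootstrap.
#' @param minWeight minimum component weight for peak status (default 0.05).
#' @return data.frame with one row per component: component, weight, mean,
#'   sd, median, ciLo, ciHi, nAssigned, isPeak, status
#'   (`"WGD-candidate"`, `"needs-corroboration"`, `"background"`).
#' @export
callPeaks <- function(fit, ages, ksSignificant = TRUE, nBoot = 200,
                      seed = 1, minWeight = 0.05) {
  x <- .windowKs(ages, fit@window)
  assign <- mixtureAssign(fit, x)
  grid <- seq(fit@window[1], fit@window[2], length.out = 2000)
  dens <- .mixtureDensity(fit, grid)
  locmax <- grid[which(diff(sign(diff(dens))) == -2) + 1L]
  # a rising density at the window edge also counts as a mode
  if (length(dens) > 1 && dens[1] > dens[2]) locmax <- c(grid[1], locmax)
  if (dens[length(dens)] > dens[length(dens) - 1])
    locmax <- c(locmax, grid[length(grid)])
  .rngSave()
  on.exit(.rngRestore())
  set.seed(seed)
  rows <- lapply(seq_len(fit@k), function(j) {
    xs <- x[assign == j]
    med <- if (length(xs)) stats::median(xs) else NA_real_
    ci <- c(NA_real_, NA_real_)
    if (length(xs) >= 2 && nBoot > 0) {
      boots <- vapply(seq_len(nBoot), function(b)
        stats::median(sample(xs, length(xs), replace = TRUE)), numeric(1))
      ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    } else if (length(xs)) ci <- c(med, med)
    nearMode <- length(locmax) > 0 &&
      any(abs(locmax - fit@mean[j]) <= fit@sd[j])
    isPeak <- fit@weight[j] >= minWeight && nearMode && length(xs) > 0
    status <- if (!isPeak) "background"
              else if (!is.na(med) && med > 2) "needs-corroboration"
              else if (ksSignificant) "WGD-candidate"
              else "background"
    data.frame(component = j, weight = fit@weight[j], mean = fit@mean[j],
               sd = fit@sd[j], median = med, ciLo = ci[1], ciHi = ci[2],
               nAssigned = length(xs), isPeak = isPeak, status = status,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' One-call WGD detection on an age distribution
#'
#' Runs the full single-species detection sequence: fit the no-WGD null,
#' K-S test against it, Gaussian-mixture fit with BIC model choice, and
#' peak calling gated on the K-S result.
#'
#' @param ages an [AgeDistribution-class] or numeric Ks vector.
#' @param ksMax analysis window upper bound, 2 or 5 (default 2).
#' @param seed integer seed driving the null sample, EM restarts and
#'   bootstrap.
#' @param alpha K-S significance gate (default 0.05).
#' @param ... passed through to [fitKsMixture()] and [callPeaks()].
#' @return list with elements `null` ([KsNullModel-class]), `ks`
#'   (K-S test list), `fit` ([KsMixtureFit-class]), `peaks` (data.frame
#'   from [callPeaks()]).
#' @export
detectWgd <- function(ages, ksMax = 2, seed = 1, alpha = 0.05, ...) {
  null <- fitNull(ages, ksMax = ksMax)
  kt <- ksGoodnessOfFit(ages, null, seed = seed)
  fit <- fitKsMixture(ages, seed = seed, window = null@window, ...)
  peaks <- callPeaks(fit, ages, ksSignificant = kt$p.value < alpha,
                     seed = seed)
  list(null = null, ks = kt, fit = fit, peaks = peaks)
}

#' Write a peaks table to TSV
#'
#' @param peaks data.frame from [callPeaks()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeaks <- function(peaks, path) {
  utils::write.table(peaks, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Plot an age distribution with its mixture overlay
#'
#' Histogram of in-window Ks values with the fitted mixture density and
#' per-component curves, in the style of standard Ks plots.
#'
#' @param ages observed ages.
#' @param fit a [KsMixtureFit-class].
#' @param path output file (png); NULL plots to the active device.
#' @param breaks histogram breaks (default 50).
#' @return invisibly, the histogram object.
#' @export
plotKs <- function(ages, fit, path = NULL, breaks = 50) {
  x <- .windowKs(ages, fit@window)
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  h <- graphics::hist(x, breaks = breaks, freq = FALSE,
                      main = "Gene-age distribution",
                      xlab = "Ks", col = "grey85", border = "grey60")
  grid <- seq(fit@window[1], fit@window[2], length.out = 500)
  graphics::lines(grid, .mixtureDensity(fit, grid), lwd = 2)
  for (j in seq_len(fit@k))
    graphics::lines(grid,
                    fit@weight[j] * stats::dnorm(grid, fit@mean[j],
                                                 fit@sd[j]),
                    lty = 2)
  invisible(h)
}
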