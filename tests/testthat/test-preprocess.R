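test_that("peak selection keeps exactly the peaks above the base-peak fraction", {
  s <- DepthProfileSpectrum(c(100, 200, 300), c(1000, 5, 0.5))
  kept <- selectPeaks(s, 0.001)
  expect_identical(peakIntensity(kept), c(1000, 5))
  # single peak always survives
  one <- DepthProfileSpectrum(100, 42)
  expect_identical(peakIntensity(selectPeaks(one, 0.999)), 42)
  # brute-force oracle on a random spectrum
  set.seed(4)
  mz <- sort(runif(500, 80, 1000))
  int <- rlnorm(500, 5, 2)
  big <- DepthProfileSpectrum(mz, int)
  expect_identical(length(peakMz(selectPeaks(big, 0.001))),
                   sum(int >= max(int) * 0.001))
  expect_error(selectPeaks(big, 0), "thresholdFraction")
  expect_error(selectPeaks(DepthProfileSpectrum(numeric(0), numeric(0))),
               "empty")
})

test_that("alignment merges within the ppm window and separates beyond it", {
  mk <- function(mz, int = rep(1, length(mz)), site = 1L)
    DepthProfileSpectrum(mz, int, patientId = "P1", region = "viable",
                         siteIndex = site)
  # 4.0 ppm apart -> one feature; 15 ppm apart -> two
  fm <- alignFeatures(list(mk(200.0000, site = 1L), mk(200.0008, site = 2L)),
                      windowPpm = 5)
  expect_identical(nrow(fm), 1L)
  fm2 <- alignFeatures(list(mk(200.0000, site = 1L), mk(200.0030, site = 2L)),
                       windowPpm = 5)
  expect_identical(nrow(fm2), 2L)
  # identical single peaks -> one feature, exact centroid, nothing missing
  fm3 <- alignFeatures(list(mk(100, 2, 1L), mk(100, 4, 2L)), windowPpm = 5)
  expect_identical(featureCentroids(fm3), 100)
  expect_false(any(missingMask(fm3)))
  # 50 well-separated peaks in one spectrum -> identity partition
  mz50 <- seq(100, 590, by = 10)
  fm4 <- alignFeatures(list(mk(mz50)), windowPpm = 5)
  expect_identical(nrow(fm4), 50L)
  expect_false(any(missingMask(fm4)))
  expect_error(alignFeatures(list(mk(100)), windowPpm = 0), "windowPpm")
})

test_that("aligned features obey the window and re-aligning centroids is stable", {
  co <- generateCohort(smallCohortConfig(seed = 13L))
  spectra <- lapply(co$spectra, selectPeaks)
  fm <- alignFeatures(spectra, windowPpm = 5)
  ctr <- featureCentroids(fm)
  # consecutive centroids separated by more than the window
  expect_true(all(diff(ctr) / ctr[-length(ctr)] * 1e6 > 5))
  # every member peak within the window of its cluster centroid
  maxDev <- max(unlist(lapply(spectra, function(s) {
    vapply(peakMz(s), function(m) min(abs((m - ctr) / ctr * 1e6)), numeric(1))
  })))
  expect_lte(maxDev, 5)
  # re-aligning the centroids reproduces the same partition
  fm2 <- alignFeatures(list(DepthProfileSpectrum(ctr, rep(1, length(ctr)))),
                       windowPpm = 5)
  expect_equal(featureCentroids(fm2), ctr, tolerance = 1e-12)
})

test_that("a sample's feature value is the sum of its in-window peaks", {
  s <- DepthProfileSpectrum(c(200.0000, 200.0004), c(3, 4))  # 2 ppm apart
  fm <- alignFeatures(list(s), windowPpm = 5)
  expect_identical(nrow(fm), 1L)
  expect_identical(as.numeric(intensityMatrix(fm)), 7)
})

test_that("missing-value filter applies the strict 'more than' rule", {
  v <- matrix(1, nrow = 3, ncol = 10)
  v[1, 1:2] <- NA   # 20% missing -> retained
  v[2, 1:3] <- NA   # 30% missing -> removed
  fm <- makeMatrix(v, transforms = c("select", "align"))
  out <- filterMissing(fm, 0.20)
  expect_identical(nrow(out), 2L)
  expect_identical(featureCentroids(out), featureCentroids(fm)[c(1, 3)])
  # fully observed matrix unchanged
  full <- makeMatrix(matrix(1:9, 3), transforms = c("select", "align"))
  expect_identical(nrow(filterMissing(full)), 3L)
})

test_that("knn imputation matches a brute-force nearest neighbour at k = 1", {
  # 3 features x 3 samples; sample distances computable by hand
  v <- matrix(c(1, 10, 5,
                2, 11, NA,
                9, 30, 5), nrow = 3)
  fm <- makeMatrix(v)
  out <- knnImpute(fm, k = 1L)
  # brute-force: over jointly observed standardized features, sample 2 is
  # nearer to sample 1 than to sample 3
  z <- t(scale(t(v)))
  d21 <- mean((z[1:2, 2] - z[1:2, 1])^2)
  d23 <- mean((z[1:2, 2] - z[1:2, 3])^2)
  donor <- if (d21 < d23) 1 else 3
  expect_identical(intensityMatrix(out)[3, 2], v[3, donor])
  # observed cells unchanged, mask cleared
  expect_identical(intensityMatrix(out)[, 1], intensityMatrix(fm)[, 1])
  expect_false(any(missingMask(out)))
  expect_error(knnImpute(fm, k = 0), "k must be")
})

test_that("imputed values stay within the donor range and identity holds with no missing", {
  co <- generateCohort(smallCohortConfig(seed = 8L))
  fm <- filterMissing(alignFeatures(lapply(co$spectra, selectPeaks)))
  v <- intensityMatrix(fm)
  out <- intensityMatrix(knnImpute(fm, k = 5L))
  miss <- which(is.na(v), arr.ind = TRUE)
  for (r in seq_len(min(nrow(miss), 50))) {
    f <- miss[r, 1]
    rng <- range(v[f, ], na.rm = TRUE)
    expect_gte(out[miss[r, 1], miss[r, 2]], rng[1])
    expect_lte(out[miss[r, 1], miss[r, 2]], rng[2])
  }
  full <- makeMatrix(matrix(1:9, 3))
  expect_identical(intensityMatrix(knnImpute(full, 2L)),
                   intensityMatrix(full))
})

test_that("background removal drops only within-tolerance centroids", {
  fm <- makeMatrix(matrix(1:9, 3), centroids = c(100, 200, 300))
  expect_identical(nrow(removeBackground(fm)), 3L)
  expect_message(out <- removeBackground(fm, blacklist = 200), "dropping")
  expect_identical(featureCentroids(out), c(100, 300))
  # 10 ppm away at 5 ppm tolerance: no removal
  out2 <- removeBackground(fm, blacklist = 100 * (1 + 10e-6), tolerancePpm = 5)
  expect_identical(nrow(out2), 3L)
})

test_that("TIC normalization makes every sample sum to one and is idempotent", {
  fm <- makeMatrix(matrix(c(1, 3, 2, 2), nrow = 2))
  out <- ticNormalize(fm)
  expect_equal(unname(intensityMatrix(out)[, 1]), c(0.25, 0.75))
  expect_true(all(abs(colSums(intensityMatrix(out)) - 1) < 1e-12))
  out2 <- ticNormalize(out)
  expect_equal(intensityMatrix(out2), intensityMatrix(out), tolerance = 1e-15)
  # single feature -> all ones
  one <- ticNormalize(makeMatrix(matrix(c(5, 8), nrow = 1)))
  expect_true(all(intensityMatrix(one) == 1))
  # zero-total sample is a data error naming the sample
  bad <- makeMatrix(matrix(c(0, 0, 1, 2), nrow = 2))
  expect_error(ticNormalize(bad), "zero total ion count.*P01")
})

test_that("Pareto scaling centres and divides by the root standard deviation", {
  fm <- makeMatrix(matrix(c(1, 2, 3), nrow = 1), regions = "viable",
                   transforms = c("knn_impute", "tic_normalize"))
  out <- paretoScale(fm)
  expect_equal(unname(intensityMatrix(out)[1, ]), c(-1, 0, 1))
  # post-scaling variance equals pre-scaling sd
  set.seed(2)
  v <- matrix(rnorm(5 * 20, sd = 4), nrow = 5)
  fm2 <- makeMatrix(v)
  out2 <- paretoScale(fm2)
  for (i in 1:5)
    expect_equal(var(intensityMatrix(out2)[i, ]), sd(v[i, ]),
                 tolerance = 1e-9)
  # constant feature -> zeros with a warning
  fm3 <- makeMatrix(matrix(c(1, 1, 1, 2, 3, 4), nrow = 2, byrow = TRUE))
  expect_warning(out3 <- paretoScale(fm3), "constant")
  expect_true(all(intensityMatrix(out3)[1, ] == 0))
})

test_that("the transform log enforces pipeline order and forbids double Pareto", {
  co <- generateCohort(syntheticConfig(nPatients = 2, sitesPerRegion = 2,
                                       nBackgroundCompounds = 30,
                                       nDiscriminativeCompounds = 2, seed = 1))
  fm <- alignFeatures(lapply(co$spectra, selectPeaks))
  expect_error(ticNormalize(fm), "requires prior|imputed")
  fmP <- paretoScale(ticNormalize(knnImpute(filterMissing(fm))))
  expect_identical(transformLog(fmP),
                   c("align", "filter_missing", "knn_impute",
                     "tic_normalize", "pareto_scale"))
  expect_error(paretoScale(fmP), "already applied")
})
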