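test_that("PCA reproduces the top singular subspace of a fixture", {
  set.seed(6)
  X <- matrix(rnorm(60), nrow = 6)           # 6 x 10
  m <- fitPCA(X, nComponents = 3)
  # oracle: direct SVD of the centred matrix, agreement up to sign
  sv <- svd(scale(X, center = TRUE, scale = FALSE))
  for (a in 1:3) {
    expect_equal(abs(sum(m@loadings[, a] * sv$v[, a])), 1, tolerance = 1e-8)
    expect_equal(abs(m@scores[, a]), abs(sv$u[, a] * sv$d[a]),
                 tolerance = 1e-8)
  }
  # loadings orthonormal
  expect_equal(crossprod(m@loadings), diag(3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # cumulative R2X non-decreasing, <= 1
  expect_true(all(diff(m@explainedR2X) >= 0))
  expect_lte(max(m@explainedR2X), 1 + 1e-12)
})

test_that("rank-1 data is fully explained by one component", {
  t1 <- rnorm(8); p1 <- rnorm(12)
  X <- outer(t1, p1)
  m <- fitPCA(X, nComponents = 1)
  expect_equal(m@explainedR2X[1], 1, tolerance = 1e-10)
  expect_warning(fitPCA(X[1:3, ], nComponents = 5), "reduced")
})

test_that("OPLS-DA with zero orthogonal components equals NIPALS PLS1", {
  set.seed(12)
  X <- matrix(rnorm(8 * 12), nrow = 8)
  y <- rep(c(-1, 1), each = 4)
  labels <- factor(rep(c("necrotic", "viable"), each = 4))
  m <- fitOPLSDA(X, labels, nOrthogonal = 0L)
  o <- pls1Oracle(X, y)
  sgn <- sign(sum(m@w * o$w))
  expect_equal(m@w * sgn, o$w, tolerance = 1e-8)
  expect_equal(m@t * sgn, o$t, tolerance = 1e-8)
  expect_equal(m@p * sgn, o$p, tolerance = 1e-8)
})

test_that("predictive scores are orthogonal to every orthogonal component", {
  co <- generateCohort(smallCohortConfig(seed = 19L))
  fm <- preprocessCohort(co$spectra)
  for (k in 1:3) {
    m <- fitOPLSDA(fm, nOrthogonal = k)
    expect_identical(ncol(m@To), k)
    for (a in seq_len(k))
      expect_lt(abs(sum(m@t * m@To[, a])) /
                  (sqrt(sum(m@t^2)) * sqrt(sum(m@To[, a]^2))), 1e-8)
    # filtered X retains no variation along the orthogonal weights: the
    # predictive weight is orthogonal to each w_o by construction
    for (a in seq_len(k))
      expect_lt(abs(sum(m@w * m@Wo[, a])), 1e-8)
  }
})

test_that("VIP scores are mean-square normalized and find the signal", {
  set.seed(33)
  n <- 24
  labels <- factor(rep(c("necrotic", "viable"), each = n / 2))
  y <- ifelse(labels == "necrotic", -1, 1)
  X <- matrix(rnorm(n * 30, sd = 0.5), nrow = n)
  X[, 7] <- y * 2 + rnorm(n, sd = 0.2)       # single informative feature
  m <- fitOPLSDA(X, labels, nOrthogonal = 1L)
  vip <- vipScores(m)
  expect_equal(sum(vip^2), 30, tolerance = 1e-8)
  expect_identical(which.max(vip), 7L)
  # all features identical copies of the signal -> all VIP exactly 1
  Xs <- matrix(rep(y * 2 + rnorm(n, sd = 0.2), 5), nrow = n)
  ms <- fitOPLSDA(Xs, labels, nOrthogonal = 0L)
  expect_equal(vipScores(ms), rep(1, 5), tolerance = 1e-10)
})

test_that("S-plot coordinates agree with closed-form covariance/correlation", {
  set.seed(44)
  X <- matrix(rnorm(20 * 15), nrow = 20)
  labels <- factor(rep(c("necrotic", "viable"), each = 10))
  m <- fitOPLSDA(X, labels, nOrthogonal = 1L)
  sp <- sPlot(m)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  for (j in c(1, 5, 15)) {
    expect_equal(sp$covariance[j], cov(m@t, Xc[, j]), tolerance = 1e-10)
    expect_equal(sp$correlation[j], cor(m@t, Xc[, j]), tolerance = 1e-10)
  }
  expect_true(all(abs(sp$correlation) <= 1 + 1e-12))
  # rank-1 data: every feature is an exact multiple of the score vector,
  # so correlation is exactly +/- 1 by feature sign
  set.seed(45)
  v <- rnorm(20)
  coefs <- c(1, 2, -1, 3)
  X2 <- outer(v, coefs)
  lab2 <- factor(ifelse(v > median(v), "necrotic", "viable"))
  m2 <- fitOPLSDA(X2, lab2, nOrthogonal = 0L)
  sp2 <- sPlot(m2)
  s <- sign(cor(m2@t, v))
  expect_equal(sp2$correlation, s * sign(coefs), tolerance = 1e-10)
})

test_that("zero-variance features get zero correlation with a warning", {
  set.seed(3)
  X <- cbind(matrix(rnorm(12 * 4), nrow = 12), 5)
  labels <- factor(rep(c("necrotic", "viable"), each = 6))
  expect_warning(m <- fitOPLSDA(X, labels), "zero-variance")
  expect_identical(sPlot(m)$correlation[5], 0)
})

test_that("Q2 is near zero on permuted structureless data", {
  set.seed(55)
  q2s <- replicate(50, {
    X <- matrix(rnorm(16 * 25), nrow = 16)
    labels <- factor(rep(c("necrotic", "viable"), each = 8)[sample(16)])
    modelQ2(fitOPLSDA(X, labels, nOrthogonal = 1L))
  })
  expect_lt(mean(q2s), 0.1)
})

test_that("Q2 degrades monotonically as the effect size shrinks", {
  q2At <- function(es) {
    co <- generateCohort(smallCohortConfig(seed = 77L, effectSize = es))
    modelQ2(fitOPLSDA(preprocessCohort(co$spectra)))
  }
  q2s <- vapply(c(2, 1, 0.5, 0), q2At, numeric(1))
  expect_true(all(diff(q2s) < 0))
  expect_gt(q2s[1], 0.4)
})

test_that("spiked features are recovered by VIP >= 1", {
  co <- generateCohort(smallCohortConfig(seed = 101L))
  fm <- preprocessCohort(co$spectra)
  m <- fitOPLSDA(fm)
  tr <- truthAssignments(co$truth)
  idx <- matchTruthFeatures(tr$theoretical_mz[tr$spiked],
                            featureCentroids(fm))
  hit <- !is.na(idx) & vipScores(m)[ifelse(is.na(idx), 1L, idx)] >= 1
  expect_gte(mean(hit), 0.9)
})

test_that("permutation test is seeded, calibrated and detects real structure", {
  co <- generateCohort(smallCohortConfig(seed = 23L,
                                         nBackgroundCompounds = 60,
                                         nDiscriminativeCompounds = 10,
                                         sitesPerRegion = 3L,
                                         nPatients = 2L))
  fm <- preprocessCohort(co$spectra)
  r1 <- permutationTest(fm, nPermutations = 99L, seed = 7L)
  r2 <- permutationTest(fm, nPermutations = 99L, seed = 7L)
  expect_identical(r1$q2Permuted, r2$q2Permuted)
  # strong separation: no permuted Q2 reaches the observed one
  expect_identical(r1$pValue, 1 / 100)
  expect_error(permutationTest(fm, nPermutations = 0L), "nPermutations")
})

test_that("permutation p-values are uniform-ish under the null", {
  set.seed(99)
  ps <- replicate(20, {
    X <- matrix(rnorm(12 * 20), nrow = 12)
    labels <- factor(rep(c("necrotic", "viable"), each = 6))
    permutationTest(X, labels, nPermutations = 39L,
                    seed = sample.int(1e6, 1))$pValue
  })
  expect_gte(mean(ps > 0.05), 0.9)
})
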