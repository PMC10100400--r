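test_that("config validation names the offending field", {
  expect_error(syntheticConfig(sitesPerRegion = 1), "sitesPerRegion")
  expect_error(syntheticConfig(missingRate = 0.7), "missingRate")
  expect_error(syntheticConfig(massJitterPpm = -1), "massJitterPpm")
  expect_error(syntheticConfig(mzRange = c(10, 2000)), "mzRange")
  expect_error(syntheticConfig(regions = c("viable", "tumour")), "regions")
})

test_that("identical seed and config give identical cohort and truth", {
  cfg <- smallCohortConfig(seed = 5L)
  a <- generateCohort(cfg)
  b <- generateCohort(cfg)
  expect_identical(lapply(a$spectra, peakMz), lapply(b$spectra, peakMz))
  expect_identical(lapply(a$spectra, peakIntensity),
                   lapply(b$spectra, peakIntensity))
  expect_identical(truthAssignments(a$truth), truthAssignments(b$truth))
  expect_identical(truthEffects(a$truth), truthEffects(b$truth))
  c2 <- generateCohort(smallCohortConfig(seed = 6L))
  expect_false(identical(lapply(a$spectra, peakMz),
                         lapply(c2$spectra, peakMz)))
})

test_that("cohort has one spectrum per patient x region x site with correct metadata", {
  cfg <- syntheticConfig(nPatients = 2, sitesPerRegion = 2,
                         nBackgroundCompounds = 30,
                         nDiscriminativeCompounds = 2, seed = 3)
  co <- generateCohort(cfg)
  expect_length(co$spectra, 2 * 3 * 2)
  regions <- vapply(co$spectra, sampleRegion, "")
  expect_identical(sort(unique(regions)), sort(cfg$regions))
  expect_true(all(table(regions) == 2 * 2))
  # every spiked compound appears in the emitted compound table
  eff <- truthEffects(co$truth)
  expect_true(all(eff$compound_id %in% co$compounds$compound_id))
  # effects cover exactly nDiscriminativeCompounds per one-vs-rest contrast
  expect_identical(as.vector(table(eff$region)[cfg$regions]), rep(2L, 3))
})

test_that("zero effect size leaves no true region effect", {
  co <- generateCohort(smallCohortConfig(seed = 9L, effectSize = 0))
  expect_true(all(truthEffects(co$truth)$magnitude == 0))
})

test_that("observed missing fraction falls in the central 99% binomial interval", {
  # 250 compounds-ish x 40 samples ~ 8800 cells at rate 0.1
  cfg <- smallCohortConfig(seed = 21L, missingRate = 0.1)
  co <- generateCohort(cfg)
  mask <- co$truth@missingMaskTruth
  n <- length(mask)
  # oracle: central 99% binomial interval computed independently
  lo <- qbinom(0.005, n, 0.1) / n
  hi <- qbinom(0.995, n, 0.1) / n
  expect_gte(mean(mask), lo)
  expect_lte(mean(mask), hi)
  # intensity-dependent mechanism masks low-intensity cells preferentially:
  # spiked (high-abundance) compounds are missing less often than average
  tr <- truthAssignments(co$truth)
  expect_lt(mean(mask[tr$spiked, ]), mean(mask))
})

test_that("mcar missingness hits the marginal rate too", {
  cfg <- smallCohortConfig(seed = 22L, missingRate = 0.2,
                           missingMechanism = "mcar")
  mask <- generateCohort(cfg)$truth@missingMaskTruth
  n <- length(mask)
  expect_gte(mean(mask), qbinom(0.005, n, 0.2) / n)
  expect_lte(mean(mask), qbinom(0.995, n, 0.2) / n)
})

test_that("per-peak ppm deviations follow the configured jitter", {
  cfg <- smallCohortConfig(seed = 17L, massJitterPpm = 1, missingRate = 0)
  co <- generateCohort(cfg)
  theo <- truthAssignments(co$truth)$theoretical_mz
  devs <- unlist(lapply(co$spectra, function(s) {
    obs <- peakMz(s)
    vapply(obs, function(m) {
      d <- (m - theo) / theo * 1e6
      d[which.min(abs(d))]
    }, numeric(1))
  }))
  expect_equal(sd(devs), 1, tolerance = 0.05)
  expect_lt(max(abs(devs)), 6)   # ~8000 draws; P(any |z| > 6) ~ 1e-5
})

test_that("spiked log-intensity effects are calibrated in Cohen's d units", {
  cfg <- syntheticConfig(regions = c("necrotic", "viable"),
                         nPatients = 4, sitesPerRegion = 50,
                         nBackgroundCompounds = 20,
                         nDiscriminativeCompounds = 5,
                         effectSize = 2, missingRate = 0, massJitterPpm = 0,
                         seed = 31)
  co <- generateCohort(cfg)
  tr <- truthAssignments(co$truth)
  eff <- truthEffects(co$truth)
  regions <- vapply(co$spectra, sampleRegion, "")
  logI <- sapply(co$spectra, function(s) log(peakIntensity(s)))
  rownames(logI) <- tr$compound_id   # jitter 0, missing 0: rows align
  nPer <- sum(regions == "necrotic")
  for (i in seq_len(nrow(eff))) {
    x <- logI[eff$compound_id[i], regions == eff$region[i]]
    y <- logI[eff$compound_id[i], regions != eff$region[i]]
    sp <- sqrt((var(x) + var(y)) / 2)
    d <- (mean(x) - mean(y)) / sp
    se <- sqrt(1 / length(x) + 1 / length(y) + d^2 / (2 * (length(x) + length(y))))
    expect_lt(abs(abs(d) - 2), 3 * se)
    expect_identical(sign(d), eff$direction[i])
  }
})

test_that("sumScans sums intensities per m/z key", {
  s <- DepthProfileSpectrum(c(100, 200), c(1, 2), patientId = "P1",
                            region = "necrotic")
  expect_identical(peakIntensity(sumScans(list(s))), c(1, 2))
  stack <- rep(list(s), 80)
  expect_identical(peakIntensity(sumScans(stack)), c(80, 160))
  # disjoint m/z keys: brute-force union oracle
  t <- DepthProfileSpectrum(c(150, 250), c(5, 7))
  u <- sumScans(list(s, t))
  expect_identical(peakMz(u), c(100, 150, 200, 250))
  expect_identical(peakIntensity(u), c(1, 5, 2, 7))
  expect_error(sumScans(list()), "empty")
})
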