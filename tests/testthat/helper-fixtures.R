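# shared fixtures and independent oracles

# small two-class cohort used by several suites
smallCohortConfig <- function(seed = 42L, ...) {
  args <- list(regions = c("necrotic", "viable"),
               nBackgroundCompounds = 180L,
               nDiscriminativeCompounds = 20L,
               effectSize = 2, missingRate = 0.1, massJitterPpm = 1,
               seed = seed)
  do.call(syntheticConfig, utils::modifyList(args, list(...)))
}

# a FeatureMatrix built directly from a values matrix (features x samples)
makeMatrix <- function(values, centroids = NULL,
                       regions = rep(c("necrotic", "viable"),
                                     length.out = ncol(values)),
                       transforms = character(0)) {
  if (is.null(centroids)) centroids <- 100 + seq_len(nrow(values))
  FeatureMatrix(values, centroids,
                data.frame(patient_id = "P01", region = regions,
                           site_index = seq_len(ncol(values))),
                transforms = transforms)
}

# independent one-component NIPALS PLS1 oracle (samples x features X)
pls1Oracle <- function(X, y) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  w <- drop(crossprod(Xc, yc))
  w <- w / sqrt(sum(w^2))
  t <- drop(Xc %*% w)
  p <- drop(crossprod(Xc, t)) / sum(t^2)
  list(w = w, t = t, p = p)
}

# match truth theoretical m/z values to feature centroids within a ppm window
matchTruthFeatures <- function(theoreticalMz, centroids, tolerancePpm = 5) {
  vapply(theoreticalMz, function(mz) {
    d <- abs((centroids - mz) / mz * 1e6)
    if (min(d) <= tolerancePpm) which.min(d) else NA_integer_
  }, integer(1))
}
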