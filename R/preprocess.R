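# Enforced processing order; each step checks its prerequisites against the
# matrix's transform log so the chain matches the documented sequence:
# select -> align -> filter_missing -> knn_impute -> remove_background ->
# tic_normalize -> pareto_scale.
.checkTransformOrder <- function(x, step, requires = character(0),
                                 forbids = character(0)) {
  tl <- transformLog(x)
  # order is enforced only for matrices originating from the package's own
  # alignment; externally prepared matrices may run any individual step
  if ("align" %in% tl) {
    missing <- setdiff(requires, tl)
    if (length(missing))
      stop("'", step, "' requires prior step(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  dup <- intersect(forbids, tl)
  if (length(dup))
    stop("'", step, "' already applied (transform log: ",
         paste(tl, collapse = " -> "), ")", call. = FALSE)
  invisible(TRUE)
}

#' Select peaks above a fraction of the base peak
#'
#' Retains exactly the peaks with intensity >= \code{thresholdFraction}
#' times the base-peak (maximum) intensity. The default 0.001 is the 0.1%
#' automatic selection threshold.
#'
#' @param spectrum A \linkS4class{DepthProfileSpectrum}.
#' @param thresholdFraction Fraction of base-peak intensity in (0, 1).
#' @return The thresholded spectrum.
#' @export
selectPeaks <- function(spectrum, thresholdFraction = 0.001) {
  stopifnot(is(spectrum, "DepthProfileSpectrum"))
  if (!length(peakMz(spectrum))) stop("empty spectrum", call. = FALSE)
  if (!(thresholdFraction > 0 && thresholdFraction < 1))
    stop("thresholdFraction must be in (0, 1)", call. = FALSE)
  cut <- thresholdFraction * max(peakIntensity(spectrum))
  keep <- peakIntensity(spectrum) >= cut
  initialize(spectrum, mz = peakMz(spectrum)[keep],
             intensity = peakIntensity(spectrum)[keep])
}

#' Align peaks across spectra within a ppm window
#'
#' Pools all peaks from all spectra, sorts ascending by m/z, and sweeps
#' left to right: a peak starts a new feature when its ppm distance to the
#' running intensity-weighted centroid of the current cluster exceeds
#' \code{windowPpm}. Adjacent clusters whose final centroids fall within the
#' window are merged, so consecutive feature centroids are always separated
#' by more than the window. A sample's value for a feature is the sum of
#' its peaks in that cluster; sample-feature pairs with no peak are missing.
#'
#' @param spectra List of \linkS4class{DepthProfileSpectrum}.
#' @param windowPpm Alignment window in ppm (default 5).
#' @return A \linkS4class{FeatureMatrix} with missing cells where a sample
#'   contributed no peak.
#' @export
alignFeatures <- function(spectra, windowPpm = 5) {
  if (windowPpm <= 0) stop("windowPpm must be > 0", call. = FALSE)
  if (!length(spectra)) stop("no spectra to align", call. = FALSE)
  stopifnot(all(vapply(spectra, is, TRUE, "DepthProfileSpectrum")))

  mz <- unlist(lapply(spectra, peakMz))
  intensity <- unlist(lapply(spectra, peakIntensity))
  sampleIdx <- rep(seq_along(spectra),
                   vapply(spectra, function(s) length(peakMz(s)), 1L))
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]; sampleIdx <- sampleIdx[o]

  n <- length(mz)
  cluster <- integer(n)
  cid <- 0L; wSum <- 0; wmzSum <- 0
  for (i in seq_len(n)) {
    newCluster <- cid == 0L ||
      abs(mz[i] - wmzSum / wSum) / (wmzSum / wSum) * 1e6 > windowPpm
    if (newCluster) {
      cid <- cid + 1L; wSum <- 0; wmzSum <- 0
    }
    cluster[i] <- cid
    w <- max(intensity[i], .Machine$double.eps)
    wSum <- wSum + w; wmzSum <- wmzSum + w * mz[i]
  }

  repeat {
    centroids <- as.numeric(rowsum(intensity * mz, cluster) /
                              pmax(rowsum(intensity, cluster), .Machine$double.eps))
    if (length(centroids) < 2L) break
    gap <- abs(diff(centroids)) / centroids[-length(centroids)] * 1e6
    tooClose <- which(gap <= windowPpm)
    if (!length(tooClose)) break
    # merge the closest adjacent pair and recompute
    k <- tooClose[which.min(gap[tooClose])]
    cluster[cluster > k] <- cluster[cluster > k] - 1L
  }

  nF <- max(cluster)
  values <- matrix(NA_real_, nrow = nF, ncol = length(spectra))
  idx <- cbind(cluster, sampleIdx)
  agg <- rowsum(intensity, group = paste(cluster, sampleIdx, sep = "_"))
  keys <- do.call(rbind, strsplit(rownames(agg), "_", fixed = TRUE))
  values[cbind(as.integer(keys[, 1]), as.integer(keys[, 2]))] <- agg[, 1]

  meta <- data.frame(
    patient_id = vapply(spectra, function(s) s@patientId, ""),
    region = vapply(spectra, function(s) s@region, ""),
    site_index = vapply(spectra, function(s) s@siteIndex, 1L),
    stringsAsFactors = FALSE)
  out <- FeatureMatrix(values, centroids, meta, transforms = "align")
  metadata(out)$windowPpm <- windowPpm
  out
}

#' Remove features with too many missing values
#'
#' Features whose missing fraction exceeds \code{maxMissingFraction} are
#' removed (strictly more than: a feature missing in exactly 20% of samples
#' is retained at the default). Feature order is preserved.
#'
#' @param matrix A \linkS4class{FeatureMatrix}.
#' @param maxMissingFraction Maximum tolerated missing fraction (default 0.20).
#' @return The filtered matrix.
#' @export
filterMissing <- function(matrix, maxMissingFraction = 0.20) {
  stopifnot(is(matrix, "FeatureMatrix"))
  .checkTransformOrder(matrix, "filter_missing", requires = "align")
  frac <- rowMeans(missingMask(matrix))
  keep <- frac <= maxMissingFraction
  if (!any(keep))
    message("filterMissing: no feature passes the ",
            maxMissingFraction * 100, "% missing cutoff")
  out <- matrix[keep, ]
  .logTransform(out, "filter_missing")
}

#' k-nearest-neighbour imputation of missing cells
#'
#' Missing cells are replaced by the mean of the k nearest samples'
#' observed values for that feature. Sample-sample distance is Euclidean
#' over jointly observed, per-feature standardized values, normalized by
#' the number of jointly observed features; ties are broken by sample
#' order. When a cell has fewer than k observing donors, all donors are
#' used. Observed cells are unchanged; the missing mask is cleared.
#'
#' @param matrix A \linkS4class{FeatureMatrix}.
#' @param k Number of neighbours (default 5).
#' @return The imputed matrix (no missing cells).
#' @export
knnImpute <- function(matrix, k = 5L) {
  stopifnot(is(matrix, "FeatureMatrix"))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  .checkTransformOrder(matrix, "knn_impute", requires = "filter_missing")
  v <- intensityMatrix(matrix)          # features x samples
  if (!anyNA(v)) return(.logTransform(matrix, "knn_impute"))
  mu <- rowMeans(v, na.rm = TRUE)
  sdv <- apply(v, 1, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z <- (v - mu) / sdv
  nS <- ncol(v)
  # mean squared difference over jointly observed features
  d2 <- matrix(Inf, nS, nS)
  for (a in seq_len(nS - 1L)) {
    for (b in seq((a + 1L), nS)) {
      joint <- !is.na(z[, a]) & !is.na(z[, b])
      if (any(joint)) {
        d2[a, b] <- d2[b, a] <- mean((z[joint, a] - z[joint, b])^2)
      }
    }
  }
  out <- v
  for (s in seq_len(nS)) {
    miss <- which(is.na(v[, s]))
    if (!length(miss)) next
    ord <- order(d2[, s])               # stable: ties by sample order
    ord <- ord[ord != s]
    for (f in miss) {
      donors <- ord[!is.na(v[f, ord])]
      if (!length(donors))
        stop("feature at m/z ", sprintf("%.4f", featureCentroids(matrix)[f]),
             " has no observed donor for sample ", s, call. = FALSE)
      use <- donors[seq_len(min(k, length(donors)))]
      out[f, s] <- mean(v[f, use])
    }
  }
  assay(matrix, "intensity") <- out
  .logTransform(matrix, "knn_impute")
}

#' Remove background features by an m/z blacklist
#'
#' Features whose centroid lies within \code{tolerancePpm} of any blacklist
#' entry are dropped. The default blacklist is empty (the identity).
#'
#' @param matrix A \linkS4class{FeatureMatrix}.
#' @param blacklist Numeric vector of background m/z values.
#' @param tolerancePpm Matching tolerance in ppm.
#' @return The filtered matrix.
#' @export
removeBackground <- function(matrix, blacklist = numeric(0),
                             tolerancePpm = 5) {
  stopifnot(is(matrix, "FeatureMatrix"))
  .checkTransformOrder(matrix, "remove_background", requires = "knn_impute")
  if (length(blacklist)) {
    ctr <- featureCentroids(matrix)
    hit <- vapply(ctr, function(m)
      any(abs(ppmError(m, blacklist)) <= tolerancePpm), TRUE)
    if (any(hit))
      message("removeBackground: dropping ", sum(hit), " feature(s) at m/z ",
              paste(sprintf("%.4f", ctr[hit]), collapse = ", "))
    matrix <- matrix[!hit, ]
  }
  .logTransform(matrix, "remove_background")
}

#' Total-ion-count normalization
#'
#' Divides each sample's intensities by that sample's total, so every
#' sample sums to 1. Requires imputation first (no missing cells).
#'
#' @param matrix A \linkS4class{FeatureMatrix}.
#' @return The normalized matrix.
#' @export
ticNormalize <- function(matrix) {
  stopifnot(is(matrix, "FeatureMatrix"))
  .checkTransformOrder(matrix, "tic_normalize", requires = "knn_impute")
  v <- intensityMatrix(matrix)
  if (anyNA(v)) stop("ticNormalize requires an imputed matrix", call. = FALSE)
  totals <- colSums(v)
  if (any(totals <= 0))
    stop("zero total ion count for sample(s): ",
         paste(colnames(v)[totals <= 0], collapse = ", "), call. = FALSE)
  assay(matrix, "intensity") <- sweep(v, 2, totals, "/")
  .logTransform(matrix, "tic_normalize")
}

#' Pareto scaling
#'
#' Mean-centres each feature and divides by the square root of its standard
#' deviation (n-1 denominator), the usual compromise between no scaling and
#' unit-variance scaling: after scaling, a feature's variance equals its
#' pre-scaling standard deviation. Constant features are set to zero with a
#' warning rather than dropped.
#'
#' @param matrix A \linkS4class{FeatureMatrix}.
#' @return The scaled matrix.
#' @export
paretoScale <- function(matrix) {
  stopifnot(is(matrix, "FeatureMatrix"))
  .checkTransformOrder(matrix, "pareto_scale", requires = "tic_normalize",
                       forbids = "pareto_scale")
  v <- intensityMatrix(matrix)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, stats::sd)
  const <- sdv == 0 | !is.finite(sdv)
  if (any(const)) {
    warning("paretoScale: ", sum(const),
            " constant feature(s) set to zero", call. = FALSE)
    sdv[const] <- 1
  }
  out <- (v - mu) / sqrt(sdv)
  out[const, ] <- 0
  assay(matrix, "intensity") <- out
  .logTransform(matrix, "pareto_scale")
}

#' Run the full preprocessing chain on a set of spectra
#'
#' Convenience wrapper executing the documented order: peak selection,
#' ppm-window alignment, missing-value filtering, knn imputation,
#' background removal, TIC normalization and (optionally) Pareto scaling.
#'
#' @param spectra List of \linkS4class{DepthProfileSpectrum}.
#' @param thresholdFraction,windowPpm,maxMissingFraction,k,blacklist
#'   Parameters passed to the individual steps.
#' @param pareto Apply Pareto scaling as the final step (set \code{FALSE}
#'   to obtain the TIC-normalized matrix used for univariate testing).
#' @return A \linkS4class{FeatureMatrix}.
#' @export
preprocessCohort <- function(spectra, thresholdFraction = 0.001,
                             windowPpm = 5, maxMissingFraction = 0.20,
                             k = 5L, blacklist = numeric(0), pareto = TRUE) {
  spectra <- lapply(spectra, selectPeaks, thresholdFraction = thresholdFraction)
  fm <- alignFeatures(spectra, windowPpm = windowPpm)
  fm <- filterMissing(fm, maxMissingFraction = maxMissingFraction)
  fm <- knnImpute(fm, k = k)
  fm <- removeBackground(fm, blacklist = blacklist)
  fm <- ticNormalize(fm)
  if (pareto) fm <- paretoScale(fm)
  fm
}
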