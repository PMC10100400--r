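#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData colData assay<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

.REGIONS <- c("necrotic", "viable", "non_cancerous")

#' DepthProfileSpectrum: one site's summed-scan peak list
#'
#' A single depth-profile spectrum: the sum over sputter-analyse scans at
#' one site, as an (m/z, intensity) peak list with sample metadata. m/z is
#' strictly increasing (duplicates are summed on construction) and
#' intensities are non-negative.
#'
#' @slot mz Numeric, strictly increasing m/z values (Da).
#' @slot intensity Numeric, non-negative ion counts, same length as mz.
#' @slot patientId Character scalar.
#' @slot region One of \code{"necrotic"}, \code{"viable"}, \code{"non_cancerous"}.
#' @slot siteIndex Integer site replicate index within the region.
#' @slot polarity Character, fixed \code{"negative"}.
#' @export
setClass("DepthProfileSpectrum",
  representation(mz = "numeric", intensity = "numeric",
                 patientId = "character", region = "character",
                 siteIndex = "integer", polarity = "character"),
  prototype(polarity = "negative", siteIndex = 1L,
            patientId = "unknown", region = "viable"))

setValidity("DepthProfileSpectrum", function(object) {
  msg <- character(0)
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity lengths differ")
  if (length(object@mz) && is.unsorted(object@mz, strictly = TRUE))
    msg <- c(msg, "m/z must be strictly increasing")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (any(!is.finite(object@mz)) || any(!is.finite(object@intensity)))
    msg <- c(msg, "m/z and intensities must be finite")
  if (!object@region %in% .REGIONS)
    msg <- c(msg, sprintf("region must be one of %s",
                          paste(.REGIONS, collapse = ", ")))
  if (!identical(object@polarity, "negative"))
    msg <- c(msg, "polarity is fixed to 'negative'")
  if (length(msg)) msg else TRUE
})

#' Construct a DepthProfileSpectrum
#'
#' Peaks are sorted ascending by m/z and duplicate m/z rows summed, so the
#' object always satisfies the class invariants regardless of input order.
#'
#' @param mz,intensity Numeric peak list.
#' @param patientId,region,siteIndex,polarity Sample metadata.
#' @return A \linkS4class{DepthProfileSpectrum}.
#' @examples
#' s <- DepthProfileSpectrum(c(200.1, 100.2, 100.2), c(1, 2, 3),
#'                           patientId = "P1", region = "viable")
#' peakMz(s)
#' @export
DepthProfileSpectrum <- function(mz, intensity, patientId = "unknown",
                                 region = "viable", siteIndex = 1L,
                                 polarity = "negative") {
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) {
    agg <- rowsum(as.numeric(intensity), group = as.numeric(mz))
    mz <- as.numeric(rownames(agg))
    intensity <- as.numeric(agg[, 1])
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  new("DepthProfileSpectrum", mz = as.numeric(mz),
      intensity = as.numeric(intensity),
      patientId = as.character(patientId), region = as.character(region),
      siteIndex = as.integer(siteIndex), polarity = polarity)
}

#' @rdname DepthProfileSpectrum
#' @param object,x A \code{DepthProfileSpectrum}.
#' @export
setGeneric("peakMz", function(x) standardGeneric("peakMz"))
#' @rdname DepthProfileSpectrum
#' @export
setGeneric("peakIntensity", function(x) standardGeneric("peakIntensity"))
#' @rdname DepthProfileSpectrum
#' @export
setGeneric("sampleRegion", function(x) standardGeneric("sampleRegion"))
#' @rdname DepthProfileSpectrum
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname DepthProfileSpectrum
#' @export
setMethod("peakMz", "DepthProfileSpectrum", function(x) x@mz)
#' @rdname DepthProfileSpectrum
#' @export
setMethod("peakIntensity", "DepthProfileSpectrum", function(x) x@intensity)
#' @rdname DepthProfileSpectrum
#' @export
setMethod("sampleRegion", "DepthProfileSpectrum", function(x) x@region)
#' @rdname DepthProfileSpectrum
#' @export
setMethod("sampleId", "DepthProfileSpectrum", function(x)
  sprintf("%s_%s_s%02d", x@patientId, x@region, x@siteIndex))

setMethod("show", "DepthProfileSpectrum", function(object) {
  cat("DepthProfileSpectrum:", sampleId(object), "\n",
      " ", length(object@mz), "peaks",
      if (length(object@mz))
        sprintf("(m/z %.4f-%.4f)", min(object@mz), max(object@mz)) else "",
      "\n  polarity:", object@polarity, "\n")
})

#' FeatureMatrix: aligned samples-by-features intensity matrix
#'
#' A \linkS4class{SummarizedExperiment} with features as rows (rowData
#' column \code{centroid_mz} holds the intensity-weighted cluster centroid
#' in Da) and samples as columns (colData: \code{patient_id}, \code{region},
#' \code{site_index}). The single assay \code{"intensity"} stores \code{NA}
#' for cells where a sample contributed no peak to a feature ("not
#' detected", distinct from a measured zero). \code{metadata(x)$transforms}
#' is the append-only log of applied processing steps.
#'
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  if (!"intensity" %in% names(assays(object)))
    return("assay 'intensity' is required")
  if (!"centroid_mz" %in% names(rowData(object)))
    return("rowData column 'centroid_mz' is required")
  ctr <- rowData(object)$centroid_mz
  if (length(ctr) > 1 && is.unsorted(ctr, strictly = TRUE))
    msg <- c(msg, "feature centroids must be strictly increasing")
  v <- assay(object, "intensity")
  if (any(!is.finite(v[!is.na(v)])))
    msg <- c(msg, "non-missing intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values Numeric matrix, features x samples; \code{NA} marks missing
#'   (not-detected) cells.
#' @param centroids Numeric vector of feature centroid m/z values (Da),
#'   strictly increasing; rows of \code{values} must follow this order.
#' @param sampleMeta data.frame with columns \code{patient_id},
#'   \code{region}, \code{site_index} (one row per sample/column).
#' @param transforms Character vector log of processing steps already applied.
#' @return A \linkS4class{FeatureMatrix}.
#' @examples
#' fm <- FeatureMatrix(matrix(1:6, nrow = 2), c(100.1, 200.2),
#'   data.frame(patient_id = "P1", region = c("necrotic", "viable", "viable"),
#'              site_index = c(1L, 1L, 2L)))
#' featureCentroids(fm)
#' @export
FeatureMatrix <- function(values, centroids, sampleMeta,
                          transforms = character(0)) {
  values <- as.matrix(values)
  stopifnot(nrow(values) == length(centroids),
            ncol(values) == nrow(sampleMeta))
  o <- order(centroids)
  values <- values[o, , drop = FALSE]
  centroids <- centroids[o]
  sampleMeta <- as.data.frame(sampleMeta)
  stopifnot(all(c("patient_id", "region", "site_index") %in% names(sampleMeta)))
  sid <- sprintf("%s_%s_s%02d", sampleMeta$patient_id, sampleMeta$region,
                 as.integer(sampleMeta$site_index))
  rownames(values) <- sprintf("F%04d", seq_along(centroids))
  colnames(values) <- make.unique(sid)
  se <- SummarizedExperiment(
    assays = list(intensity = values),
    rowData = DataFrame(centroid_mz = as.numeric(centroids)),
    colData = DataFrame(sampleMeta, row.names = colnames(values)))
  metadata(se)$transforms <- transforms
  new("FeatureMatrix", se)
}

#' @rdname FeatureMatrix
#' @param x A \code{FeatureMatrix}.
#' @export
setGeneric("featureCentroids", function(x) standardGeneric("featureCentroids"))
#' @rdname FeatureMatrix
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))
#' @rdname FeatureMatrix
#' @export
setGeneric("transformLog", function(x) standardGeneric("transformLog"))
#' @rdname FeatureMatrix
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname FeatureMatrix
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname FeatureMatrix
#' @export
setMethod("featureCentroids", "FeatureMatrix",
          function(x) rowData(x)$centroid_mz)
#' @rdname FeatureMatrix
#' @export
setMethod("missingMask", "FeatureMatrix",
          function(x) is.na(assay(x, "intensity")))
#' @rdname FeatureMatrix
#' @export
setMethod("transformLog", "FeatureMatrix",
          function(x) metadata(x)$transforms)
#' @rdname FeatureMatrix
#' @export
setMethod("intensityMatrix", "FeatureMatrix",
          function(x) assay(x, "intensity"))
#' @rdname FeatureMatrix
#' @export
setMethod("sampleInfo", "FeatureMatrix",
          function(x) as.data.frame(colData(x)))

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object), "features x", ncol(object), "samples\n")
  if (nrow(object))
    cat(sprintf("  centroid m/z: %.4f - %.4f\n",
                min(featureCentroids(object)), max(featureCentroids(object))))
  nm <- sum(missingMask(object))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", nm,
              100 * nm / max(1, length(missingMask(object)))))
  tl <- transformLog(object)
  cat("  transforms:", if (length(tl)) paste(tl, collapse = " -> ")
      else "(raw)", "\n")
})

# internal: append to the transform log
.logTransform <- function(x, step) {
  metadata(x)$transforms <- c(metadata(x)$transforms, step)
  x
}

#' PcaModel: principal component analysis fit
#'
#' @slot scores samples x components score matrix.
#' @slot loadings features x components orthonormal loading matrix.
#' @slot explainedR2X cumulative fraction of X variance explained.
#' @slot Q2 cross-validated R2X from venetian-blind row exclusion.
#' @slot centers feature means used for centring.
#' @export
setClass("PcaModel",
  representation(scores = "matrix", loadings = "matrix",
                 explainedR2X = "numeric", Q2 = "numeric",
                 centers = "numeric"))

setMethod("show", "PcaModel", function(object) {
  k <- ncol(object@scores)
  cat("PcaModel:", nrow(object@scores), "samples,", k, "components\n")
  cat(sprintf("  cumulative R2X: %s\n",
              paste(sprintf("%.3f", object@explainedR2X), collapse = " ")))
  cat(sprintf("  Q2 (7-fold venetian blinds): %.3f\n", object@Q2))
})

#' OplsdaModel: two-class OPLS-DA fit
#'
#' One predictive component plus \code{nOrthogonal} orthogonal (class-
#' uncorrelated) components, fitted by orthogonal-signal-corrected NIPALS.
#'
#' @slot t Predictive score per sample.
#' @slot w,p Predictive weight and loading per feature.
#' @slot c Regression of the class dummy on t.
#' @slot To,Wo,Po Orthogonal scores, weights, loadings (one column per
#'   orthogonal component).
#' @slot R2X,R2Y,Q2 Modelled X variance, modelled class variance, and
#'   leave-one-out cross-validated Q2.
#' @slot vip Per-feature variable importance in projection (mean square 1).
#' @slot splotCov,splotCorr S-plot coordinates: cov(t, x_j) and corr(t, x_j).
#' @slot xMeans,yMean Centring statistics.
#' @slot labels Factor of the two class labels in sample order.
#' @export
setClass("OplsdaModel",
  representation(t = "numeric", w = "numeric", p = "numeric", c = "numeric",
                 To = "matrix", Wo = "matrix", Po = "matrix",
                 R2X = "numeric", R2Y = "numeric", Q2 = "numeric",
                 vip = "numeric", splotCov = "numeric", splotCorr = "numeric",
                 xMeans = "numeric", yMean = "numeric", labels = "factor"))

setMethod("show", "OplsdaModel", function(object) {
  cat("OplsdaModel:", length(object@t), "samples,", length(object@w),
      "features, 1 predictive +", ncol(object@To), "orthogonal component(s)\n")
  cat(sprintf("  R2X = %.3f, R2Y = %.3f, Q2 (leave-one-out) = %.3f\n",
              object@R2X, object@R2Y, object@Q2))
  cat("  classes:", paste(levels(object@labels), collapse = " vs "), "\n")
})

#' @rdname OplsdaModel
#' @param object,x An \code{OplsdaModel} (or \code{PcaModel} where noted).
#' @export
setGeneric("predictiveScores", function(x) standardGeneric("predictiveScores"))
#' @rdname OplsdaModel
#' @export
setMethod("predictiveScores", "OplsdaModel", function(x) x@t)
#' @rdname OplsdaModel
#' @export
setGeneric("orthogonalScores", function(x) standardGeneric("orthogonalScores"))
#' @rdname OplsdaModel
#' @export
setMethod("orthogonalScores", "OplsdaModel", function(x) x@To)
#' @rdname OplsdaModel
#' @export
setGeneric("modelQ2", function(x) standardGeneric("modelQ2"))
#' @rdname OplsdaModel
#' @export
setMethod("modelQ2", "OplsdaModel", function(x) x@Q2)
#' @rdname OplsdaModel
#' @export
setMethod("modelQ2", "PcaModel", function(x) x@Q2)

#' IonImage: single-ion intensity image
#'
#' @slot intensities Numeric matrix (rows = y, cols = x; row-major,
#'   origin top-left, 0-based pixel coordinates in the accessors).
#' @slot pixelSize Pixel edge length in micrometres.
#' @slot centerMz,tolerancePpm The m/z window the image integrates.
#' @export
setClass("IonImage",
  representation(intensities = "matrix", pixelSize = "numeric",
                 centerMz = "numeric", tolerancePpm = "numeric"))

setValidity("IonImage", function(object) {
  if (!all(dim(object@intensities) > 0)) return("image dimensions must be positive")
  if (any(!is.finite(object@intensities))) return("intensities must be finite")
  if (any(object@intensities < 0)) return("intensities must be non-negative")
  TRUE
})

setMethod("show", "IonImage", function(object) {
  cat(sprintf("IonImage: %d x %d px (%.1f um/px), m/z %.4f +/- %.1f ppm\n",
              ncol(object@intensities), nrow(object@intensities),
              object@pixelSize, object@centerMz, object@tolerancePpm))
})

#' SyntheticTruth: ground truth for a generated cohort
#'
#' @slot assignments data.frame mapping each emitted feature (theoretical
#'   adduct m/z) to its compound and adduct.
#' @slot effects data.frame of true region effects: compound, region
#'   contrast (region vs rest), signed magnitude on the log-intensity scale
#'   in standardized (Cohen's d) units.
#' @slot missingMaskTruth Logical matrix (compounds x samples) of cells
#'   masked as missing by the generator.
#' @export
setClass("SyntheticTruth",
  representation(assignments = "data.frame", effects = "data.frame",
                 missingMaskTruth = "matrix"))

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", nrow(object@assignments), "features,",
      nrow(object@effects), "true region effects\n")
})

#' @rdname SyntheticTruth
#' @param x A \code{SyntheticTruth}.
#' @export
setGeneric("truthAssignments", function(x) standardGeneric("truthAssignments"))
#' @rdname SyntheticTruth
#' @export
setMethod("truthAssignments", "SyntheticTruth", function(x) x@assignments)
#' @rdname SyntheticTruth
#' @export
setGeneric("truthEffects", function(x) standardGeneric("truthEffects"))
#' @rdname SyntheticTruth
#' @export
setMethod("truthEffects", "SyntheticTruth", function(x) x@effects)
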