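#' Build a single-ion image from pixel-indexed peak lists
#'
#' Each pixel's value is the summed intensity of its peaks within the ppm
#' window around \code{centerMz}. Pixel coordinates are 0-based, row-major
#' with the origin at the top-left.
#'
#' @param pixelPeaks data.frame with columns \code{x}, \code{y} (0-based
#'   pixel coordinates), \code{mz}, \code{intensity}: the long-format
#'   concatenation of per-pixel peak lists. Pixels absent from the table
#'   get intensity 0.
#' @param width,height Image dimensions in pixels; inferred from the
#'   coordinates when omitted.
#' @param centerMz Window centre m/z.
#' @param tolerancePpm Window half-width in ppm.
#' @param pixelSize Pixel edge length in micrometres (default 3).
#' @return An \linkS4class{IonImage}.
#' @export
buildIonImage <- function(pixelPeaks, centerMz, tolerancePpm,
                          width = NULL, height = NULL, pixelSize = 3) {
  stopifnot(all(c("x", "y", "mz", "intensity") %in% names(pixelPeaks)))
  if (!nrow(pixelPeaks)) stop("empty pixel grid", call. = FALSE)
  if (tolerancePpm <= 0) stop("tolerancePpm must be > 0", call. = FALSE)
  if (is.null(width)) width <- max(pixelPeaks$x) + 1L
  if (is.null(height)) height <- max(pixelPeaks$y) + 1L
  if (any(pixelPeaks$x < 0 | pixelPeaks$x >= width |
            pixelPeaks$y < 0 | pixelPeaks$y >= height))
    stop("pixel coordinates outside the image bounds", call. = FALSE)
  img <- matrix(0, nrow = height, ncol = width)
  inWin <- abs(ppmError(pixelPeaks$mz, centerMz)) <= tolerancePpm
  if (any(inWin)) {
    sel <- pixelPeaks[inWin, , drop = FALSE]
    agg <- rowsum(sel$intensity, group = paste(sel$y, sel$x, sep = "_"))
    keys <- do.call(rbind, strsplit(rownames(agg), "_", fixed = TRUE))
    img[cbind(as.integer(keys[, 1]) + 1L, as.integer(keys[, 2]) + 1L)] <-
      agg[, 1]
  }
  new("IonImage", intensities = img, pixelSize = pixelSize,
      centerMz = centerMz, tolerancePpm = tolerancePpm)
}

#' Mean intensity within a rectangular region of interest
#'
#' @param image An \linkS4class{IonImage}.
#' @param originX,originY Top-left corner of the ROI, 0-based pixels.
#' @param width,height ROI size in pixels; must lie within the image.
#' @return Arithmetic mean over the ROI pixels.
#' @export
roiMean <- function(image, originX, originY, width, height) {
  stopifnot(is(image, "IonImage"))
  W <- ncol(image@intensities); H <- nrow(image@intensities)
  if (originX < 0 || originY < 0 || width < 1 || height < 1 ||
        originX + width > W || originY + height > H)
    stop("ROI extends outside the image bounds", call. = FALSE)
  mean(image@intensities[(originY + 1):(originY + height),
                         (originX + 1):(originX + width)])
}

#' Per-pixel ROI intensities
#'
#' The per-pixel values inside an ROI, for distribution-style comparison
#' between regions (the companion to \code{\link{roiMean}}).
#'
#' @inheritParams roiMean
#' @return Numeric vector of pixel intensities (row-major).
#' @export
roiPixels <- function(image, originX, originY, width, height) {
  stopifnot(is(image, "IonImage"))
  W <- ncol(image@intensities); H <- nrow(image@intensities)
  if (originX < 0 || originY < 0 || width < 1 || height < 1 ||
        originX + width > W || originY + height > H)
    stop("ROI extends outside the image bounds", call. = FALSE)
  as.numeric(t(image@intensities[(originY + 1):(originY + height),
                                 (originX + 1):(originX + width)]))
}
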