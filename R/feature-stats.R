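#' Per-feature two-sample Student's t-tests
#'
#' Two-sided pooled-variance Student's t per feature with n1 + n2 - 2
#' degrees of freedom (Welch's unequal-variance form available via
#' \code{welch = TRUE}). Features with zero pooled variance get t = 0 and
#' p = 1 with a warning.
#'
#' @param x A \linkS4class{FeatureMatrix} (no missing values) or
#'   samples x features matrix.
#' @param labels Two-group factor (default: region metadata of a
#'   \code{FeatureMatrix}).
#' @param welch Use Welch's t instead of the pooled-variance form.
#' @return data.frame with columns \code{t} and \code{p}, one row per
#'   feature.
#' @export
studentTTests <- function(x, labels = NULL, welch = FALSE) {
  X <- .asSamplesByFeatures(x)
  if (is.null(labels)) {
    if (!is(x, "FeatureMatrix"))
      stop("labels are required for a plain matrix", call. = FALSE)
    labels <- sampleInfo(x)$region
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("exactly two groups are required", call. = FALSE)
  g1 <- labels == levels(labels)[1]
  n1 <- sum(g1); n2 <- sum(!g1)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 samples",
                               call. = FALSE)
  m1 <- colMeans(X[g1, , drop = FALSE])
  m2 <- colMeans(X[!g1, , drop = FALSE])
  v1 <- apply(X[g1, , drop = FALSE], 2, stats::var)
  v2 <- apply(X[!g1, , drop = FALSE], 2, stats::var)
  if (welch) {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, ncol(X))
  }
  zero <- se == 0 | !is.finite(se)
  if (any(zero))
    warning(sum(zero), " feature(s) with zero pooled variance; p set to 1",
            call. = FALSE)
  t <- ifelse(zero, 0, (m1 - m2) / se)
  p <- ifelse(zero, 1, 2 * stats::pt(-abs(t), df))
  data.frame(t = t, p = p)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment:
#' \eqn{q_i = \min_{j \ge i} p_{(j)} m / j}, mapped back to input order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Vector of q-values, \code{q >= p}, in input order.
#' @export
benjaminiHochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Discriminative-feature predicate
#'
#' A feature is discriminative when its VIP score meets the threshold and
#' its FDR-adjusted q-value is below alpha.
#'
#' @param vip,q Aligned per-feature vectors.
#' @param vipThreshold VIP cut (default 1).
#' @param alpha Significance level on q (default 0.05).
#' @return Logical vector.
#' @export
selectDiscriminative <- function(vip, q, vipThreshold = 1, alpha = 0.05) {
  if (length(vip) != length(q))
    stop("vip and q must have equal length", call. = FALSE)
  vip >= vipThreshold & q < alpha
}

#' Ubiquitous-feature predicate
#'
#' A feature is ubiquitous (equal abundance across the two regions) when
#' its VIP score meets the threshold while its unadjusted p-value exceeds
#' alpha. \code{highVip = FALSE} selects the alternative reading in which a
#' ubiquitous feature must instead have a VIP below the threshold.
#'
#' @param vip,p Aligned per-feature vectors.
#' @param vipThreshold VIP cut (default 1).
#' @param alpha Significance level (default 0.05).
#' @param highVip Use the VIP >= threshold form (default) or VIP < threshold.
#' @return Logical vector.
#' @export
selectUbiquitous <- function(vip, p, vipThreshold = 1, alpha = 0.05,
                             highVip = TRUE) {
  if (length(vip) != length(p))
    stop("vip and p must have equal length", call. = FALSE)
  vipOk <- if (highVip) vip >= vipThreshold else vip < vipThreshold
  vipOk & p > alpha
}

#' Full univariate results table for a two-region comparison
#'
#' Runs Student's t-tests on TIC-normalized intensities, adds BH q-values,
#' VIP scores from the supplied OPLS-DA model, and both selection flags.
#'
#' @param ticMatrix \linkS4class{FeatureMatrix} after TIC normalization
#'   (not Pareto scaled), restricted to two regions.
#' @param model \linkS4class{OplsdaModel} fitted on the matching
#'   Pareto-scaled data.
#' @param labels Optional explicit group labels.
#' @param vipThreshold,alpha Selection thresholds.
#' @return data.frame with centroid m/z, group means, t, p, q, vip and the
#'   discriminative/ubiquitous flags.
#' @export
featureStatsTable <- function(ticMatrix, model, labels = NULL,
                              vipThreshold = 1, alpha = 0.05) {
  stopifnot(is(ticMatrix, "FeatureMatrix"), is(model, "OplsdaModel"))
  if (is.null(labels)) labels <- sampleInfo(ticMatrix)$region
  labels <- droplevels(as.factor(labels))
  tt <- studentTTests(ticMatrix, labels)
  q <- benjaminiHochberg(tt$p)
  vip <- vipScores(model)
  if (length(vip) != nrow(tt))
    stop("model feature count does not match the matrix", call. = FALSE)
  X <- t(intensityMatrix(ticMatrix))
  lv <- levels(labels)
  means <- vapply(lv, function(l)
    colMeans(X[labels == l, , drop = FALSE]), numeric(ncol(X)))
  out <- data.frame(centroid_mz = featureCentroids(ticMatrix),
                    means, t = tt$t, p = tt$p, q = q, vip = vip)
  names(out)[2:(1 + length(lv))] <- paste0("mean_", lv)
  out$discriminative <- selectDiscriminative(vip, q, vipThreshold, alpha)
  out$ubiquitous <- selectUbiquitous(vip, tt$p, vipThreshold, alpha)
  out
}
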