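# internal: coerce input to a samples x features numeric matrix
.asSamplesByFeatures <- function(x) {
  if (is(x, "FeatureMatrix")) {
    v <- t(intensityMatrix(x))
    if (anyNA(v)) stop("matrix contains missing values; impute first",
                       call. = FALSE)
    v
  } else {
    as.matrix(x)
  }
}

#' Principal component analysis with cross-validated Q2
#'
#' PCA by singular value decomposition of the column-centred matrix.
#' Q2 is computed by 7-fold venetian-blind row exclusion: each fold's rows
#' are held out, the loadings refitted on the remainder, held-out rows
#' projected and reconstructed, and Q2 = 1 - PRESS / SS.
#'
#' @param x A \linkS4class{FeatureMatrix} (no missing values) or a
#'   samples x features numeric matrix.
#' @param nComponents Number of components; reduced with a warning if it
#'   exceeds \code{min(samples - 1, features)}.
#' @param nFolds Cross-validation folds (default 7).
#' @return A \linkS4class{PcaModel}.
#' @export
fitPCA <- function(x, nComponents = 2L, nFolds = 7L) {
  X <- .asSamplesByFeatures(x)
  n <- nrow(X); p <- ncol(X)
  maxK <- min(n - 1L, p)
  if (nComponents > maxK) {
    warning("nComponents reduced from ", nComponents, " to ", maxK,
            call. = FALSE)
    nComponents <- maxK
  }
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = nComponents, nv = nComponents)
  scores <- sv$u %*% diag(sv$d[seq_len(nComponents)], nComponents)
  loadings <- sv$v
  ssx <- sum(Xc^2)
  r2 <- cumsum(sv$d[seq_len(nComponents)]^2) / ssx

  folds <- ((seq_len(n) - 1L) %% min(nFolds, n)) + 1L
  press <- 0; ss <- 0
  for (f in unique(folds)) {
    hold <- folds == f
    if (sum(!hold) <= nComponents) next
    ctrF <- colMeans(X[!hold, , drop = FALSE])
    XcF <- sweep(X[!hold, , drop = FALSE], 2, ctrF)
    V <- svd(XcF, nu = 0, nv = nComponents)$v
    H <- sweep(X[hold, , drop = FALSE], 2, ctrF)
    rec <- (H %*% V) %*% t(V)
    press <- press + sum((H - rec)^2)
    ss <- ss + sum(H^2)
  }
  q2 <- if (ss > 0) 1 - press / ss else NA_real_

  rownames(scores) <- rownames(X)
  new("PcaModel", scores = scores, loadings = loadings,
      explainedR2X = r2, Q2 = q2, centers = ctr)
}

# internal OPLS core on raw (uncentred) samples x features X and numeric y.
# Centring statistics are computed here so cross-validation folds refit them.
.oplsCore <- function(X, y, nOrtho = 1L) {
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm); yc <- y - ym
  p <- ncol(X)
  Wo <- matrix(0, p, 0); Po <- matrix(0, p, 0)
  To <- matrix(0, nrow(X), 0)
  Xf <- Xc
  for (a in seq_len(nOrtho)) {
    w <- drop(crossprod(Xf, yc))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps) break
    w <- w / nw
    t <- drop(Xf %*% w)
    pl <- drop(crossprod(Xf, t)) / sum(t^2)
    wo <- pl - sum(w * pl) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break               # no orthogonal variation left
    wo <- wo / nwo
    to <- drop(Xf %*% wo)
    po <- drop(crossprod(Xf, to)) / sum(to^2)
    Xf <- Xf - tcrossprod(to, po)
    Wo <- cbind(Wo, wo); Po <- cbind(Po, po); To <- cbind(To, to)
  }
  w <- drop(crossprod(Xf, yc))
  nw <- sqrt(sum(w^2))
  if (nw < .Machine$double.eps)
    stop("predictive weight vector is zero: no covariance between X and the class",
         call. = FALSE)
  w <- w / nw
  t <- drop(Xf %*% w)
  pl <- drop(crossprod(Xf, t)) / sum(t^2)
  cc <- sum(yc * t) / sum(t^2)
  list(w = w, p = pl, c = cc, t = t, Wo = Wo, Po = Po, To = To,
       xMeans = xm, yMean = ym, Xc = Xc, yc = yc)
}

# internal: predict class scores for new raw rows
.oplsPredict <- function(fit, Xnew) {
  Xc <- sweep(Xnew, 2, fit$xMeans)
  if (ncol(fit$Wo)) {
    for (a in seq_len(ncol(fit$Wo))) {
      to <- drop(Xc %*% fit$Wo[, a])
      Xc <- Xc - tcrossprod(to, fit$Po[, a])
    }
  }
  t <- drop(Xc %*% fit$w)
  fit$yMean + t * fit$c
}

# internal: leave-one-out cross-validated Q2
.oplsLooQ2 <- function(X, y, nOrtho) {
  n <- nrow(X)
  press <- 0
  for (i in seq_len(n)) {
    fit <- .oplsCore(X[-i, , drop = FALSE], y[-i], nOrtho)
    press <- press + (y[i] - .oplsPredict(fit, X[i, , drop = FALSE]))^2
  }
  as.numeric(1 - press / sum((y - mean(y))^2))
}

# internal: labels -> centred +/-1 dummy
.classDummy <- function(labels) {
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("exactly two classes are required (got ",
         nlevels(labels), ")", call. = FALSE)
  ifelse(labels == levels(labels)[1], -1, 1)
}

#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis in the
#' orthogonal-signal-corrected NIPALS formulation: class-orthogonal
#' components (weight \eqn{w_o \propto p - (w^\top p)w}) are extracted and
#' deflated from X, then a single predictive component is fitted on the
#' filtered matrix. With zero orthogonal components the fit coincides with
#' one-component NIPALS PLS1. The class is encoded as a centred +/-1 dummy.
#' Q2 is leave-one-out: each held-out sample is predicted by a model refit
#' (including centring statistics) without it.
#'
#' @param x A \linkS4class{FeatureMatrix} (preprocessed, no missing values)
#'   or samples x features matrix.
#' @param labels Two-class factor; defaults to the \code{region} column of
#'   a \code{FeatureMatrix}'s sample metadata.
#' @param nOrthogonal Number of orthogonal components (default 1).
#' @return An \linkS4class{OplsdaModel}.
#' @export
fitOPLSDA <- function(x, labels = NULL, nOrthogonal = 1L) {
  X <- .asSamplesByFeatures(x)
  if (is.null(labels)) {
    if (!is(x, "FeatureMatrix"))
      stop("labels are required for a plain matrix", call. = FALSE)
    labels <- sampleInfo(x)$region
  }
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) != 2L)
    stop("exactly two classes are required", call. = FALSE)
  if (any(table(labels) < 3L))
    stop("each class needs at least 3 samples", call. = FALSE)
  if (nOrthogonal < 0L) stop("nOrthogonal must be >= 0", call. = FALSE)
  y <- .classDummy(labels)

  fit <- .oplsCore(X, y, nOrthogonal)
  yhat <- fit$t * fit$c
  r2y <- 1 - sum((fit$yc - yhat)^2) / sum(fit$yc^2)
  ssx <- sum(fit$Xc^2)
  r2x <- (sum(fit$t^2) * sum(fit$p^2) +
            if (ncol(fit$To)) sum(colSums(fit$To^2) * colSums(fit$Po^2)) else 0) / ssx
  q2 <- .oplsLooQ2(X, y, nOrthogonal)

  # VIP over the single predictive component: sqrt(J) * |w_j| / ||w||
  J <- ncol(X)
  vip <- sqrt(J) * abs(fit$w) / sqrt(sum(fit$w^2))

  # S-plot against the original centred data
  n <- nrow(X)
  covj <- drop(crossprod(fit$Xc, fit$t)) / (n - 1)
  sdx <- apply(fit$Xc, 2, stats::sd)
  sdt <- stats::sd(fit$t)
  zerovar <- sdx == 0
  if (any(zerovar))
    warning("s-plot: ", sum(zerovar),
            " zero-variance feature(s); correlation set to 0", call. = FALSE)
  corrj <- ifelse(zerovar, 0, covj / (sdt * sdx))

  new("OplsdaModel", t = fit$t, w = fit$w, p = fit$p, c = fit$c,
      To = fit$To, Wo = fit$Wo, Po = fit$Po,
      R2X = r2x, R2Y = r2y, Q2 = q2, vip = vip,
      splotCov = covj, splotCorr = corrj,
      xMeans = fit$xMeans, yMean = fit$yMean, labels = labels)
}

#' Variable importance in projection
#'
#' VIP over the predictive component(s):
#' \deqn{VIP_j = \sqrt{J \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' which for the single predictive component reduces to
#' \eqn{\sqrt{J}\,|w_j|/\|w\|}. The mean of \eqn{VIP^2} is exactly 1.
#'
#' @param model A fitted \linkS4class{OplsdaModel}.
#' @return Numeric vector of per-feature VIP scores.
#' @export
vipScores <- function(model) {
  stopifnot(is(model, "OplsdaModel"))
  model@vip
}

#' S-plot coordinates
#'
#' Per-feature covariance and correlation between the predictive score
#' vector t and the (centred) feature values: high covariance flags
#' high-magnitude markers, high correlation flags reliable ones.
#'
#' @param model A fitted \linkS4class{OplsdaModel}.
#' @return data.frame with columns \code{covariance} and \code{correlation}.
#' @export
sPlot <- function(model) {
  stopifnot(is(model, "OplsdaModel"))
  data.frame(covariance = model@splotCov, correlation = model@splotCorr)
}

#' Permutation test of an OPLS-DA model
#'
#' Compares the observed leave-one-out Q2 with the distribution of Q2
#' values obtained when the class labels are randomly permuted, guarding
#' against overfitting. The empirical p-value is
#' \code{(1 + #[Q2_perm >= Q2_obs]) / (nPermutations + 1)}.
#'
#' @param x Preprocessed matrix or \linkS4class{FeatureMatrix}.
#' @param labels Two-class labels (default: region metadata).
#' @param nPermutations Number of label permutations (default 999).
#' @param nOrthogonal Orthogonal components, matching the observed fit.
#' @param seed Integer seed making the permutations reproducible.
#' @return List with \code{q2Observed}, \code{q2Permuted} (numeric vector)
#'   and \code{pValue}.
#' @export
permutationTest <- function(x, labels = NULL, nPermutations = 999L,
                            nOrthogonal = 1L, seed = 1L) {
  if (nPermutations < 1L) stop("nPermutations must be >= 1", call. = FALSE)
  X <- .asSamplesByFeatures(x)
  if (is.null(labels)) {
    if (!is(x, "FeatureMatrix"))
      stop("labels are required for a plain matrix", call. = FALSE)
    labels <- sampleInfo(x)$region
  }
  y <- .classDummy(labels)
  q2obs <- .oplsLooQ2(X, y, nOrthogonal)
  set.seed(seed, kind = "Mersenne-Twister")
  q2perm <- vapply(seq_len(nPermutations), function(i) {
    yp <- sample(y)
    tryCatch(.oplsLooQ2(X, yp, nOrthogonal), error = function(e) -Inf)
  }, numeric(1))
  p <- (1 + sum(q2perm >= q2obs)) / (nPermutations + 1)
  list(q2Observed = q2obs, q2Permuted = q2perm, pValue = p)
}
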