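#' Pipeline configuration
#'
#' All tunable parameters of the end-to-end analysis, with defaults equal
#' to the documented values: 0.1% base-peak selection threshold, 5 ppm
#' alignment window, 20% missing cutoff, k = 5 imputation, 1 orthogonal
#' component, VIP >= 1, alpha 0.05 on FDR-adjusted q, 5 ppm annotation and
#' 2 ppm pathway-mapping tolerance.
#'
#' @param thresholdFraction,windowPpm,maxMissingFraction,k,blacklist
#'   Preprocessing parameters.
#' @param nOrthogonal,nPermutations Modelling parameters.
#' @param vipThreshold,alpha Feature-selection thresholds.
#' @param annotationTolerancePpm,pathwayTolerancePpm Matching tolerances.
#' @param contrast Character pair of regions compared in the supervised
#'   analysis.
#' @param synthetic A \code{\link{syntheticConfig}} for the simulate stage
#'   (ignored when \code{spectra} are supplied to \code{\link{runPipeline}}).
#' @param seed Global seed; per-stage seeds are derived from it so stages
#'   are independently reproducible.
#' @return A validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(thresholdFraction = 0.001, windowPpm = 5,
                           maxMissingFraction = 0.20, k = 5L,
                           blacklist = numeric(0), nOrthogonal = 1L,
                           nPermutations = 99L, vipThreshold = 1,
                           alpha = 0.05, annotationTolerancePpm = 5,
                           pathwayTolerancePpm = 2,
                           contrast = c("necrotic", "viable"),
                           synthetic = syntheticConfig(), seed = 1L) {
  bad <- function(field, what) stop("invalid PipelineConfig field '", field,
                                    "': ", what, call. = FALSE)
  if (!(thresholdFraction > 0 && thresholdFraction < 1))
    bad("thresholdFraction", "must be in (0, 1)")
  if (windowPpm <= 0) bad("windowPpm", "must be > 0")
  if (maxMissingFraction < 0 || maxMissingFraction > 1)
    bad("maxMissingFraction", "must be in [0, 1]")
  if (k < 1) bad("k", "must be >= 1")
  if (nOrthogonal < 0) bad("nOrthogonal", "must be >= 0")
  if (nPermutations < 1) bad("nPermutations", "must be >= 1")
  if (vipThreshold < 0) bad("vipThreshold", "must be >= 0")
  if (alpha <= 0 || alpha >= 1) bad("alpha", "must be in (0, 1)")
  if (annotationTolerancePpm <= 0) bad("annotationTolerancePpm", "must be > 0")
  if (pathwayTolerancePpm <= 0) bad("pathwayTolerancePpm", "must be > 0")
  if (length(contrast) != 2L || anyDuplicated(contrast))
    bad("contrast", "must be two distinct region labels")
  cfg <- list(thresholdFraction = thresholdFraction, windowPpm = windowPpm,
              maxMissingFraction = maxMissingFraction, k = as.integer(k),
              blacklist = blacklist, nOrthogonal = as.integer(nOrthogonal),
              nPermutations = as.integer(nPermutations),
              vipThreshold = vipThreshold, alpha = alpha,
              annotationTolerancePpm = annotationTolerancePpm,
              pathwayTolerancePpm = pathwayTolerancePpm,
              contrast = as.character(contrast),
              synthetic = synthetic, seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

# derived per-stage seed: global seed folded with the stage name, kept
# inside the 32-bit integer range
.stageSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 10007 + sum(utf8ToInt(stage))) %%
               .Machine$integer.max)
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) a cohort, preprocess it, fit the multivariate
#' models, run univariate statistics, annotate and map pathways, writing
#' every checkpoint plus a machine-readable manifest (parameters, per-file
#' MD5 hashes) under \code{outdir}. Deterministic given the config seed.
#'
#' @param config A \code{\link{pipelineConfig}}.
#' @param outdir Output directory (created if needed).
#' @param spectra Optional list of \linkS4class{DepthProfileSpectrum}; when
#'   omitted the synthetic simulate stage runs first.
#' @return Invisibly, a list with the main in-memory results: the
#'   Pareto-scaled \code{matrix}, the TIC-normalized matrix, the
#'   \code{pca} and \code{oplsda} fits, the \code{permutation} result, the
#'   \code{stats} table, \code{annotations}, \code{pathwayReport}, and the
#'   manifest path.
#' @export
runPipeline <- function(config, outdir, spectra = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  compounds <- compoundLibrary()

  if (is.null(spectra)) {
    simCfg <- config$synthetic
    simCfg$seed <- .stageSeed(config$seed, "simulate")
    cohort <- generateCohort(simCfg)
    spectra <- cohort$spectra
    truth <- cohort$truth
    simDir <- file.path(outdir, "simulated")
    dir.create(simDir, showWarnings = FALSE)
    for (s in spectra)
      writePeakList(s, file.path(simDir, paste0(sampleId(s), ".tsv")))
    utils::write.table(truthAssignments(truth),
                       file.path(outdir, "truth_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truthEffects(truth),
                       file.path(outdir, "truth_effects.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # preprocessing (TIC matrix kept for univariate tests, Pareto for models)
  ticAll <- preprocessCohort(spectra,
                             thresholdFraction = config$thresholdFraction,
                             windowPpm = config$windowPpm,
                             maxMissingFraction = config$maxMissingFraction,
                             k = config$k, blacklist = config$blacklist,
                             pareto = FALSE)
  writeFeatureMatrix(ticAll, file.path(outdir, "feature_matrix_tic.csv"))

  regions <- sampleInfo(ticAll)$region
  inContrast <- regions %in% config$contrast
  if (sum(inContrast) < 6L)
    stop("stage 'model': fewer than 6 samples in contrast ",
         paste(config$contrast, collapse = " vs "), call. = FALSE)
  tic2 <- ticAll[, inContrast]
  pareto2 <- paretoScale(tic2)
  writeFeatureMatrix(pareto2, file.path(outdir, "feature_matrix_pareto.csv"))

  pca <- fitPCA(pareto2, nComponents = min(2L, ncol(pareto2) - 1L))
  opls <- fitOPLSDA(pareto2, nOrthogonal = config$nOrthogonal)
  perm <- permutationTest(pareto2, nPermutations = config$nPermutations,
                          nOrthogonal = config$nOrthogonal,
                          seed = .stageSeed(config$seed, "permute"))

  scoresDf <- data.frame(sample_id = colnames(pareto2),
                         region = sampleInfo(pareto2)$region,
                         t_predictive = predictiveScores(opls),
                         orthogonalScores(opls))
  utils::write.table(scoresDf, file.path(outdir, "oplsda_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  loadingsDf <- data.frame(centroid_mz = featureCentroids(pareto2),
                           w = opls@w, p = opls@p, vip = vipScores(opls),
                           sPlot(opls))
  utils::write.table(loadingsDf, file.path(outdir, "oplsda_loadings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summaryJson <- list(
    contrast = config$contrast,
    pca = list(R2X = pca@explainedR2X, Q2 = pca@Q2),
    oplsda = list(R2X = opls@R2X, R2Y = opls@R2Y, Q2 = opls@Q2,
                  nOrthogonal = config$nOrthogonal),
    permutation = list(n = config$nPermutations, p = perm$pValue))
  jsonlite::write_json(summaryJson, file.path(outdir, "model_summary.json"),
                       auto_unbox = TRUE, digits = NA)

  stats <- featureStatsTable(tic2, opls, vipThreshold = config$vipThreshold,
                             alpha = config$alpha)
  utils::write.table(stats, file.path(outdir, "feature_stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ann <- annotateFeatures(featureCentroids(tic2), compounds,
                          tolerancePpm = config$annotationTolerancePpm)
  utils::write.table(ann, file.path(outdir, "annotations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- ubiquitousPathwayReport(stats, ann,
                                    tolerancePpm = config$pathwayTolerancePpm)
  utils::write.table(report$coverage, file.path(outdir, "pathway_coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$members, file.path(outdir, "pathway_members.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  files <- setdiff(list.files(outdir, recursive = TRUE), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("simsMetab")),
    seed = config$seed,
    parameters = unclass(config)[setdiff(names(config), "synthetic")],
    synthetic = if (is.null(truth)) NULL else unclass(config$synthetic),
    files = as.list(tools::md5sum(file.path(outdir, files))))
  names(manifest$files) <- files
  manifestPath <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
                       null = "null")

  invisible(list(matrix = pareto2, ticMatrix = tic2, pca = pca,
                 oplsda = opls, permutation = perm, stats = stats,
                 annotations = ann, pathwayReport = report, truth = truth,
                 manifest = manifestPath))
}
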