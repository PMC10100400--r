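#' Configuration for the synthetic depth-profile cohort generator
#'
#' The defaults mirror the emulated study design: 4 patients, three
#' histological regions, 5 depth-profile sites per region, each profile a
#' sum of 80 scans over m/z 75-1125 in negative mode.
#'
#' @param nPatients Number of patients.
#' @param regions Region labels (subset of necrotic/viable/non_cancerous).
#' @param sitesPerRegion Depth-profile sites per patient x region (>= 2).
#' @param nScans Scans summed per profile.
#' @param mzRange Instrument m/z range in Da.
#' @param nBackgroundCompounds Compounds with no region effect.
#' @param nDiscriminativeCompounds Spiked compounds per region contrast
#'   (one-vs-rest; a two-region design has a single contrast).
#' @param effectSize True standardized mean shift (Cohen's d units) on the
#'   log-intensity scale for spiked compounds.
#' @param massJitterPpm SD of per-peak Gaussian m/z error, ppm.
#' @param missingRate Marginal fraction of masked cells, in [0, 0.5].
#' @param intensityCv Coefficient of variation of the log-normal
#'   site-to-site intensity noise.
#' @param patientSd SD of the per-patient random effect on log-intensity.
#' @param missingMechanism \code{"intensity"} (detection-limited: mask
#'   probability decreases with log-intensity via a logistic, calibrated so
#'   the marginal rate equals \code{missingRate}) or \code{"mcar"}.
#' @param seed Integer RNG seed; the cohort is fully reproducible from it.
#' @return A validated list of class \code{"SyntheticConfig"}.
#' @export
syntheticConfig <- function(nPatients = 4L,
                            regions = c("necrotic", "viable", "non_cancerous"),
                            sitesPerRegion = 5L, nScans = 80L,
                            mzRange = c(75, 1125),
                            nBackgroundCompounds = 150L,
                            nDiscriminativeCompounds = 10L,
                            effectSize = 2, massJitterPpm = 1,
                            missingRate = 0.1, intensityCv = 0.3,
                            patientSd = 0.2,
                            missingMechanism = c("intensity", "mcar"),
                            seed = 1L) {
  cfg <- list(nPatients = as.integer(nPatients), regions = as.character(regions),
              sitesPerRegion = as.integer(sitesPerRegion),
              nScans = as.integer(nScans), mzRange = as.numeric(mzRange),
              nBackgroundCompounds = as.integer(nBackgroundCompounds),
              nDiscriminativeCompounds = as.integer(nDiscriminativeCompounds),
              effectSize = as.numeric(effectSize),
              massJitterPpm = as.numeric(massJitterPpm),
              missingRate = as.numeric(missingRate),
              intensityCv = as.numeric(intensityCv),
              patientSd = as.numeric(patientSd),
              missingMechanism = match.arg(missingMechanism),
              seed = as.integer(seed))
  .checkConfig <- function(ok, field, what) {
    if (!ok) stop("invalid SyntheticConfig field '", field, "': ", what,
                  call. = FALSE)
  }
  .checkConfig(cfg$nPatients >= 1L, "nPatients", "must be >= 1")
  .checkConfig(length(cfg$regions) >= 1L &&
                 all(cfg$regions %in% .REGIONS) &&
                 !anyDuplicated(cfg$regions),
               "regions", "must be distinct labels from necrotic/viable/non_cancerous")
  .checkConfig(cfg$sitesPerRegion >= 2L, "sitesPerRegion", "must be >= 2")
  .checkConfig(cfg$nScans >= 1L, "nScans", "must be >= 1")
  .checkConfig(length(cfg$mzRange) == 2L && cfg$mzRange[1] < cfg$mzRange[2] &&
                 cfg$mzRange[1] >= 75 && cfg$mzRange[2] <= 1125,
               "mzRange", "must lie within the instrument range [75, 1125]")
  .checkConfig(cfg$nBackgroundCompounds >= 0L, "nBackgroundCompounds", ">= 0")
  .checkConfig(cfg$nDiscriminativeCompounds >= 0L,
               "nDiscriminativeCompounds", ">= 0")
  .checkConfig(cfg$massJitterPpm >= 0, "massJitterPpm", "must be >= 0")
  .checkConfig(cfg$missingRate >= 0 && cfg$missingRate <= 0.5,
               "missingRate", "must be in [0, 0.5]")
  .checkConfig(cfg$intensityCv > 0, "intensityCv", "must be > 0")
  .checkConfig(cfg$patientSd >= 0, "patientSd", "must be >= 0")
  class(cfg) <- "SyntheticConfig"
  cfg
}

# one-vs-rest region contrasts; a 2-region design collapses to one contrast
.regionContrasts <- function(regions) {
  if (length(regions) == 2L) regions[1] else regions
}

#' Generate a synthetic depth-profile cohort
#'
#' Emits one summed-scan spectrum per patient x region x site. Each
#' spectrum's peaks are the theoretical negative-mode adduct m/z values of
#' compounds drawn from the bundled library, perturbed by Gaussian ppm
#' jitter. Log-intensities are normal (so intensities log-normal) with
#' additive patient effects and, for spiked compounds, a region shift of
#' \code{effectSize} standardized units; cells are masked missing at the
#' configured marginal rate, preferentially at low intensity under the
#' detection-limited mechanism.
#'
#' @param config A \code{\link{syntheticConfig}}.
#' @param compounds Optional compound table (as from
#'   \code{\link{readCompoundTable}}); defaults to the bundled library.
#' @return List with elements \code{spectra} (list of
#'   \linkS4class{DepthProfileSpectrum}), \code{truth}
#'   (\linkS4class{SyntheticTruth}) and \code{compounds} (the compound table
#'   actually used, spiked compounds guaranteed present).
#' @examples
#' cohort <- generateCohort(syntheticConfig(nPatients = 2, sitesPerRegion = 2,
#'   nBackgroundCompounds = 30, nDiscriminativeCompounds = 3, seed = 7))
#' length(cohort$spectra)
#' @export
generateCohort <- function(config, compounds = compoundLibrary()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  contrasts <- .regionContrasts(config$regions)
  nSpiked <- config$nDiscriminativeCompounds * length(contrasts)
  nNeeded <- config$nBackgroundCompounds + nSpiked

  # restrict to compounds whose [M-H]- falls in range (water loss shifts
  # further down, also checked after adduct assignment)
  pool <- compounds[compounds$monoisotopic_mass - 1.008 > config$mzRange[1] &
                    compounds$monoisotopic_mass < config$mzRange[2] + 19, ,
                    drop = FALSE]
  pool <- pool[sample.int(nrow(pool)), , drop = FALSE]
  adducts <- defaultAdducts()$adduct

  # greedily select compounds whose assigned adduct m/z keeps >= 15 ppm
  # separation, so features stay resolvable at the 5 ppm alignment window
  selId <- character(0); selAdduct <- character(0); selMz <- numeric(0)
  for (i in seq_len(nrow(pool))) {
    if (length(selId) >= nNeeded) break
    add <- sample(adducts, 1L, prob = c(0.7, 0.3))
    mz <- tryCatch(adductMz(pool$monoisotopic_mass[i], add),
                   error = function(e) NA_real_)
    tryBoth <- c(add, setdiff(adducts, add))
    for (a in tryBoth) {
      mz <- tryCatch(adductMz(pool$monoisotopic_mass[i], a),
                     error = function(e) NA_real_)
      if (is.na(mz) || mz < config$mzRange[1] || mz > config$mzRange[2]) next
      if (!length(selMz) || min(abs(ppmError(mz, selMz))) > 15) {
        selId <- c(selId, pool$compound_id[i])
        selAdduct <- c(selAdduct, a)
        selMz <- c(selMz, mz)
        break
      }
    }
  }
  if (length(selId) < nNeeded)
    stop("compound library too small for ", nNeeded,
         " mass-resolved features (got ", length(selId), ")", call. = FALSE)

  o <- order(selMz)
  selId <- selId[o]; selAdduct <- selAdduct[o]; selMz <- selMz[o]
  nC <- length(selId)

  # spiked compounds and their contrasts
  spikedIdx <- sample.int(nC, nSpiked)
  effRegion <- rep(contrasts, each = config$nDiscriminativeCompounds)
  effSign <- sample(c(-1, 1), nSpiked, replace = TRUE)

  # sample grid
  grid <- expand.grid(site = seq_len(config$sitesPerRegion),
                      region = config$regions,
                      patient = sprintf("P%02d", seq_len(config$nPatients)),
                      stringsAsFactors = FALSE)
  nS <- nrow(grid)

  sdLog <- sqrt(log(1 + config$intensityCv^2))
  sdTotal <- sqrt(sdLog^2 + config$patientSd^2)  # spread d is standardized by

  # background abundances span three decades; spiked compounds sit in the
  # top decade so the recovery benchmark probes effect recovery rather
  # than detectability (mirrors the prominence of real discriminative ions)
  baseLog <- stats::runif(nC, log(1e3), log(1e6))
  baseLog[spikedIdx] <- stats::runif(nSpiked, log(1e5), log(1e6))
  patientEff <- matrix(stats::rnorm(nC * config$nPatients, 0, config$patientSd),
                       nrow = nC)
  colnames(patientEff) <- sprintf("P%02d", seq_len(config$nPatients))

  shift <- matrix(0, nrow = nC, ncol = nS)
  for (k in seq_len(nSpiked)) {
    inRegion <- grid$region == effRegion[k]
    shift[spikedIdx[k], inRegion] <-
      effSign[k] * config$effectSize * sdTotal
  }

  logI <- baseLog + patientEff[, grid$patient] + shift +
    matrix(stats::rnorm(nC * nS, 0, sdLog), nrow = nC)
  intensity <- exp(logI) * config$nScans

  # missingness
  if (config$missingRate > 0) {
    if (config$missingMechanism == "intensity") {
      z <- (logI - mean(logI)) / stats::sd(logI)
      slope <- 1.5
      f <- function(a) mean(stats::plogis(a - slope * z)) - config$missingRate
      a <- stats::uniroot(f, c(-50, 50))$root
      pMiss <- stats::plogis(a - slope * z)
    } else {
      pMiss <- matrix(config$missingRate, nrow = nC, ncol = nS)
    }
    mask <- matrix(stats::runif(nC * nS) < pMiss, nrow = nC)
  } else {
    mask <- matrix(FALSE, nrow = nC, ncol = nS)
  }

  # per-peak ppm jitter and spectrum assembly
  spectra <- vector("list", nS)
  for (j in seq_len(nS)) {
    keep <- which(!mask[, j])
    mzObs <- selMz[keep] *
      (1 + stats::rnorm(length(keep), 0, config$massJitterPpm) * 1e-6)
    spectra[[j]] <- DepthProfileSpectrum(
      mzObs, intensity[keep, j],
      patientId = grid$patient[j], region = grid$region[j],
      siteIndex = grid$site[j])
  }
  names(spectra) <- vapply(spectra, sampleId, "")
  dimnames(mask) <- list(selId, names(spectra))

  assignments <- data.frame(
    theoretical_mz = selMz, compound_id = selId, adduct = selAdduct,
    spiked = seq_len(nC) %in% spikedIdx, stringsAsFactors = FALSE)
  effects <- data.frame(
    compound_id = selId[spikedIdx], region = effRegion,
    direction = effSign,
    magnitude = rep(config$effectSize, nSpiked),
    stringsAsFactors = FALSE)

  truth <- new("SyntheticTruth", assignments = assignments, effects = effects,
               missingMaskTruth = mask)
  used <- compounds[compounds$compound_id %in% selId, , drop = FALSE]
  list(spectra = spectra, truth = truth, compounds = used)
}

#' Sum a stack of per-scan peak lists into one depth-profile spectrum
#'
#' Intensities are summed per identical m/z key across scans; the peak
#' count of the result equals the number of distinct m/z keys in the stack.
#'
#' @param scanStack Non-empty list of \linkS4class{DepthProfileSpectrum}
#'   (per-scan peak lists sharing an m/z axis convention). Metadata is taken
#'   from the first scan.
#' @return A \linkS4class{DepthProfileSpectrum}.
#' @export
sumScans <- function(scanStack) {
  if (!length(scanStack)) stop("empty scan stack", call. = FALSE)
  stopifnot(all(vapply(scanStack, is, TRUE, "DepthProfileSpectrum")))
  first <- scanStack[[1]]
  DepthProfileSpectrum(
    unlist(lapply(scanStack, peakMz)),
    unlist(lapply(scanStack, peakIntensity)),
    patientId = first@patientId, region = first@region,
    siteIndex = first@siteIndex)
}
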