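#' Read a two-column peak list
#'
#' Ingests the two-column (m/z, intensity) text export of a depth-profile
#' spectrum. Tab- or comma-delimited, optional header; rows are sorted
#' ascending by m/z and duplicate m/z rows summed.
#'
#' @param path Path to the peak-list file.
#' @param patientId,region,siteIndex Sample metadata attached to the
#'   returned spectrum.
#' @return A \linkS4class{DepthProfileSpectrum}.
#' @export
readPeakList <- function(path, patientId = "unknown", region = "viable",
                         siteIndex = 1L) {
  if (!file.exists(path)) stop("peak list not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty peak list: ", path, call. = FALSE)
  sep <- if (grepl("\t", lines[[1]])) "\t" else ","
  first <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  hasHeader <- suppressWarnings(anyNA(as.numeric(first[1:2])))
  start <- if (hasHeader) 2L else 1L
  if (start > length(lines)) stop("peak list has a header but no data rows: ",
                                  path, call. = FALSE)
  mz <- numeric(0); intensity <- numeric(0)
  for (i in seq(start, length(lines))) {
    fields <- trimws(strsplit(lines[[i]], sep, fixed = TRUE)[[1]])
    vals <- suppressWarnings(as.numeric(fields[1:2]))
    if (length(fields) < 2L || anyNA(vals))
      stop("non-numeric peak-list row at line ", i, " of ", path, call. = FALSE)
    if (vals[2] < 0)
      stop("negative intensity at line ", i, " of ", path, call. = FALSE)
    mz <- c(mz, vals[1]); intensity <- c(intensity, vals[2])
  }
  DepthProfileSpectrum(mz, intensity, patientId = patientId, region = region,
                       siteIndex = siteIndex)
}

#' Write a peak list as two-column TSV
#'
#' @param spectrum A \linkS4class{DepthProfileSpectrum}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writePeakList <- function(spectrum, path) {
  stopifnot(is(spectrum, "DepthProfileSpectrum"))
  df <- data.frame(mz = sprintf("%.17g", peakMz(spectrum)),
                   intensity = sprintf("%.17g", peakIntensity(spectrum)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a compound table
#'
#' TSV with columns \code{compound_id}, \code{name}, \code{formula} and an
#' optional \code{monoisotopic_mass}. A missing mass column is computed from
#' the formula; a supplied mass inconsistent with the formula by more than
#' 1e-3 Da is rejected.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns compound_id, name, formula,
#'   monoisotopic_mass.
#' @export
readCompoundTable <- function(path) {
  if (!file.exists(path)) stop("compound table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "name", "formula")
  if (!all(need %in% names(df)))
    stop("compound table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) {
    df$monoisotopic_mass <- numeric(0)
    return(df[c(need, "monoisotopic_mass")])
  }
  mass <- vapply(seq_len(nrow(df)), function(i) {
    tryCatch(monoisotopicMass(df$formula[i]),
             error = function(e) stop("compound '", df$compound_id[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  }, numeric(1))
  if ("monoisotopic_mass" %in% names(df)) {
    given <- as.numeric(df$monoisotopic_mass)
    bad <- which(!is.na(given) & abs(given - mass) > 1e-3)
    if (length(bad))
      stop("monoisotopic_mass inconsistent with formula for: ",
           paste(df$compound_id[bad], collapse = ", "), call. = FALSE)
    mass <- ifelse(is.na(given), mass, given)
  }
  df$monoisotopic_mass <- mass
  df[c(need, "monoisotopic_mass")]
}

#' Read a pathway membership table
#'
#' TSV with columns \code{pathway_id}, \code{pathway_name},
#' \code{compound_id}, \code{formula}.
#'
#' @param path Path to the TSV.
#' @return data.frame with one row per (pathway, member) pair and a
#'   \code{monoisotopic_mass} column computed from the formula.
#' @export
readPathwayTable <- function(path) {
  if (!file.exists(path)) stop("pathway table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pathway_id", "pathway_name", "compound_id", "formula")
  if (!all(need %in% names(df)))
    stop("pathway table must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$monoisotopic_mass <- monoisotopicMass(df$formula)
  df
}

#' Bundled compound library
#'
#' A table of ~230 common human metabolites (id, name, formula) used as the
#' local accurate-mass annotation reference and as the sampling pool for the
#' synthetic cohort generator.
#'
#' @return data.frame as from \code{\link{readCompoundTable}}.
#' @export
compoundLibrary <- function() {
  readCompoundTable(system.file("extdata", "compound_library.tsv",
                                package = "simsMetab", mustWork = TRUE))
}

#' Bundled miniature pathway tables
#'
#' Tryptophan, arginine/proline, tyrosine and histidine metabolism with
#' members drawn from the bundled compound library. A compact local stand-in
#' for a full pathway database, sufficient for coverage computation.
#'
#' @return data.frame as from \code{\link{readPathwayTable}}.
#' @export
pathwayLibrary <- function() {
  readPathwayTable(system.file("extdata", "pathways.tsv",
                               package = "simsMetab", mustWork = TRUE))
}

#' Write / read a feature matrix checkpoint
#'
#' CSV layout: one row per sample; the first three columns are
#' \code{patient_id}, \code{region}, \code{site_index}; remaining column
#' names are the feature centroid m/z at full double precision. Missing
#' (not-detected) cells are written as empty fields, never zeros. A trailing
#' comment line records the transform log. The round trip is lossless for
#' values, mask, centroids and metadata.
#'
#' @param matrix A \linkS4class{FeatureMatrix}.
#' @param path Output CSV path.
#' @return \code{path} invisibly (write); a \code{FeatureMatrix} (read).
#' @export
writeFeatureMatrix <- function(matrix, path) {
  stopifnot(is(matrix, "FeatureMatrix"))
  v <- intensityMatrix(matrix)
  allMissing <- apply(is.na(v), 1, all)
  if (any(allMissing))
    stop("refusing to write feature matrix with all-missing feature(s) at m/z ",
         paste(sprintf("%.4f", featureCentroids(matrix)[allMissing]),
               collapse = ", "), call. = FALSE)
  meta <- sampleInfo(matrix)
  header <- c("patient_id", "region", "site_index",
              sprintf("%.17g", featureCentroids(matrix)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#transforms=", paste(transformLog(matrix), collapse = ";")),
             con)
  writeLines(paste(header, collapse = ","), con)
  for (j in seq_len(ncol(v))) {
    vals <- ifelse(is.na(v[, j]), "", sprintf("%.17g", v[, j]))
    writeLines(paste(c(meta$patient_id[j], meta$region[j],
                       as.integer(meta$site_index[j]), vals), collapse = ","),
               con)
  }
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  if (!file.exists(path)) stop("feature matrix not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  transforms <- character(0)
  if (length(lines) && startsWith(lines[[1]], "#transforms=")) {
    tl <- sub("^#transforms=", "", lines[[1]])
    if (nzchar(tl)) transforms <- strsplit(tl, ";", fixed = TRUE)[[1]]
    lines <- lines[-1]
  }
  if (length(lines) < 2L) stop("feature matrix file has no data: ", path,
                               call. = FALSE)
  header <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  if (!identical(header[1:3], c("patient_id", "region", "site_index")))
    stop("unexpected feature-matrix header in ", path, call. = FALSE)
  centroids <- as.numeric(header[-(1:3)])
  if (anyNA(centroids)) stop("non-numeric centroid in header of ", path,
                             call. = FALSE)
  rows <- strsplit(lines[-1], ",", fixed = TRUE)
  nf <- length(centroids)
  bad <- which(lengths(rows) != nf + 3L)
  if (length(bad))
    stop("row/shape mismatch at data line ", bad[1], " of ", path, call. = FALSE)
  meta <- data.frame(
    patient_id = vapply(rows, `[[`, "", 1L),
    region = vapply(rows, `[[`, "", 2L),
    site_index = as.integer(vapply(rows, `[[`, "", 3L)),
    stringsAsFactors = FALSE)
  values <- t(vapply(rows, function(r) {
    v <- r[-(1:3)]
    out <- suppressWarnings(as.numeric(v))
    out[v == ""] <- NA_real_
    out
  }, numeric(nf)))
  if (nf == 1L) values <- matrix(as.numeric(values), ncol = 1L)
  FeatureMatrix(t(values), centroids, meta, transforms = transforms)
}
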