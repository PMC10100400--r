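#' Accurate-mass annotation of feature centroids
#'
#' Matches observed feature centroid m/z values against all (compound,
#' adduct) theoretical m/z values within a ppm tolerance. All
#' within-tolerance candidates are reported without arbitration (level-3
#' identification by accurate mass alone is inherently ambiguous), sorted
#' by absolute ppm error.
#'
#' @param featureMz Numeric vector of observed feature centroid m/z.
#' @param compounds Compound table (as from \code{\link{readCompoundTable}};
#'   defaults to the bundled library).
#' @param adducts Character vector of adduct names to consider.
#' @param tolerancePpm Matching tolerance in ppm (default 5).
#' @return data.frame with one row per hit: \code{feature_mz},
#'   \code{compound_id}, \code{name}, \code{formula}, \code{adduct},
#'   \code{theoretical_mz}, \code{neutral_mass}, signed \code{ppm_error}
#'   and \code{level} (\code{"level3"}).
#' @examples
#' annotateFeatures(116.0506)
#' @export
annotateFeatures <- function(featureMz, compounds = compoundLibrary(),
                             adducts = defaultAdducts()$adduct,
                             tolerancePpm = 5) {
  if (tolerancePpm <= 0) stop("tolerancePpm must be > 0", call. = FALSE)
  empty <- data.frame(feature_mz = numeric(0), compound_id = character(0),
                      name = character(0), formula = character(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      neutral_mass = numeric(0), ppm_error = numeric(0),
                      level = character(0), stringsAsFactors = FALSE)
  if (!nrow(compounds) || !length(featureMz)) return(empty)

  cand <- do.call(rbind, lapply(adducts, function(a) {
    ok <- compounds$monoisotopic_mass >
      -defaultAdducts()$mass_shift[match(a, defaultAdducts()$adduct)]
    cc <- compounds[ok, , drop = FALSE]
    if (!nrow(cc)) return(NULL)
    data.frame(compound_id = cc$compound_id, name = cc$name,
               formula = cc$formula, neutral_mass = cc$monoisotopic_mass,
               adduct = a,
               theoretical_mz = adductMz(cc$monoisotopic_mass, a),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cand)) return(empty)

  hits <- do.call(rbind, lapply(seq_along(featureMz), function(i) {
    err <- ppmError(featureMz[i], cand$theoretical_mz)
    sel <- which(abs(err) <= tolerancePpm)
    if (!length(sel)) return(NULL)
    data.frame(feature_mz = featureMz[i], cand[sel, , drop = FALSE],
               ppm_error = err[sel], level = "level3",
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) return(empty)
  hits <- hits[order(abs(hits$ppm_error)), ]
  rownames(hits) <- NULL
  hits[names(empty)]
}
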