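# Most-abundant-isotope atomic masses, Da (IUPAC/CIAAW 2021 isotopic masses,
# truncated to 7 decimals). 12C is exact by definition.
.ATOMIC_MASS <- c(
  C  = 12.0000000,
  H  = 1.0078250,
  N  = 14.0030740,
  O  = 15.9949146,
  P  = 30.9737615,
  S  = 31.9720707,
  Na = 22.9897693,
  K  = 38.9637065,
  Cl = 34.9688527,
  F  = 18.9984032,
  Se = 79.9165218,
  Fe = 55.9349363,
  Mg = 23.9850417,
  Ca = 39.9625909,
  I  = 126.9044730
)

# Proton mass, Da: deprotonation subtracts a proton (the anion keeps the
# electron), not a neutral hydrogen atom.
.PROTON_MASS <- 1.0072765
.H2O_MASS <- 2 * .ATOMIC_MASS[["H"]] + .ATOMIC_MASS[["O"]]

#' Parse a molecular formula
#'
#' Parses a Hill-style molecular formula (e.g. \code{"C8H7N"}) into a named
#' vector of element counts. Elements supported are the common biological
#' set C, H, N, O, P, S plus Na, K, Cl, F, Se, Fe, Mg, Ca, I.
#'
#' @param formula Character scalar, e.g. \code{"C10H12N2O"}. The empty string
#'   parses to an empty composition (mass 0).
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C8H7N")
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, !is.na(formula))
  formula <- trimws(formula)
  if (!nzchar(formula)) {
    return(structure(integer(0), names = character(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  tokens <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  if (sum(nchar(tokens)) != nchar(formula)) {
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  }
  elements <- sub("[0-9]*$", "", tokens)
  counts <- as.integer(ifelse(grepl("[0-9]+$", tokens),
                              sub("^[A-Za-z]+", "", tokens), "1"))
  unknown <- setdiff(elements, names(.ATOMIC_MASS))
  if (length(unknown)) {
    stop("unknown element symbol(s) in formula '", formula, "': ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  counts <- tapply(counts, factor(elements, levels = unique(elements)), sum)
  structure(as.integer(counts), names = names(counts))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums most-abundant-isotope atomic masses over the elemental composition.
#'
#' @param formula Character vector of molecular formulae.
#' @return Numeric vector of monoisotopic masses in Da.
#' @examples
#' monoisotopicMass("H2O")     # 18.010565
#' monoisotopicMass("C8H7N")   # indole, 117.057849
#' @export
monoisotopicMass <- function(formula) {
  vapply(formula, function(f) {
    comp <- parseFormula(f)
    if (!length(comp)) return(0)
    sum(.ATOMIC_MASS[names(comp)] * comp)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Negative-mode adduct definitions
#'
#' The two singly charged negative-mode ion types considered throughout:
#' the deprotonated molecule \eqn{[M-H]^-} and the deprotonated molecule
#' after water loss \eqn{[M-H_2O-H]^-}. Mass shifts are computed from the
#' proton (1.0072765 Da) and water (18.0105646 Da) masses.
#'
#' @return A data.frame with columns \code{adduct}, \code{mass_shift} (Da)
#'   and \code{charge}.
#' @examples
#' defaultAdducts()
#' @export
defaultAdducts <- function() {
  data.frame(
    adduct = c("[M-H]-", "[M-H2O-H]-"),
    mass_shift = c(-.PROTON_MASS, -(.H2O_MASS + .PROTON_MASS)),
    charge = c(-1L, -1L),
    stringsAsFactors = FALSE
  )
}

#' Theoretical m/z of a negative-mode adduct ion
#'
#' @param mass Numeric vector of neutral monoisotopic masses (Da).
#' @param adduct Adduct name, one of \code{"[M-H]-"}, \code{"[M-H2O-H]-"},
#'   recycled against \code{mass}.
#' @return Theoretical m/z (Da per unit charge).
#' @examples
#' adductMz(monoisotopicMass("C8H7N"), "[M-H]-")  # indole anion, 116.0506
#' @export
adductMz <- function(mass, adduct = "[M-H]-") {
  adducts <- defaultAdducts()
  idx <- match(adduct, adducts$adduct)
  if (anyNA(idx)) {
    stop("unknown adduct(s): ", paste(unique(adduct[is.na(idx)]), collapse = ", "),
         "; supported: ", paste(adducts$adduct, collapse = ", "), call. = FALSE)
  }
  shift <- adducts$mass_shift[idx]
  mz <- (mass + shift) / abs(adducts$charge[idx])
  if (any(mz <= 0)) {
    stop("adduct m/z is non-positive: neutral mass smaller than the adduct loss",
         call. = FALSE)
  }
  mz
}

#' Convert an observed adduct m/z back to a neutral monoisotopic mass
#'
#' @param mz Observed m/z.
#' @param adduct Adduct name (see \code{\link{defaultAdducts}}).
#' @return Neutral monoisotopic mass in Da.
#' @export
neutralMass <- function(mz, adduct = "[M-H]-") {
  adducts <- defaultAdducts()
  idx <- match(adduct, adducts$adduct)
  if (anyNA(idx)) {
    stop("unknown adduct(s): ", paste(unique(adduct[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  mz * abs(adducts$charge[idx]) - adducts$mass_shift[idx]
}

#' Signed parts-per-million mass error
#'
#' @param observed,theoretical m/z values.
#' @return \code{(observed - theoretical) / theoretical * 1e6}.
#' @export
ppmError <- function(observed, theoretical) {
  (observed - theoretical) / theoretical * 1e6
}
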