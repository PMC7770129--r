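# Element symbols, standard atomic weights, and common isotope masses.

# IUPAC standard atomic weights (abridged, conventional values where an
# interval is published). Covers the elements that occur in drug-like small
# molecules, common counterions, and noble gases.
.atomic_weights <- c(
  H = 1.008, He = 4.003, Li = 6.94, Be = 9.012, B = 10.81, C = 12.011,
  N = 14.007, O = 15.999, F = 18.998, Ne = 20.180, Na = 22.990, Mg = 24.305,
  Al = 26.982, Si = 28.085, P = 30.974, S = 32.06, Cl = 35.45, Ar = 39.948,
  K = 39.098, Ca = 40.078, Ti = 47.867, Cr = 51.996, Mn = 54.938,
  Fe = 55.845, Co = 58.933, Ni = 58.693, Cu = 63.546, Zn = 65.38,
  Ga = 69.723, Ge = 72.630, As = 74.922, Se = 78.971, Br = 79.904,
  Kr = 83.798, Rb = 85.468, Sr = 87.62, Mo = 95.95, Ru = 101.07,
  Pd = 106.42, Ag = 107.868, Cd = 112.414, Sn = 118.710, Sb = 121.760,
  Te = 127.60, I = 126.904, Xe = 131.293, Cs = 132.905, Ba = 137.327,
  W = 183.84, Pt = 195.084, Au = 196.967, Hg = 200.592, Tl = 204.38,
  Pb = 207.2, Bi = 208.980
)

# Exact masses of isotopes commonly used as labels; keyed "<symbol>:<A>".
# Other isotopes fall back to their mass number.
.isotope_masses <- c(
  "H:2" = 2.0141, "H:3" = 3.0160, "C:13" = 13.0034, "C:14" = 14.0032,
  "N:15" = 15.0001, "O:17" = 16.9991, "O:18" = 17.9992, "S:34" = 33.9679,
  "P:32" = 31.9739, "Cl:37" = 36.9659, "I:125" = 124.9046
)

#' Normalize a chemical element symbol
#'
#' Case-normalizes symbols (`"CL"` becomes `"Cl"`) and checks them against
#' the periodic-table symbols known to the package.
#'
#' @param symbol character vector of element symbols.
#' @return Character vector of normalized symbols.
#' @examples
#' normalize_element(c("c", "CL", "Br"))
#' @export
normalize_element <- function(symbol) {
  if (!is.character(symbol) || anyNA(symbol)) {
    stop("element symbols must be a character vector without NA", call. = FALSE)
  }
  s <- trimws(symbol)
  s <- paste0(toupper(substr(s, 1L, 1L)), tolower(substr(s, 2L, nchar(s))))
  bad <- !(s %in% names(.atomic_weights))
  if (any(bad)) {
    stop("unknown element symbol(s): ", paste(unique(symbol[bad]), collapse = ", "),
         call. = FALSE)
  }
  s
}

# Mass of one atom: standard atomic weight, or the isotope mass when a mass
# number is given (NA mass number = natural abundance).
.atom_mass <- function(element, mass_number = NA_integer_) {
  element <- normalize_element(element)
  m <- unname(.atomic_weights[element])
  iso <- !is.na(mass_number)
  if (any(iso)) {
    key <- paste0(element[iso], ":", mass_number[iso])
    exact <- .isotope_masses[key]
    m[iso] <- ifelse(is.na(exact), as.numeric(mass_number[iso]), unname(exact))
  }
  m
}
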