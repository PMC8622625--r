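# Elemental molecular formula (EMF) utilities: parsing, Hill notation,
# monoisotopic masses, and ion m/z for the positive-mode adducts used in
# direct-infusion FT-MS lipidomics (H, Na, K, NH4; singly charged).

# monoisotopic masses of the light isotopes (Da)
.ELEMENT_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.9949146196,
  P = 30.97376163
)

# mass gap of one 13C substitution (13C - 12C)
.C13_DELTA <- 1.0033548378

.ELECTRON_MASS <- 0.00054857990

# singly-charged positive adduct masses: M + adduct -> ion m/z
.ADDUCT_MASS <- c(
  H   = 1.00782503207 - 0.00054857990,
  Na  = 22.9897692809 - 0.00054857990,
  K   = 38.96370668 - 0.00054857990,
  NH4 = 14.0030740048 + 4 * 1.00782503207 - 0.00054857990
)

# element caps used when generating formulas (FT-MS assignment search limits)
.ELEMENT_CAPS <- c(C = 130, H = 230, N = 7, O = 28, P = 3)

#' Parse an elemental molecular formula string
#'
#' Parses a Hill-notation formula such as `"C42H82NO8P"` into a named
#' integer vector of element counts. Only C, H, N, O and P are allowed,
#' matching the element space of the lipid assignment search.
#'
#' @param emf Formula string in Hill notation.
#' @return Named integer vector with entries C, H, N, O, P.
#' @export
parse_emf <- function(emf) {
  stopifnot(is.character(emf), length(emf) == 1L, nzchar(emf))
  counts <- c(C = 0L, H = 0L, N = 0L, O = 0L, P = 0L)
  matches <- gregexpr("([A-Z][a-z]?)([0-9]*)", emf)[[1]]
  pieces <- regmatches(emf, list(matches))[[1]]
  pieces <- pieces[nzchar(pieces)]
  if (sum(nchar(pieces)) != nchar(emf)) {
    stop("malformed formula string: ", emf)
  }
  for (piece in pieces) {
    el <- gsub("[0-9]", "", piece)
    if (!el %in% names(counts)) stop("unsupported element '", el, "' in ", emf)
    num <- gsub("[A-Za-z]", "", piece)
    counts[el] <- counts[el] + if (nzchar(num)) as.integer(num) else 1L
  }
  counts
}

#' Format element counts as a Hill-notation formula
#'
#' @param counts Named numeric vector with (a subset of) C, H, N, O, P.
#' @return Formula string; carbon first, hydrogen second, rest alphabetical.
#' @export
format_emf <- function(counts) {
  counts <- counts[counts > 0]
  ord <- c("C", "H", "N", "O", "P")
  counts <- counts[intersect(ord, names(counts))]
  paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
}

#' Monoisotopic mass of a neutral formula
#'
#' @param emf Formula string or parsed count vector.
#' @return Neutral monoisotopic mass in Da.
#' @export
emf_mass <- function(emf) {
  counts <- if (is.character(emf)) parse_emf(emf) else emf
  sum(counts[names(.ELEMENT_MASS)] * .ELEMENT_MASS)
}

#' Theoretical ion m/z of an isotopologue
#'
#' m/z of the singly-charged `[M + adduct]+` ion of the isotopologue with
#' `isotopologue` heavy-carbon (13C) substitutions.
#'
#' @param emf Formula string or parsed count vector.
#' @param isotopologue Number of 13C substitutions (0 = monoisotopic peak).
#' @param adduct One of `"H"`, `"Na"`, `"K"`, `"NH4"`.
#' @return Ion m/z in Da (charge 1).
#' @export
ion_mz <- function(emf, isotopologue = 0L, adduct = "H") {
  if (!all(adduct %in% names(.ADDUCT_MASS))) {
    stop("unknown adduct: ", paste(setdiff(adduct, names(.ADDUCT_MASS)), collapse = ", "))
  }
  emf_mass(emf) + isotopologue * .C13_DELTA + unname(.ADDUCT_MASS[adduct])
}
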