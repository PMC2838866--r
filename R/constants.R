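# Monoisotopic element masses (Da) and isotope abundance vectors.
# Abundance vectors are indexed by neutron offset from the lightest isotope
# (offset 0 = monoisotopic); they are the inputs to envelope prediction.
.element_mass <- c(
  C = 12.0,
  H = 1.0078250319,
  N = 14.0030740052,
  O = 15.9949146221,
  S = 31.97207069
)

.element_abundance <- list(
  C = c(0.9893, 0.0107),
  H = c(0.999885, 0.000115),
  N = c(0.99636, 0.00364),
  O = c(0.99757, 0.00038, 0.00205),
  S = c(0.9499, 0.0075, 0.0425, 0, 0.0001)
)

#' Physical constants used throughout the package
#'
#' `proton_mass` is the mass of a proton in Da (charge carrier for
#' protonated peptide ions); `water_mass` the monoisotopic mass of H2O;
#' `iso_spacing` the C13-C12 mass difference, i.e. the spacing between
#' successive isotopic peaks of a singly charged ion.
#'
#' @name mass-constants
#' @export
proton_mass <- 1.00727646688

#' @rdname mass-constants
#' @export
water_mass <- 2 * 1.0078250319 + 15.9949146221

#' @rdname mass-constants
#' @export
iso_spacing <- 1.0033548378

# Elemental composition of amino acid residues (peptide-bond form, i.e. the
# free amino acid minus one water). J is the single-letter stand-in for the
# isobaric pair I/L.
.residue_formula <- matrix(
  c(
    # C   H  N  O  S
    3,  5, 1, 1, 0, # A
    6, 12, 4, 1, 0, # R
    4,  6, 2, 2, 0, # N
    4,  5, 1, 3, 0, # D
    3,  5, 1, 1, 1, # C
    5,  7, 1, 3, 0, # E
    5,  8, 2, 2, 0, # Q
    2,  3, 1, 1, 0, # G
    6,  7, 3, 1, 0, # H
    6, 11, 1, 1, 0, # I
    6, 11, 1, 1, 0, # L
    6, 12, 2, 1, 0, # K
    5,  9, 1, 1, 1, # M
    9,  9, 1, 1, 0, # F
    5,  7, 1, 1, 0, # P
    3,  5, 1, 2, 0, # S
    4,  7, 1, 2, 0, # T
    11, 10, 2, 1, 0, # W
    9,  9, 1, 2, 0, # Y
    5,  9, 1, 1, 0, # V
    6, 11, 1, 1, 0  # J (= I = L)
  ),
  ncol = 5, byrow = TRUE,
  dimnames = list(
    c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
      "K", "M", "F", "P", "S", "T", "W", "Y", "V", "J"),
    c("C", "H", "N", "O", "S")
  )
)

# The 19-letter alphabet used for sequence tags: I and L collapse to J so
# that every letter has a unique residue mass.
.tag_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "K", "M", "N",
                   "P", "Q", "R", "S", "T", "V", "W", "J", "Y")

#' Monoisotopic residue masses for the tag alphabet
#'
#' Returns the named vector of monoisotopic residue masses over the 19-letter
#' tag alphabet, in which the isobaric residues I and L are represented by the
#' single letter J so every letter has a unique mass. Masses are computed from
#' elemental compositions, so exact identities such as
#' `M(G) + M(A) == M(Q)` hold to machine precision.
#'
#' @param overrides optional named numeric vector of replacement masses, e.g.
#'   `c(C = 160.03065)` for carbamidomethylated cysteine.
#' @return named numeric vector of residue masses in Da.
#' @examples
#' m <- residue_masses()
#' m["K"] - m["Q"] # the 0.036 Da near-isobar
#' @export
residue_masses <- function(overrides = NULL) {
  m <- drop(.residue_formula %*% .element_mass)
  m <- m[.tag_alphabet]
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!names(overrides) %in% names(m))) {
      stop("overrides must be named with letters from the tag alphabet")
    }
    m[names(overrides)] <- overrides
  }
  if (anyDuplicated(m)) {
    stop("residue masses must be unique within the table")
  }
  m
}

#' Elemental composition of a peptide
#'
#' Sums residue formulas and adds one water for the intact peptide.
#' Accepts the 20 standard one-letter codes plus J.
#'
#' @param peptide character scalar, e.g. `"PEPTIDER"`.
#' @return named integer vector with counts for C, H, N, O, S.
#' @export
peptide_formula <- function(peptide) {
  aa <- strsplit(peptide, "")[[1]]
  bad <- setdiff(aa, rownames(.residue_formula))
  if (length(bad) > 0) {
    stop("unknown residue letter(s): ", paste(unique(bad), collapse = ", "))
  }
  counts <- colSums(.residue_formula[aa, , drop = FALSE])
  counts["H"] <- counts["H"] + 2
  counts["O"] <- counts["O"] + 1
  counts
}

#' Neutral monoisotopic mass of a peptide
#'
#' @inheritParams peptide_formula
#' @return neutral monoisotopic mass in Da.
#' @export
peptide_neutral_mass <- function(peptide) {
  f <- peptide_formula(peptide)
  unname(drop(f %*% .element_mass[names(f)]))
}

# string reversal helper used throughout tag handling
.rev_str <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
}

# map I/L to J so peptides are comparable with tags
.j_map <- function(x) chartr("IL", "JJ", x)
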