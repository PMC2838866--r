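# Isotopic envelope prediction by elemental convolution. Abundances are
# aggregated on the integer neutron-offset grid; peak masses are placed at
# mono + k * iso_spacing, which is accurate to well below 1 mDa for peptides.

.polymul <- function(a, b) {
  r <- numeric(length(a) + length(b) - 1L)
  for (k in seq_along(a)) {
    idx <- k:(k + length(b) - 1L)
    r[idx] <- r[idx] + a[k] * b
  }
  r
}

# n-fold self-convolution by binary exponentiation
.polypow <- function(p, n, trunc = 1e-12) {
  r <- 1
  while (n > 0) {
    if (n %% 2 == 1) {
      r <- .polymul(r, p)
      r <- r[cumsum(rev(r)) |> rev() > trunc]
    }
    n <- n %/% 2
    if (n > 0) {
      p <- .polymul(p, p)
      p <- p[cumsum(rev(p)) |> rev() > trunc]
    }
  }
  r
}

# Relative isotope abundances (offset 0, 1, 2, ...) for an elemental formula
.isotope_pattern <- function(formula) {
  dist <- 1
  for (el in names(formula)) {
    n <- formula[[el]]
    if (n <= 0) next
    dist <- .polymul(dist, .polypow(.element_abundance[[el]], n))
    dist <- dist[cumsum(rev(dist)) |> rev() > 1e-12]
  }
  dist / sum(dist)
}

# Averagine model: average elemental composition per 111.1254 Da of peptide
# mass, used to predict envelope shapes for ions of unknown sequence.
.averagine_pattern <- function(neutral_mass) {
  scale <- max(neutral_mass, 57) / 111.1254
  formula <- c(C = round(4.9384 * scale), H = round(7.7583 * scale),
               N = round(1.3577 * scale), O = round(1.4773 * scale),
               S = round(0.0417 * scale))
  .isotope_pattern(formula)
}

#' Theoretical isotopic distribution of a peptide ion
#'
#' Sums the elemental composition from residue formulas plus water, convolves
#' elemental isotope abundances on the neutron-offset grid, truncates the
#' envelope to peaks of at least 1% relative intensity and renormalizes the
#' intensities to sum to one.
#'
#' @param peptide peptide sequence (standard one-letter codes; J allowed).
#' @param charge charge state (>= 1).
#' @return object of class `isotope_distribution`: list with `mz` and
#'   `intensity` vectors, `charge` and the neutral `mono_mass`.
#' @examples
#' d <- theoretical_isotope_distribution("G", 1)
#' d$mz[1] # ~76.0393
#' @export
theoretical_isotope_distribution <- function(peptide, charge) {
  stopifnot(charge >= 1)
  formula <- peptide_formula(peptide)
  mono <- peptide_neutral_mass(peptide)
  p <- .isotope_pattern(formula)
  # drop the sub-1% tail; the leading (monoisotopic) peak is always kept so
  # the grid stays anchored at the mono mass
  p <- p[seq_len(max(which(p >= 0.01 * max(p))))]
  p <- p / sum(p)
  k <- seq_along(p) - 1L
  structure(
    list(mz = (mono + k * iso_spacing) / charge + proton_mass,
         intensity = p, charge = as.integer(charge), mono_mass = mono),
    class = "isotope_distribution"
  )
}
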