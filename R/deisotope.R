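#' Deisotope a raw peak list into neutral monoisotopic fragment ions
#'
#' Greedy highest-intensity-first envelope search. Each unassigned peak is
#' tried as the monoisotopic peak of an envelope at candidate charges (the
#' peak's own charge annotation when present, otherwise 1..`parent_charge`).
#' Successive isotopic peaks are looked up at spacings of `iso_spacing / z`
#' within `config$iso_mz_tol` Th, and their intensity ratios must agree with
#' an averagine-predicted envelope within a factor of
#' `config$ratio_tolerance`. An envelope is accepted when it contains at
#' least the configured minimum number of peaks (default: 1 for charge 1,
#' 2 for charge >= 2). Peaks not assignable to any envelope are removed.
#'
#' Accepted envelopes are reduced to neutral monoisotopic masses
#' `(mono m/z - proton) * z` with the summed envelope intensity as abundance;
#' near-duplicate neutral masses (within `config$merge_tol` Da) are merged
#' keeping the more abundant ion, and abundances are rescaled so the base
#' peak is 100.
#'
#' @param raw_peaks data frame of peaks ascending in m/z, with at least `mz`
#'   and `intensity` columns (a `charge` column, if present, constrains the
#'   candidate charge when positive).
#' @param parent_charge parent charge state (>= 1); bounds candidate fragment
#'   charges.
#' @param config a [denovo_config()].
#' @return data frame of fragment ions with columns `mass` (neutral Da),
#'   `abundance` (percent of base peak) and `charge`, ascending in mass.
#' @export
deisotope <- function(raw_peaks, parent_charge, config = denovo_config()) {
  stopifnot(parent_charge >= 1)
  n <- nrow(raw_peaks)
  if (n == 0) {
    return(data.frame(mass = numeric(0), abundance = numeric(0),
                      charge = integer(0)))
  }
  mz <- raw_peaks$mz
  inten <- raw_peaks$intensity
  pk_charge <- if ("charge" %in% names(raw_peaks)) raw_peaks$charge else rep(0L, n)

  min_peaks <- function(z) {
    if (!is.null(config$min_isotope_peaks)) return(config$min_isotope_peaks)
    if (config$require_partner) return(2L)
    if (z == 1) 1L else 2L
  }

  assigned <- logical(n)
  ord <- order(inten, decreasing = TRUE)
  out_mass <- numeric(0)
  out_ab <- numeric(0)
  out_z <- integer(0)

  for (p in ord) {
    if (assigned[p]) next
    zs <- if (!is.na(pk_charge[p]) && pk_charge[p] > 0) pk_charge[p] else seq_len(parent_charge)
    best <- NULL
    for (z in zs) {
      neutral <- (mz[p] - proton_mass) * z
      if (neutral <= 0) next
      pred <- .averagine_pattern(neutral)
      members <- p
      k <- 1L
      repeat {
        if (k + 1L > length(pred)) break
        expect <- mz[p] + k * iso_spacing / z
        cand <- which(!assigned & abs(mz - expect) < config$iso_mz_tol)
        cand <- setdiff(cand, members)
        if (length(cand) == 0) break
        cand <- cand[which.min(abs(mz[cand] - expect))]
        ratio_obs <- inten[cand] / inten[p]
        ratio_pred <- pred[k + 1L] / pred[1L]
        if (ratio_pred <= 0) break
        fold <- ratio_obs / ratio_pred
        if (fold > config$ratio_tolerance || fold < 1 / config$ratio_tolerance) break
        members <- c(members, cand)
        k <- k + 1L
      }
      if (length(members) >= min_peaks(z)) {
        if (is.null(best) || length(members) > length(best$members) ||
            (length(members) == length(best$members) && z < best$z)) {
          best <- list(z = z, members = members, neutral = neutral)
        }
      }
    }
    if (!is.null(best)) {
      assigned[best$members] <- TRUE
      out_mass <- c(out_mass, best$neutral)
      out_ab <- c(out_ab, sum(inten[best$members]))
      out_z <- c(out_z, best$z)
    }
  }

  if (length(out_mass) == 0) {
    return(data.frame(mass = numeric(0), abundance = numeric(0),
                      charge = integer(0)))
  }
  ord2 <- order(out_mass)
  ions <- data.frame(mass = out_mass[ord2], abundance = out_ab[ord2],
                     charge = out_z[ord2])
  # merge near-duplicate neutral masses, keeping the more abundant ion
  keep <- rep(TRUE, nrow(ions))
  i <- 1L
  while (i < nrow(ions)) {
    j <- i + 1L
    if (keep[i] && ions$mass[j] - ions$mass[i] < config$merge_tol) {
      if (ions$abundance[j] >= ions$abundance[i]) keep[i] <- FALSE else keep[j] <- FALSE
    }
    i <- j
  }
  ions <- ions[keep, , drop = FALSE]
  ions$abundance <- 100 * ions$abundance / max(ions$abundance)
  rownames(ions) <- NULL
  ions
}
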