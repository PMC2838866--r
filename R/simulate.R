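# Ground-truthed synthetic data: tryptic-like peptides, tandem spectra with
# partial y/b ladders, Gaussian fragment mass error and noise peaks, and
# full scans carrying isotopic envelopes with a controllable calibration
# offset, paired with an identification table. All randomness derives from
# the configured seed; per-spectrum seeds are offset by scan number so
# spectra are individually reproducible.

#' Simulation configuration
#'
#' @param n_peptides number of peptides to generate.
#' @param length_range inclusive peptide length range.
#' @param charges possible parent charge states with `charge_probs`
#'   probabilities.
#' @param charge_probs sampling probabilities for `charges`.
#' @param fragment_sd Gaussian fragment mass error sd in Da; the default,
#'   0.0025 Da (a quarter of the 0.01 Da edge tolerance), keeps most
#'   relative errors between adjacent fragments inside [-0.01, 0.01] Da.
#' @param coverage per-ion inclusion probability for each theoretical y and
#'   b ion.
#' @param noise_peaks number of uniform-m/z noise peaks per spectrum, with
#'   intensities drawn from the lower quartile of the signal intensities.
#' @param calibration_offset systematic parent-mass offset in Da applied to
#'   full-scan envelopes on the neutral-mass scale (envelope m/z shifts by
#'   offset / charge).
#' @param ms1_sd per-peak full-scan mass jitter sd in Da (neutral scale).
#' @param decoy_rate fraction of identification rows flagged as decoys.
#' @param bad_rate fraction of identifications rendered with an extra
#'   +0.05 Da mass error (wrong-mass identifications that the parent-mass
#'   filter should remove).
#' @param seed integer seed fixing all downstream randomness.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_peptides = 100L,
                       length_range = c(7L, 20L),
                       charges = c(2L, 3L),
                       charge_probs = c(0.6, 0.4),
                       fragment_sd = 0.0025,
                       coverage = 0.8,
                       noise_peaks = 10L,
                       calibration_offset = 0,
                       ms1_sd = 0.001,
                       decoy_rate = 0,
                       bad_rate = 0,
                       seed = 1L) {
  stopifnot(coverage >= 0, coverage <= 1, fragment_sd >= 0,
            length_range[1] >= 2, length_range[2] >= length_range[1],
            decoy_rate >= 0, decoy_rate <= 1, bad_rate >= 0, bad_rate <= 1)
  structure(as.list(environment()), class = "sim_config")
}

# residues a tryptic digest can end in
.tryptic_ends <- c("K", "R")
.standard_aa <- setdiff(rownames(.residue_formula), "J")

#' Generate random tryptic-like peptides
#'
#' Peptides over the 20 standard residues, ending in K or R, with lengths
#' uniform in the configured range. Fully reproducible under the
#' configuration seed.
#'
#' @param config a [sim_config()].
#' @return character vector of peptide sequences.
#' @export
generate_peptides <- function(config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  lens <- sample(seq(config$length_range[1], config$length_range[2]),
                 config$n_peptides, replace = TRUE)
  vapply(lens, function(L) {
    body <- sample(.standard_aa, L - 1L, replace = TRUE)
    paste(c(body, sample(.tryptic_ends, 1L)), collapse = "")
  }, character(1))
}

#' Theoretical y/b fragment ladders of a peptide
#'
#' Neutral monoisotopic masses: `b_k` is the sum of the first k residue
#' masses, `y_h` the sum of the last h residue masses plus one water, so
#' complementary pairs satisfy `y_h + b_(n-h) = P`.
#'
#' @param peptide peptide sequence (standard letters; J allowed).
#' @return list with numeric vectors `b` (b1..b(n-1)) and `y` (y1..y(n-1)).
#' @export
theoretical_fragments <- function(peptide) {
  aa <- strsplit(peptide, "")[[1]]
  m <- drop(.residue_formula[aa, , drop = FALSE] %*% .element_mass)
  n <- length(aa)
  list(b = unname(cumsum(m)[-n]),
       y = unname(cumsum(rev(m))[-n]) + water_mass)
}

#' Simulate one tandem spectrum with ground truth
#'
#' Each theoretical y/b ion is included with probability
#' `config$coverage`, perturbed with Gaussian mass error
#' (`config$fragment_sd`), and `config$noise_peaks` uniform-mass noise
#' peaks are added below the parent mass. Near-coincident masses are merged
#' so spectrum-graph vertices stay distinct. The ground-truth record maps
#' every retained signal ion to its (type, index) identity.
#'
#' @param peptide peptide sequence.
#' @param config a [sim_config()].
#' @param scan scan number; also offsets the seed so each spectrum draws
#'   its own reproducible randomness.
#' @return list with `spectrum` (a [tandem_spectrum()]), `truth` (data
#'   frame: mass, type, index, is_noise) and `peptide`.
#' @export
simulate_spectrum <- function(peptide, config = sim_config(), scan = 1L) {
  if (!is.null(config$seed)) {
    set.seed((config$seed * 10007L + as.integer(scan)) %% .Machine$integer.max)
  }
  p <- peptide_neutral_mass(peptide)
  frag <- theoretical_fragments(peptide)
  true_mass <- c(frag$b, frag$y)
  type <- c(rep("b", length(frag$b)), rep("y", length(frag$y)))
  index <- c(seq_along(frag$b), seq_along(frag$y))
  keep <- stats::runif(length(true_mass)) < config$coverage
  mass <- true_mass[keep] +
    if (config$fragment_sd > 0) stats::rnorm(sum(keep), 0, config$fragment_sd) else 0
  ab <- stats::runif(sum(keep), 20, 100)
  truth <- data.frame(mass = mass, type = type[keep], index = index[keep],
                      is_noise = rep(FALSE, sum(keep)))
  if (config$noise_peaks > 0 && sum(keep) > 0) {
    lo <- min(residue_masses())
    nmass <- stats::runif(config$noise_peaks, lo, max(p - lo, lo + 1))
    q25 <- stats::quantile(ab, 0.25)
    nab <- stats::runif(config$noise_peaks, 1, q25)
    truth <- rbind(truth, data.frame(mass = nmass, type = "noise",
                                     index = NA_integer_, is_noise = TRUE))
    mass <- c(mass, nmass)
    ab <- c(ab, nab)
  }
  ord <- order(mass)
  mass <- mass[ord]; ab <- ab[ord]
  truth <- truth[order(truth$mass), , drop = FALSE]
  # merge coincident masses (keep the first, i.e. lighter, of a close pair)
  if (length(mass) > 1) {
    keep2 <- c(TRUE, diff(mass) > 0.005)
    mass <- mass[keep2]; ab <- ab[keep2]
    truth <- truth[keep2, , drop = FALSE]
  }
  ions <- data.frame(mass = mass, abundance = if (length(ab) && max(ab) > 0)
    100 * ab / max(ab) else ab)
  spectrum <- prepare_spectrum(list(scan = scan, charge = sample(
    config$charges, 1L, prob = config$charge_probs),
    mhplus = p + proton_mass), ions)
  rownames(truth) <- NULL
  list(spectrum = spectrum, truth = truth, peptide = peptide)
}

#' Simulate full scans and an identification table
#'
#' Each peptide gets its own scan block: six full scans (three below, three
#' above) surrounding one MS/MS scan number. Full scans carry the peptide's
#' isotopic envelope with the configured calibration offset (neutral
#' scale), per-peak jitter and random intensity scaling. The paired
#' identification table contains one row per peptide with flanking
#' residues, plausible search scores, proteins grouped two peptides each,
#' decoy rows at `config$decoy_rate` and corrupted-mass rows at
#' `config$bad_rate` (flagged in the truth table).
#'
#' @param peptides character vector of peptide sequences.
#' @param config a [sim_config()].
#' @return list with `full_scans`, `ids` (identification table) and
#'   `truth` (data frame: scan, true_offset, bad).
#' @export
simulate_full_scans <- function(peptides, config = sim_config()) {
  if (!is.null(config$seed)) set.seed(config$seed + 777L)
  n <- length(peptides)
  charges <- sample(config$charges, n, replace = TRUE, prob = config$charge_probs)
  bad <- stats::runif(n) < config$bad_rate
  decoy <- stats::runif(n) < config$decoy_rate
  full_scans <- list()
  ms2_scan <- integer(n)
  for (i in seq_len(n)) {
    base <- 100L * i
    ms2_scan[i] <- base + 6L
    dist <- theoretical_isotope_distribution(peptides[i], charges[i])
    offset <- config$calibration_offset + if (bad[i]) 0.05 else 0
    for (s in base + c(0L, 2L, 4L, 8L, 10L, 12L)) {
      scale <- stats::runif(1, 0.5, 2) * 1e5
      mz <- dist$mz + offset / charges[i] +
        stats::rnorm(length(dist$mz), 0, config$ms1_sd / charges[i])
      full_scans[[length(full_scans) + 1L]] <- structure(
        list(scan = s,
             peaks = data.frame(mz = mz,
                                intensity = scale * dist$intensity,
                                resolution = 30000,
                                baseline = 0, noise = 1,
                                charge = charges[i])),
        class = "full_scan")
    }
  }
  ids <- data.frame(
    scan = ms2_scan,
    charge = charges,
    peptide = paste0("K.", peptides, ".", sample(.standard_aa, n, replace = TRUE)),
    xcorr = round(stats::runif(n, 2.6, 5.5), 4),
    delcn = round(stats::runif(n, 0.1, 0.4), 4),
    protein = paste0(ifelse(decoy, "Reverse_", ""), "prot_",
                     (seq_len(n) + 1L) %/% 2L),
    decoy = decoy
  )
  truth <- data.frame(scan = ms2_scan,
                      true_offset = config$calibration_offset + ifelse(bad, 0.05, 0),
                      bad = bad)
  list(full_scans = full_scans, ids = ids, truth = truth)
}

#' Simulate a full dataset, optionally writing it to disk
#'
#' Generates peptides, tandem spectra and full scans with one consistent
#' configuration. When `dir` is given, writes `spectra.ft2`,
#' `fullscans.ft1`, `ids.tsv` and a `manifest.txt` recording the
#' configuration.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory.
#' @return list with `peptides`, `spectra` (list of [simulate_spectrum()]
#'   results), `full_scans`, `ids`, `truth`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  peptides <- generate_peptides(config)
  spectra <- lapply(seq_along(peptides), function(i) {
    simulate_spectrum(peptides[i], config, scan = 100L * i + 6L)
  })
  fs <- simulate_full_scans(peptides, config)
  out <- list(peptides = peptides, spectra = spectra,
              full_scans = fs$full_scans, ids = fs$ids, truth = fs$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    recs <- lapply(spectra, function(s) {
      sp <- s$spectrum
      ions <- sp$ions[sp$ions$mass > 0, , drop = FALSE]
      list(scan = sp$scan,
           premz = (sp$parent_mass + sp$charge * proton_mass) / sp$charge,
           charge = sp$charge,
           mhplus = sp$parent_mass + proton_mass,
           peaks = data.frame(mz = ions$mass + proton_mass,
                              intensity = ions$abundance,
                              resolution = 7500, baseline = 0, noise = 1,
                              charge = 1L))
    })
    write_ft2(recs, file.path(dir, "spectra.ft2"))
    write_ft1(fs$full_scans, file.path(dir, "fullscans.ft1"))
    write_id_table(fs$ids, file.path(dir, "ids.tsv"))
    cfg <- config[setdiff(names(config), "")]
    writeLines(c("# simulation manifest",
                 paste0(names(cfg), " = ",
                        vapply(cfg, function(x) paste(x, collapse = ","),
                               character(1)))),
               file.path(dir, "manifest.txt"))
  }
  out
}
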