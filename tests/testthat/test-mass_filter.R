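# reference monoisotopic residue masses (standard published values), used as
# an independent check of the composition-derived table
.ref_residue <- c(
  A = 71.037114, R = 156.101111, N = 114.042927, D = 115.026943,
  C = 103.009185, E = 129.042593, Q = 128.058578, G = 57.021464,
  H = 137.058912, I = 113.084064, L = 113.084064, K = 128.094963,
  M = 131.040485, F = 147.068414, P = 97.052764, S = 87.032028,
  T = 101.047678, W = 186.079313, Y = 163.063329, V = 99.068414
)
.ref_water <- 18.010565

test_that("theoretical envelopes are normalized and anchored at the mono peak", {
  d <- theoretical_isotope_distribution("G", 1)
  expect_equal(d$mz[1], 76.0393, tolerance = 1e-4)
  expect_equal(sum(d$intensity), 1, tolerance = 1e-6)
  expect_true(all(abs(diff(d$mz) - iso_spacing) < 1e-9))

  d2 <- theoretical_isotope_distribution("PEPTIDEK", 2)
  expect_equal(sum(d2$intensity), 1, tolerance = 1e-6)
  expect_true(all(abs(diff(d2$mz) - iso_spacing / 2) < 1e-9))

  # the A+1/A ratio grows with peptide size (more carbon)
  r1 <- with(theoretical_isotope_distribution("G", 1),
             intensity[2] / intensity[1])
  r2 <- with(theoretical_isotope_distribution("GGGGGGGGGG", 1),
             intensity[2] / intensity[1])
  expect_gt(r2, r1)

  expect_error(theoretical_isotope_distribution("GXZ", 1), "unknown residue")
})

test_that("first-peak m/z and A+1 ratios match independent calculations", {
  set.seed(407)
  for (k in 1:20) {
    pep <- paste(sample(names(.ref_residue), sample(6:15, 1), replace = TRUE),
                 collapse = "")
    z <- sample(1:3, 1)
    d <- theoretical_isotope_distribution(pep, z)
    mono_ref <- sum(.ref_residue[strsplit(pep, "")[[1]]]) + .ref_water
    expect_equal(d$mz[1], (mono_ref + z * 1.00727646688) / z,
                 tolerance = 1e-5)
    # linear single-substitution approximation of the A+1/A ratio
    f <- peptide_formula(pep)
    ratio_ref <- f[["C"]] * 0.0107 / 0.9893 + f[["H"]] * 0.000115 / 0.999885 +
      f[["N"]] * 0.00364 / 0.99636 + f[["O"]] * 0.00038 / 0.99757 +
      f[["S"]] * 0.0075 / 0.9499
    expect_equal(d$intensity[2] / d$intensity[1], ratio_ref,
                 tolerance = 0.02)
  }
})

test_that("envelope matching picks the nearest peak per window and scan", {
  d <- theoretical_isotope_distribution("SPVTMEK", 2)
  shift <- 0.005 # Th
  mk_scan <- function(id, mz_shift) structure(list(
    scan = id,
    peaks = data.frame(mz = d$mz + mz_shift, intensity = 1000 * d$intensity,
                       resolution = 30000, baseline = 0, noise = 1,
                       charge = 2L)), class = "full_scan")
  scans <- lapply(c(1L, 3L, 5L, 9L, 11L, 13L, 15L), mk_scan, mz_shift = shift)
  matched <- match_observed(d, scans, ms2_scan_id = 7L)
  # six surrounding scans only (15 is the fourth after and is ignored)
  expect_setequal(unique(matched$scan), c(1L, 3L, 5L, 9L, 11L, 13L))
  expect_equal(matched$error, rep(shift * 2, nrow(matched)), tolerance = 1e-9)

  # envelope absent: no matches
  far <- list(structure(list(scan = 6L, peaks = data.frame(
    mz = 100, intensity = 1, resolution = 1, baseline = 0, noise = 0,
    charge = 0L)), class = "full_scan"))
  expect_equal(nrow(match_observed(d, far, 7L)), 0)

  # two candidates inside the window: the nearer m/z wins
  twin <- list(structure(list(scan = 6L, peaks = data.frame(
    mz = c(d$mz[1] + 0.004, d$mz[1] - 0.02),
    intensity = c(5, 500), resolution = 1, baseline = 0, noise = 0,
    charge = 2L)), class = "full_scan"))
  m <- match_observed(d, twin, 7L)
  expect_equal(m$error[1], 0.008, tolerance = 1e-9)
})

test_that("weighted mass error is the intensity-weighted mean", {
  one <- data.frame(error = 0.005, intensity = 10)
  expect_equal(weighted_mass_error(one), 0.005)
  two <- data.frame(error = c(0.002, 0.004), intensity = c(5, 5))
  expect_equal(weighted_mass_error(two), 0.003)
  skew <- data.frame(error = c(0.004, 0.008), intensity = c(3, 1))
  expect_equal(weighted_mass_error(skew), 0.005)
  # invariant under uniform intensity scaling
  expect_equal(weighted_mass_error(transform(skew, intensity = intensity * 7)),
               0.005)
  expect_true(is.na(weighted_mass_error(skew[0, ])))
})

test_that("median normalization shifts and the threshold filters", {
  ann <- data.frame(scan = 1:3, raw_error = c(0.010, 0.012, 0.014))
  out <- normalize_and_filter(ann, threshold = 0.02)
  expect_equal(attr(out, "median_error"), 0.012)
  expect_equal(nrow(out), 3)
  expect_equal(out$normalized_error, c(-0.002, 0, 0.002))

  edge <- data.frame(scan = 1:3, raw_error = c(0, 0, 0.021))
  out2 <- normalize_and_filter(edge, threshold = 0.02)
  expect_false(3 %in% out2$scan)
})

test_that("decoy FDR follows the concatenated-database estimator", {
  expect_equal(decoy_fdr(data.frame(decoy = rep(FALSE, 10))), 0)
  ids <- data.frame(decoy = c(rep(FALSE, 1999), TRUE))
  expect_equal(decoy_fdr(ids), 2 * 1 / 2000)
  expect_equal(decoy_fdr(data.frame(decoy = rep(TRUE, 5))), 1)
  expect_true(is.na(decoy_fdr(data.frame(decoy = logical(0)))))
})

test_that("threshold filtering applies score, tryptic and protein rules", {
  ids <- data.frame(
    scan = 1:5,
    charge = c(2L, 1L, 1L, 2L, 3L),
    peptide = c("K.SAMPLEK.A", "K.TESTPEPK.G", "K.TESTPEPR.G",
                "A.BADFLANKK.G", "K.GOODPEPK.A"),
    xcorr = c(2.4, 1.9, 1.9, 4.0, 3.6),
    delcn = c(0.2, 0.09, 0.09, 0.2, 0.2),
    protein = c("p1", "p2", "p2", "p3", "p4"),
    decoy = FALSE
  )
  out <- threshold_filter(ids)
  # +2 with Xcorr 2.4 fails the 2.5 threshold
  expect_false(1 %in% out$scan)
  # +1 at 1.9 / 0.09, fully tryptic, protein with two peptides: retained
  expect_true(all(c(2, 3) %in% out$scan))
  # non-tryptic N-flank rejected
  expect_false(4 %in% out$scan)
  # protein with a single peptide rejected
  expect_false(5 %in% out$scan)
})
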