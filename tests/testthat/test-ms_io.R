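test_that("FT2 records round-trip through write and read, byte-stably", {
  recs <- list(
    list(scan = 10L, premz = 500.25, charge = 2L, mhplus = 999.49273,
         peaks = data.frame(mz = c(200.12345, 300.5, 400.75),
                            intensity = c(1000, 2000, 1500),
                            resolution = c(7500, 7500, 7500),
                            baseline = c(0, 0, 0), noise = c(1, 1, 1),
                            charge = c(1L, 1L, 0L))),
    list(scan = 12L, premz = 620.1, charge = 3L, mhplus = 1858.27818,
         peaks = data.frame(mz = c(150.11111, 250.2, 350.33333),
                            intensity = c(10, 20, 30),
                            resolution = c(7500, 7500, 7500),
                            baseline = c(0, 0, 0), noise = c(1, 1, 1),
                            charge = c(0L, 2L, 1L)))
  )
  path <- withr::local_tempfile(fileext = ".ft2")
  write_ft2(recs, path)
  back <- read_ft2(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$scan, 10L)
  expect_equal(back[[1]]$charge, 2L)
  expect_equal(back[[1]]$mhplus, 999.49273)
  expect_equal(back[[1]]$premz, 500.25)
  expect_equal(nrow(back[[1]]$peaks), 3)
  expect_equal(back[[2]]$peaks$mz, recs[[2]]$peaks$mz)
  expect_equal(back[[2]]$peaks$charge, recs[[2]]$peaks$charge)
  path2 <- withr::local_tempfile(fileext = ".ft2")
  write_ft2(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("FT1 reading handles empty files, round-trips, and seven columns", {
  empty <- withr::local_tempfile(fileext = ".ft1")
  writeLines(character(0), empty)
  expect_length(read_ft1(empty), 0)

  scans <- list(structure(list(
    scan = 5L,
    peaks = data.frame(mz = seq(400.1, 400.5, by = 0.1),
                       intensity = 1:5 * 10, resolution = rep(30000, 5),
                       baseline = rep(0, 5), noise = rep(1, 5),
                       charge = rep(0L, 5))), class = "full_scan"))
  path <- withr::local_tempfile(fileext = ".ft1")
  write_ft1(scans, path)
  back <- read_ft1(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$scan, 5L)
  expect_equal(nrow(back[[1]]$peaks), 5)

  # a trailing reserved seventh column is accepted and ignored
  lines <- readLines(path)
  lines[3] <- paste0(lines[3], "\t99")
  writeLines(lines, path)
  expect_equal(read_ft1(path)[[1]]$peaks$mz[2], 400.2)
})

test_that("malformed peak and header lines fail with the line number", {
  path <- withr::local_tempfile(fileext = ".ft2")
  writeLines(c("S\t1\t1\t500.0", "Z\t2\t999.0", "100.0 200.0 1.0"), path)
  expect_error(read_ft2(path), "line 3")
  writeLines(c("S\t1\t1", "100.0 1 1 1 1 0"), path)
  expect_error(read_ft2(path), "S line")
  writeLines(c("100.0 1 1 1 1 0"), path)
  expect_error(read_ft1(path), "line 1")
})

test_that("DTA export prints singly protonated masses at five decimals", {
  sp <- tandem_spectrum(1L, 1000.0, 2L,
                        data.frame(mass = c(0, 500.0), abundance = c(100, 50)))
  path <- withr::local_tempfile(fileext = ".dta")
  write_dta(sp, path)
  lines <- readLines(path)
  expect_equal(lines[1], "1001.00728 2")
  expect_equal(lines[2], "501.00728 50.0")

  empty <- tandem_spectrum(2L, 1000.0, 1L,
                           data.frame(mass = 0, abundance = 100))
  write_dta(empty, path)
  expect_length(readLines(path), 1)
})

test_that("deisotoping collapses envelopes to neutral masses and charges", {
  cfg <- denovo_config()
  # +1 envelope, ~3:1 intensities
  pk1 <- data.frame(mz = c(501.00728, 502.01064),
                    intensity = c(3000, 1000), charge = c(0L, 0L))
  ions <- deisotope(pk1, 2L, cfg)
  expect_equal(nrow(ions), 1)
  expect_equal(ions$charge, 1L)
  expect_equal(ions$mass, 500.0, tolerance = 1e-3)

  # same envelope at half the spacing: charge 2, twice the neutral mass
  pk2 <- data.frame(mz = c(501.00728, 501.50896),
                    intensity = c(3000, 1000), charge = c(0L, 0L))
  ions2 <- deisotope(pk2, 2L, cfg)
  expect_equal(ions2$charge, 2L)
  expect_equal(ions2$mass, 1000.0, tolerance = 1e-3)

  # lone peak: kept at charge 1 by default, dropped when a partner is required
  lone <- data.frame(mz = 321.1, intensity = 100, charge = c(0L))
  expect_equal(nrow(deisotope(lone, 2L, cfg)), 1)
  strict <- denovo_config(require_partner = TRUE)
  expect_equal(nrow(deisotope(lone, 2L, strict)), 0)
})

test_that("deisotoping is idempotent on a rendering of its own output", {
  cfg <- denovo_config()
  pk <- data.frame(mz = c(301.18453, 302.18789, 450.25, 451.25336),
                   intensity = c(900, 250, 1200, 380),
                   charge = c(0L, 0L, 0L, 0L))
  ions <- deisotope(pk, 2L, cfg)
  rendered <- data.frame(mz = ions$mass + proton_mass,
                         intensity = ions$abundance, charge = 1L)
  again <- deisotope(rendered[order(rendered$mz), ], 2L, cfg)
  expect_equal(again$mass, ions$mass, tolerance = 1e-6)
})

test_that("prepare_spectrum enforces the anchor and ordering invariants", {
  ions <- data.frame(mass = c(700.1, 300.2, 500.3), abundance = c(10, 90, 100))
  sp <- prepare_spectrum(list(scan = 7L, charge = 2L, mhplus = 901.00728), ions)
  expect_equal(nrow(sp$ions), 4)
  expect_equal(sp$ions$mass[1], 0)
  expect_equal(sp$ions$abundance[1], 100)
  expect_true(all(diff(sp$ions$mass) > 0))
  expect_equal(sp$parent_mass, 900.0, tolerance = 1e-6)

  # ion above the parent mass is dropped with a warning
  heavy <- rbind(ions, data.frame(mass = 950, abundance = 5))
  expect_warning(
    sp2 <- prepare_spectrum(list(scan = 8L, charge = 2L, mhplus = 901.00728),
                            heavy),
    "heavier")
  expect_equal(nrow(sp2$ions), 4)

  # parent charge 0 yields a flagged, rejected spectrum
  expect_warning(
    bad <- prepare_spectrum(list(scan = 9L, charge = 0L, mhplus = 901.0), ions),
    "rejected")
  expect_false(bad$valid)
  expect_false(sequence_spectrum(bad)$sequenced)
})
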