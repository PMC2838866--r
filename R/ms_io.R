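# FT1/FT2 are seven-column text extensions of the MS1/MS2 formats used for
# high-resolution data: "H" header lines (ignored), "S" scan lines (with the
# precursor m/z in FT2), a "Z" charge line (FT2 only; charge and singly
# protonated mass), then whitespace-separated peak lines with columns
# m/z, intensity, resolution, baseline, noise, charge. A trailing seventh
# column, if present, is accepted and ignored.

.peak_cols <- c("mz", "intensity", "resolution", "baseline", "noise", "charge")

.parse_peak_lines <- function(lines, linenos) {
  if (length(lines) == 0) {
    return(as.data.frame(matrix(numeric(0), ncol = 6,
                                dimnames = list(NULL, .peak_cols))))
  }
  parts <- strsplit(lines, "[ \t]+")
  nf <- lengths(parts)
  bad <- which(nf < 6 | nf > 7)
  if (length(bad) > 0) {
    stop(sprintf("malformed peak line at line %d: expected 6 or 7 columns, got %d",
                 linenos[bad[1]], nf[bad[1]]))
  }
  vals <- vapply(parts, function(p) as.numeric(p[1:6]), numeric(6))
  if (anyNA(vals)) {
    bad <- which(apply(is.na(vals), 2, any))
    stop(sprintf("non-numeric peak field at line %d", linenos[bad[1]]))
  }
  df <- as.data.frame(t(vals))
  names(df) <- .peak_cols
  df
}

#' Read a tandem-MS (FT2) file
#'
#' @param path path to an FT2 text file.
#' @return a list of scan records; each record is a list with `scan`
#'   (integer), `premz` (precursor m/z from the S line), `charge` and
#'   `mhplus` (singly protonated parent mass, from the Z line), and `peaks`
#'   (data frame with columns mz, intensity, resolution, baseline, noise,
#'   charge).
#' @seealso [write_ft2()], [deisotope()], [prepare_spectrum()]
#' @export
read_ft2 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL
  peak_lines <- character(0)
  peak_nos <- integer(0)
  flush <- function() {
    if (is.null(cur)) return()
    cur$peaks <- .parse_peak_lines(peak_lines, peak_nos)
    recs[[length(recs) + 1L]] <<- cur
  }
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    first <- substr(ln, 1, 1)
    if (first == "H") next
    if (first == "S") {
      flush()
      f <- strsplit(ln, "[ \t]+")[[1]]
      if (length(f) < 4 || is.na(as.numeric(f[4]))) {
        stop(sprintf("malformed S line at line %d (need scan numbers and precursor m/z)", k))
      }
      cur <- list(scan = as.integer(f[2]), premz = as.numeric(f[4]),
                  charge = NA_integer_, mhplus = NA_real_)
      peak_lines <- character(0)
      peak_nos <- integer(0)
    } else if (first == "Z") {
      if (is.null(cur)) stop(sprintf("Z line before any S line at line %d", k))
      f <- strsplit(ln, "[ \t]+")[[1]]
      if (length(f) < 3) stop(sprintf("malformed Z line at line %d", k))
      cur$charge <- as.integer(f[2])
      cur$mhplus <- as.numeric(f[3])
    } else {
      if (is.null(cur)) stop(sprintf("peak line before any S line at line %d", k))
      peak_lines <- c(peak_lines, ln)
      peak_nos <- c(peak_nos, k)
    }
  }
  flush()
  recs
}

#' Read a full-scan (FT1) file
#'
#' @param path path to an FT1 text file.
#' @return list of full scans, each a list with `scan` and `peaks` (same
#'   columns as [read_ft2()]).
#' @export
read_ft1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  recs <- list()
  cur <- NULL
  peak_lines <- character(0)
  peak_nos <- integer(0)
  flush <- function() {
    if (is.null(cur)) return()
    cur$peaks <- .parse_peak_lines(peak_lines, peak_nos)
    recs[[length(recs) + 1L]] <<- structure(cur, class = "full_scan")
  }
  for (k in seq_along(lines)) {
    ln <- trimws(lines[k])
    if (!nzchar(ln)) next
    first <- substr(ln, 1, 1)
    if (first == "H") next
    if (first == "S") {
      flush()
      f <- strsplit(ln, "[ \t]+")[[1]]
      cur <- list(scan = as.integer(f[2]))
      peak_lines <- character(0)
      peak_nos <- integer(0)
    } else {
      if (is.null(cur)) stop(sprintf("peak line before any S line at line %d", k))
      peak_lines <- c(peak_lines, ln)
      peak_nos <- c(peak_nos, k)
    }
  }
  flush()
  recs
}

.format_peaks <- function(peaks) {
  sprintf("%.5f\t%.2f\t%.1f\t%.2f\t%.2f\t%d",
          peaks$mz, peaks$intensity, peaks$resolution,
          peaks$baseline, peaks$noise, as.integer(peaks$charge))
}

#' Write scan records to an FT2 file
#'
#' Inverse of [read_ft2()]; the round trip through canonical formatting is
#' byte-stable.
#'
#' @param records list of scan records as returned by [read_ft2()].
#' @param path output file path.
#' @export
write_ft2 <- function(records, path) {
  out <- c("H\tExtractor\tdenovotag")
  for (r in records) {
    out <- c(out,
             sprintf("S\t%d\t%d\t%.5f", r$scan, r$scan, r$premz),
             sprintf("Z\t%d\t%.5f", r$charge, r$mhplus),
             .format_peaks(r$peaks))
  }
  writeLines(out, path)
  invisible(path)
}

#' Write full scans to an FT1 file
#'
#' @param scans list of full scans as returned by [read_ft1()].
#' @param path output file path.
#' @export
write_ft1 <- function(scans, path) {
  out <- c("H\tExtractor\tdenovotag")
  for (r in scans) {
    out <- c(out,
             sprintf("S\t%d\t%d", r$scan, r$scan),
             .format_peaks(r$peaks))
  }
  writeLines(out, path)
  invisible(path)
}

#' Export a spectrum as a DTA file
#'
#' The first line carries the singly protonated parent mass (neutral mass
#' plus one proton) and the parent charge; each following line is a fragment
#' m/z (singly protonated) and its abundance. All m/z values are printed with
#' exactly five digits after the decimal point, preserving high-resolution
#' information.
#'
#' @param spectrum a [tandem_spectrum()].
#' @param path output file path.
#' @export
write_dta <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "tandem_spectrum"))
  out <- sprintf("%.5f %d", spectrum$parent_mass + proton_mass, spectrum$charge)
  ions <- spectrum$ions[spectrum$ions$mass > 0, , drop = FALSE]
  if (nrow(ions) > 0) {
    out <- c(out, sprintf("%.5f %.1f", ions$mass + proton_mass, ions$abundance))
  }
  writeLines(out, path)
  invisible(path)
}

#' Construct a tandem spectrum object
#'
#' @param scan scan number.
#' @param parent_mass neutral monoisotopic parent mass P in Da.
#' @param charge parent charge state.
#' @param ions data frame with columns `mass` (neutral monoisotopic Da) and
#'   `abundance` (percent of base peak); the zero-mass anchor is added by
#'   [prepare_spectrum()] and is expected as the first row here.
#' @param valid logical; `FALSE` flags a rejected spectrum (e.g. unknown
#'   parent charge) that is excluded from sequencing.
#' @return object of class `tandem_spectrum`.
#' @export
tandem_spectrum <- function(scan, parent_mass, charge, ions, valid = TRUE) {
  structure(
    list(scan = as.integer(scan), parent_mass = parent_mass,
         charge = as.integer(charge), ions = ions, valid = valid),
    class = "tandem_spectrum"
  )
}

#' @export
print.tandem_spectrum <- function(x, ...) {
  cat(sprintf("tandem spectrum: scan %d, P = %.5f Da, charge %d, %d ions%s\n",
              x$scan, x$parent_mass, x$charge, nrow(x$ions) - 1L,
              if (x$valid) "" else " (rejected)"))
  invisible(x)
}

#' Assemble a deisotoped ion list into a tandem spectrum
#'
#' Prepends the zero-mass anchor ion (mass 0, abundance 100), sorts ions
#' ascending by mass, computes the neutral parent mass from the scan header
#' (preferring the Z line's singly protonated mass, else precursor m/z and
#' charge) and drops ions heavier than the parent mass plus `tol` with a
#' warning. A header with parent charge 0 yields a rejected spectrum that
#' is flagged and excluded from sequencing.
#'
#' @param header a scan record header: list with `scan`, `charge` and either
#'   `mhplus` (singly protonated parent mass) or `premz` (precursor m/z).
#' @param ions data frame with `mass` and `abundance` columns, as returned by
#'   [deisotope()].
#' @param tol tolerance in Da for the ion-below-parent invariant.
#' @return a `tandem_spectrum`.
#' @export
prepare_spectrum <- function(header, ions, tol = 0.01) {
  charge <- header$charge
  if (is.na(charge) || charge < 1) {
    warning(sprintf("scan %d: parent charge undetermined; spectrum rejected",
                    header$scan), call. = FALSE)
    return(tandem_spectrum(header$scan, NA_real_, 0L,
                           data.frame(mass = 0, abundance = 100),
                           valid = FALSE))
  }
  if (!is.null(header$mhplus) && !is.na(header$mhplus)) {
    p <- header$mhplus - proton_mass
  } else if (!is.null(header$premz) && !is.na(header$premz)) {
    p <- header$premz * charge - charge * proton_mass
  } else {
    stop(sprintf("scan %d: no parent mass in header", header$scan))
  }
  ions <- ions[, c("mass", "abundance")]
  over <- ions$mass >= p + tol
  if (any(over)) {
    warning(sprintf("scan %d: dropped %d ion(s) heavier than the parent mass",
                    header$scan, sum(over)), call. = FALSE)
    ions <- ions[!over, , drop = FALSE]
  }
  ions <- rbind(data.frame(mass = 0, abundance = 100), ions)
  ions <- ions[order(ions$mass), , drop = FALSE]
  rownames(ions) <- NULL
  tandem_spectrum(header$scan, p, charge, ions)
}
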