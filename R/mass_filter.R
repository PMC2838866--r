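# Accurate parent-mass annotation and filtering of database-search
# identifications. Each identification's theoretical isotopic envelope is
# matched against the six full scans surrounding its MS/MS scan (three
# before, three after); every matched isotopic peak is an independent mass
# measurement, and the identification's mass error is the intensity-weighted
# mean of the per-peak errors on the neutral-mass scale. Run-level
# systematic error is removed by shifting the median error to zero, and
# identifications beyond the normalized-error threshold (default 0.02 Da)
# are discarded. Decoy hits give the false discovery rate.

#' Match a theoretical envelope in surrounding full scans
#'
#' Finds, for each expected isotopic peak, the nearest observed peak within
#' `window` Th in each of the six full scans surrounding the MS/MS scan
#' (three before and three after by scan number; fewer at run boundaries).
#'
#' @param distribution an [theoretical_isotope_distribution()] result.
#' @param full_scans list of full scans (from [read_ft1()] or
#'   [simulate_full_scans()]).
#' @param ms2_scan_id scan number of the MS/MS scan.
#' @param window m/z matching half-window in Th (default 0.05).
#' @return data frame of matched peaks: `scan`, `peak` (isotope index,
#'   0-based), `mz`, `intensity`, `error` (neutral-scale Da, observed minus
#'   theoretical).
#' @export
match_observed <- function(distribution, full_scans, ms2_scan_id,
                           window = 0.05) {
  empty <- data.frame(scan = integer(0), peak = integer(0), mz = numeric(0),
                      intensity = numeric(0), error = numeric(0))
  if (length(full_scans) == 0) return(empty)
  scan_ids <- vapply(full_scans, `[[`, integer(1), "scan")
  ord <- order(scan_ids)
  full_scans <- full_scans[ord]
  scan_ids <- scan_ids[ord]
  before <- which(scan_ids < ms2_scan_id)
  after <- which(scan_ids > ms2_scan_id)
  chosen <- c(utils::tail(before, 3), utils::head(after, 3))
  rows <- list()
  z <- distribution$charge
  for (s in chosen) {
    peaks <- full_scans[[s]]$peaks
    if (nrow(peaks) == 0) next
    for (k in seq_along(distribution$mz)) {
      dmz <- abs(peaks$mz - distribution$mz[k])
      hit <- which.min(dmz)
      if (dmz[hit] <= window) {
        rows[[length(rows) + 1L]] <- data.frame(
          scan = scan_ids[s], peak = k - 1L, mz = peaks$mz[hit],
          intensity = peaks$intensity[hit],
          error = (peaks$mz[hit] - distribution$mz[k]) * z
        )
      }
    }
  }
  if (length(rows) == 0) return(empty)
  do.call(rbind, rows)
}

#' Intensity-weighted parent mass error
#'
#' @param matched data frame from [match_observed()].
#' @return weighted mean error in Da, or `NA_real_` with zero matches (the
#'   annotation is then marked missing).
#' @export
weighted_mass_error <- function(matched) {
  if (nrow(matched) == 0) return(NA_real_)
  sum(matched$error * matched$intensity) / sum(matched$intensity)
}

#' Annotate identifications with parent mass errors
#'
#' @param ids identification table: data frame with columns `scan`,
#'   `charge`, `peptide` (flanked or bare) and any others, which are
#'   carried through.
#' @param full_scans list of full scans.
#' @param window m/z matching half-window in Th.
#' @return `ids` with added columns `raw_error` and `n_matched_peaks`.
#' @export
annotate_mass_errors <- function(ids, full_scans, window = 0.05) {
  raw <- numeric(nrow(ids))
  nm <- integer(nrow(ids))
  for (r in seq_len(nrow(ids))) {
    dist <- theoretical_isotope_distribution(.j_map(strip_flanks(ids$peptide[r])),
                                             ids$charge[r])
    matched <- match_observed(dist, full_scans, ids$scan[r], window)
    raw[r] <- weighted_mass_error(matched)
    nm[r] <- nrow(matched)
  }
  ids$raw_error <- raw
  ids$n_matched_peaks <- nm
  ids
}

#' Median-normalize mass errors and filter
#'
#' Subtracts the run median from every raw error (systematic calibration
#' correction) and retains identifications with
#' `|normalized error| < threshold`. Identifications without an error
#' annotation are dropped.
#'
#' @param annotations data frame with a `raw_error` column (from
#'   [annotate_mass_errors()]).
#' @param threshold normalized-error cutoff in Da (default 0.02).
#' @return the retained rows with an added `normalized_error` column;
#'   attribute `median_error` carries the subtracted run median.
#' @export
normalize_and_filter <- function(annotations, threshold = 0.02) {
  med <- stats::median(annotations$raw_error, na.rm = TRUE)
  annotations$normalized_error <- annotations$raw_error - med
  keep <- !is.na(annotations$normalized_error) &
    abs(annotations$normalized_error) < threshold
  out <- annotations[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "median_error") <- med
  out
}

#' Target-decoy false discovery rate
#'
#' FDR of a concatenated target-decoy search: `2 D / (T + D)`, capped at 1.
#'
#' @param ids identification table with a logical (or 0/1) `decoy` column.
#' @return FDR as a fraction in `[0, 1]`; `NA` with zero identifications.
#' @export
decoy_fdr <- function(ids) {
  n <- nrow(ids)
  if (n == 0) return(NA_real_)
  d <- sum(as.logical(ids$decoy))
  min(1, 2 * d / n)
}

#' Score, tryptic and protein-level threshold filter
#'
#' Applies charge-dependent cross-correlation thresholds (1.8 for +1, 2.5
#' for +2, 3.5 for charge 3 and above), a minimum delta-correlation, a
#' fully-tryptic rule (preceding flank K, R or a protein terminus, and the
#' peptide ending in K/R or at the protein terminus) and a minimum number of
#' distinct peptides per protein.
#'
#' @param ids identification table with columns `scan`, `charge`, `peptide`
#'   (flanked, `X.PEPTIDE.Y`), `xcorr`, `delcn`, `protein`.
#' @param xcorr_min named numeric vector of thresholds for charges 1, 2 and
#'   3-and-up.
#' @param delcn_min minimum delta-correlation (default 0.08).
#' @param min_peptides_per_protein minimum number of distinct peptide
#'   sequences per retained protein (default 2).
#' @return the retained rows.
#' @export
threshold_filter <- function(ids,
                             xcorr_min = c(`1` = 1.8, `2` = 2.5, `3` = 3.5),
                             delcn_min = 0.08,
                             min_peptides_per_protein = 2L) {
  if (nrow(ids) == 0) return(ids)
  zkey <- as.character(pmin(ids$charge, 3L))
  score_ok <- ids$xcorr >= xcorr_min[zkey] & ids$delcn >= delcn_min

  core <- strip_flanks(ids$peptide)
  prev <- ifelse(grepl("\\.", ids$peptide),
                 substr(ids$peptide, 1, 1), "-")
  nxt <- ifelse(grepl("\\.", ids$peptide),
                substr(ids$peptide, nchar(ids$peptide), nchar(ids$peptide)), "-")
  last_res <- substr(core, nchar(core), nchar(core))
  tryptic <- (prev %in% c("K", "R", "-")) &
    (last_res %in% c("K", "R") | nxt == "-")

  keep <- score_ok & tryptic
  sub <- ids[keep, , drop = FALSE]
  core <- core[keep]
  pep_per_prot <- tapply(core, sub$protein, function(x) length(unique(x)))
  good_prot <- names(pep_per_prot)[pep_per_prot >= min_peptides_per_protein]
  out <- sub[sub$protein %in% good_prot, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write the tab-separated identification table
#'
#' Columns: scan, charge, peptide (flanked), xcorr, delcn, protein, decoy.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_id_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_id_table
#' @param ids identification data frame.
#' @export
write_id_table <- function(ids, path) {
  utils::write.table(ids, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
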