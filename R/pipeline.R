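# End-to-end drivers tying the modules into the three workflows:
# sequencing an FT2 file into tags, benchmarking tags against
# identifications, and parent-mass filtering of identifications against an
# FT1 file.

#' Run de novo sequencing over a set of spectra
#'
#' Accepts an FT2 file path, a list of raw scan records (from
#' [read_ft2()]) or a list of prepared [tandem_spectrum()] objects. Raw
#' records are deisotoped and assembled first. Each spectrum is sequenced
#' independently; per-spectrum failures are logged to standard error and
#' the run continues.
#'
#' @param input FT2 path, list of scan records, or list of
#'   `tandem_spectrum`.
#' @param config a [denovo_config()].
#' @return data frame with one row per attempted spectrum: `scan`,
#'   `parent_mass`, `charge`, `mp`, `tag`, `mq`, `score`, `length`,
#'   `sequenced`, `consensus` and `tag_reported` (top tag or consensus tag
#'   according to `config$tag_mode`; `NA` when the spectrum is
#'   unsequenced).
#' @export
run_sequencing <- function(input, config = denovo_config()) {
  spectra <- .as_spectra(input, config)
  rows <- lapply(spectra, function(sp) {
    row <- data.frame(scan = sp$scan, parent_mass = sp$parent_mass,
                      charge = sp$charge, mp = NA_real_, tag = NA_character_,
                      mq = NA_real_, score = NA_real_, length = NA_integer_,
                      sequenced = FALSE, consensus = NA_character_)
    result <- tryCatch(sequence_spectrum(sp, config), error = function(e) {
      message(sprintf("scan %d: sequencing failed (%s)", sp$scan,
                      conditionMessage(e)))
      NULL
    })
    if (!is.null(result) && nrow(result$tags) > 0) {
      top <- result$tags[1, ]
      row$mp <- top$mp; row$tag <- top$tag; row$mq <- top$mq
      row$score <- top$score; row$length <- top$length
      row$sequenced <- result$sequenced
      row$consensus <- result$consensus
    }
    row
  })
  out <- do.call(rbind, rows)
  out$tag_reported <- ifelse(
    !out$sequenced, NA_character_,
    if (config$tag_mode == "consensus") out$consensus else out$tag)
  if (config$tag_mode == "consensus") {
    out$tag_reported[!is.na(out$tag_reported) &
                       nchar(out$tag_reported) < config$min_tag_length] <- NA_character_
  }
  message(sprintf("sequenced %d of %d spectra (%s tag mode)",
                  sum(!is.na(out$tag_reported)), nrow(out), config$tag_mode))
  rownames(out) <- NULL
  out
}

.as_spectra <- function(input, config) {
  if (is.character(input)) input <- read_ft2(input)
  if (length(input) == 0) return(list())
  if (inherits(input[[1]], "tandem_spectrum")) return(input)
  lapply(input, function(rec) {
    ions <- deisotope(rec$peaks, max(rec$charge, 1L, na.rm = TRUE), config)
    prepare_spectrum(rec, ions, tol = config$delta)
  })
}

#' Benchmark sequencing results against identifications
#'
#' Joins the tag table to the identification table by scan, verifies each
#' reported tag, classifies errors and computes the figures of merit.
#' Scans whose identification is a decoy are excluded from the
#' intersection. Results can be stratified by parent charge group and
#' mass-coverage bin.
#'
#' @param tag_table output of [run_sequencing()] (or any data frame with
#'   `scan`, `tag_reported`, `parent_mass`, `charge`).
#' @param id_table identification table with `scan` and `peptide` columns
#'   (optional `decoy`).
#' @return list with `table` (per-scan verification report), `fom`
#'   (figures of merit), `errors` (error-type histogram with counts and
#'   percentages), `venn` (tag-only / id-only / intersection counts) and
#'   `by_charge` (figures of merit per charge group).
#' @export
run_benchmark <- function(tag_table, id_table) {
  tagged <- tag_table[!is.na(tag_table$tag_reported), , drop = FALSE]
  if (!"decoy" %in% names(id_table)) id_table$decoy <- FALSE
  idx <- match(tagged$scan, id_table$scan)
  peptide <- id_table$peptide[idx]
  decoy <- id_table$decoy[idx]
  validity <- rep("not_available", nrow(tagged))
  for (r in seq_len(nrow(tagged))) {
    if (!is.na(idx[r]) && !isTRUE(as.logical(decoy[r]))) {
      validity[r] <- verify_tag(tagged$tag_reported[r], peptide[r])
    }
  }
  error_type <- rep(NA_character_, nrow(tagged))
  wrong <- which(validity == "incorrect")
  for (r in wrong) {
    error_type[r] <- classify_error(tagged$tag_reported[r], peptide[r])
  }
  report <- data.frame(scan = tagged$scan, tag = tagged$tag_reported,
                       validity = validity,
                       identification = ifelse(is.na(idx), NA_character_,
                                               peptide),
                       error_type = error_type)
  if ("parent_mass" %in% names(tagged)) {
    report$mass_coverage <- mapply(mass_coverage, tagged$tag_reported,
                                   tagged$parent_mass)
    report$coverage_bin <- .coverage_bin(report$mass_coverage)
  }
  if ("charge" %in% names(tagged)) {
    report$charge_group <- .charge_group(tagged$charge)
  }
  fom <- figures_of_merit(data.frame(tag = report$tag,
                                     validity = report$validity))
  errors <- table(factor(error_type[wrong], levels = .error_types))
  errors <- data.frame(error_type = names(errors),
                       count = as.integer(errors),
                       percentage = if (length(wrong) > 0)
                         round(100 * as.integer(errors) / length(wrong), 1)
                       else rep(0, length(errors)))
  id_scans <- id_table$scan[!as.logical(id_table$decoy)]
  venn <- list(tag_only = sum(!tagged$scan %in% id_scans),
               id_only = sum(!id_scans %in% tagged$scan),
               intersection = sum(tagged$scan %in% id_scans))
  by_charge <- NULL
  if ("charge_group" %in% names(report)) {
    by_charge <- lapply(split(report, report$charge_group), function(d) {
      figures_of_merit(data.frame(tag = d$tag, validity = d$validity))
    })
  }
  list(table = report, fom = fom, errors = errors, venn = venn,
       by_charge = by_charge)
}

#' Write a verification report
#'
#' Tab-separated per-scan report followed by a summary block with the
#' figures of merit and the error-type histogram.
#'
#' @param benchmark result of [run_benchmark()].
#' @param path output file path.
#' @export
write_verification_report <- function(benchmark, path) {
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(benchmark$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(c("",
               sprintf("# accuracy\t%s",
                       ifelse(is.na(benchmark$fom$accuracy), "NA",
                              sprintf("%.1f%%", benchmark$fom$accuracy))),
               sprintf("# average_tag_length\t%.2f",
                       benchmark$fom$average_tag_length),
               sprintf("# sequenced_count\t%d", benchmark$fom$sequenced_count),
               "# error_type\tcount\tpercentage",
               sprintf("# %s\t%d\t%.1f", benchmark$errors$error_type,
                       benchmark$errors$count, benchmark$errors$percentage)),
             con)
  invisible(path)
}

#' Parent-mass annotate and filter an identification table
#'
#' Reads full scans (FT1 path or list), annotates each identification with
#' its intensity-weighted parent mass error, median-normalizes the errors
#' and retains identifications below the threshold; reports the decoy FDR
#' before and after filtering.
#'
#' @param full_scans FT1 file path or list of full scans.
#' @param ids identification table (data frame or TSV path).
#' @param threshold normalized-error cutoff in Da (default 0.02).
#' @param window envelope matching half-window in Th (default 0.05).
#' @return list with `annotations`, `retained`, `median_error`,
#'   `fdr_before`, `fdr_after`.
#' @export
run_mass_filter <- function(full_scans, ids, threshold = 0.02, window = 0.05) {
  if (is.character(full_scans)) full_scans <- read_ft1(full_scans)
  if (is.character(ids)) ids <- read_id_table(ids)
  ann <- annotate_mass_errors(ids, full_scans, window)
  retained <- normalize_and_filter(ann, threshold)
  list(annotations = ann,
       retained = retained,
       median_error = attr(retained, "median_error"),
       fdr_before = if ("decoy" %in% names(ids)) decoy_fdr(ids) else NA_real_,
       fdr_after = if ("decoy" %in% names(retained)) decoy_fdr(retained)
       else NA_real_)
}
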