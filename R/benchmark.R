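# Tag verification against database-search identifications, error-type
# classification and the three figures of merit (accuracy, average tag
# length, number of sequenced spectra).

#' Strip flanking-residue annotation from a peptide string
#'
#' Identifications conventionally carry flanking residues as
#' `X.PEPTIDE.Y`; the core is obtained by splitting on the first and last
#' period. Strings without periods are returned unchanged.
#'
#' @param peptide annotated or bare peptide string(s).
#' @return bare peptide core(s).
#' @export
strip_flanks <- function(peptide) {
  core <- sub("^[^.]*\\.", "", peptide)
  sub("\\.[^.]*$", "", core)
}

#' Verify a sequence tag against an identified peptide
#'
#' The tag is correct if it, in either direction, matches exactly a
#' contiguous portion of the peptide sequence. The peptide's I and L
#' residues are mapped to J before matching, since the two isobars are not
#' distinguishable by mass.
#'
#' @param tag_residues tag residue string (over the tag alphabet).
#' @param peptide peptide string, with or without flanking annotation.
#' @return `"correct"` or `"incorrect"`.
#' @export
verify_tag <- function(tag_residues, peptide) {
  if (is.na(tag_residues) || !nzchar(tag_residues)) {
    stop("verify_tag requires a non-empty tag")
  }
  core <- .j_map(strip_flanks(peptide))
  hit <- grepl(tag_residues, core, fixed = TRUE) ||
    grepl(.rev_str(tag_residues), core, fixed = TRUE)
  if (hit) "correct" else "incorrect"
}

.error_types <- c("substitution_Q_by_GA", "substitution_N_by_GG",
                  "adjacent_inversion", "end_substitution",
                  "internal_substitution", "other")

# candidate corrected tags for one error type
.error_candidates <- function(tag, type) {
  ch <- strsplit(tag, "")[[1]]
  m <- length(ch)
  out <- character(0)
  if (type == "substitution_Q_by_GA") {
    for (i in which(ch == "Q")) {
      for (rep in c("GA", "AG")) {
        out <- c(out, paste(c(ch[seq_len(i - 1)], rep, ch[-seq_len(i)]),
                            collapse = ""))
      }
    }
  } else if (type == "substitution_N_by_GG") {
    for (i in which(ch == "N")) {
      out <- c(out, paste(c(ch[seq_len(i - 1)], "GG", ch[-seq_len(i)]),
                          collapse = ""))
    }
  } else if (type == "adjacent_inversion") {
    if (m >= 2) {
      for (i in seq_len(m - 1)) {
        if (ch[i] == ch[i + 1]) next
        sw <- ch; sw[c(i, i + 1)] <- ch[c(i + 1, i)]
        out <- c(out, paste(sw, collapse = ""))
      }
    }
  } else if (type == "end_substitution") {
    for (i in unique(c(1L, m))) {
      for (r in setdiff(.tag_alphabet, ch[i])) {
        sub <- ch; sub[i] <- r
        out <- c(out, paste(sub, collapse = ""))
      }
    }
  } else if (type == "internal_substitution") {
    if (m >= 3) {
      for (i in 2:(m - 1)) {
        for (r in setdiff(.tag_alphabet, ch[i])) {
          sub <- ch; sub[i] <- r
          out <- c(out, paste(sub, collapse = ""))
        }
      }
    }
  }
  unique(out)
}

#' Classify the error type of an incorrect tag
#'
#' Tests, in fixed precedence order -- Q replaced by GA, N replaced by GG,
#' inversion of two adjacent residues, substitution of an end residue,
#' substitution of an internal residue -- whether a single change of that
#' type makes the tag verify as correct; the first success wins, otherwise
#' `"other"`.
#'
#' @inheritParams verify_tag
#' @return one of `"substitution_Q_by_GA"`, `"substitution_N_by_GG"`,
#'   `"adjacent_inversion"`, `"end_substitution"`,
#'   `"internal_substitution"`, `"other"`.
#' @export
classify_error <- function(tag_residues, peptide) {
  if (verify_tag(tag_residues, peptide) == "correct") {
    stop("classify_error expects an incorrect tag")
  }
  for (type in .error_types[-length(.error_types)]) {
    cands <- .error_candidates(tag_residues, type)
    for (cand in cands) {
      if (verify_tag(cand, peptide) == "correct") return(type)
    }
  }
  "other"
}

#' Figures of merit of a sequencing run
#'
#' Accuracy is the percentage of correctly sequenced spectra among spectra
#' that have both a tag and an identification; the average tag length is
#' taken over all tagged spectra; the sequenced count is the number of
#' tagged spectra. With an empty intersection the accuracy is undefined
#' (`NA`, not zero).
#'
#' @param results data frame with one row per tagged spectrum: columns
#'   `tag` and `validity` (`"correct"`, `"incorrect"` or
#'   `"not_available"`).
#' @return list with `accuracy` (percent), `average_tag_length` and
#'   `sequenced_count`.
#' @export
figures_of_merit <- function(results) {
  n_corr <- sum(results$validity == "correct")
  n_inc <- sum(results$validity == "incorrect")
  acc <- if (n_corr + n_inc == 0) NA_real_ else 100 * n_corr / (n_corr + n_inc)
  list(accuracy = acc,
       average_tag_length = if (nrow(results) == 0) NA_real_ else
         mean(nchar(results$tag)),
       sequenced_count = nrow(results))
}

#' Mass coverage of a tag
#'
#' Percentage of the neutral parent peptide mass explained by the tag's
#' residues.
#'
#' @param tag residue string (may be empty).
#' @param p neutral parent mass (> 0).
#' @param masses residue-mass table.
#' @return coverage percentage in `[0, 100)`.
#' @export
mass_coverage <- function(tag, p, masses = residue_masses()) {
  stopifnot(p > 0)
  if (is.na(tag) || !nzchar(tag)) return(0)
  100 * sum(masses[strsplit(tag, "")[[1]]]) / p
}

# coverage bin labels used for stratified reporting
.coverage_bin <- function(cov) {
  cut(cov, breaks = c(-Inf, 20, 40, Inf),
      labels = c("0-20%", "20-40%", "40-100%"))
}

.charge_group <- function(z) {
  ifelse(z <= 1, "+1", ifelse(z == 2, "+2", ">=+3"))
}
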