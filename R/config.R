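#' Run configuration for sequencing and preprocessing
#'
#' Collects the tunable parameters of the pipeline. Defaults follow the
#' method's standard operating point: a relative mass error tolerance of
#' 0.01 Da, a minimum tag length of 3 residues and a top-tag score cutoff
#' of 4.0.
#'
#' @param delta relative mass error tolerance in Da for spectrum-graph edges.
#' @param min_tag_length minimum number of residues in a reported tag.
#' @param score_cutoff minimum top-tag score for a spectrum to count as
#'   sequenced.
#' @param tag_mode `"top"` to report the top tag per spectrum, `"consensus"`
#'   to report the consensus of the top two tags.
#' @param max_paths per-component cap on enumerated paths; a component
#'   exceeding it is skipped with a warning and its spectrum flagged
#'   unsequenced.
#' @param min_isotope_peaks minimum number of peaks for an accepted isotopic
#'   envelope during deisotoping; `NULL` means 1 for charge 1 and 2 for
#'   charge >= 2.
#' @param ratio_tolerance maximum fold deviation of observed isotope intensity
#'   ratios from the averagine-predicted envelope.
#' @param require_partner if `TRUE`, lone peaks without any isotopic partner
#'   are dropped regardless of charge.
#' @param iso_mz_tol m/z window (Th) for matching isotopic partner peaks.
#' @param merge_tol neutral-mass window (Da) within which deisotoped ions are
#'   merged, keeping the more abundant one.
#' @param mass_overrides optional named numeric vector of residue-mass
#'   overrides, passed to [residue_masses()].
#' @return a list of class `denovo_config`.
#' @export
denovo_config <- function(delta = 0.01,
                          min_tag_length = 3L,
                          score_cutoff = 4.0,
                          tag_mode = c("top", "consensus"),
                          max_paths = 1e6,
                          min_isotope_peaks = NULL,
                          ratio_tolerance = 3,
                          require_partner = FALSE,
                          iso_mz_tol = 0.01,
                          merge_tol = 0.005,
                          mass_overrides = NULL) {
  stopifnot(delta > 0, min_tag_length >= 1, max_paths >= 1)
  tag_mode <- match.arg(tag_mode)
  structure(
    list(
      delta = delta,
      min_tag_length = as.integer(min_tag_length),
      score_cutoff = score_cutoff,
      tag_mode = tag_mode,
      max_paths = max_paths,
      min_isotope_peaks = min_isotope_peaks,
      ratio_tolerance = ratio_tolerance,
      require_partner = require_partner,
      iso_mz_tol = iso_mz_tol,
      merge_tol = merge_tol,
      mass_overrides = mass_overrides,
      masses = residue_masses(mass_overrides)
    ),
    class = "denovo_config"
  )
}

#' Read a key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and lines starting with `#`
#' are ignored. Keys named `mass.X` (X a tag-alphabet letter) become residue
#' mass overrides; every other key must be an argument of [denovo_config()].
#'
#' @param path file path.
#' @return a `denovo_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  overrides <- c()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(kv[2])
    if (startsWith(key, "mass.")) {
      res <- sub("^mass\\.", "", key)
      overrides[res] <- as.numeric(val)
    } else if (key == "tag_mode") {
      args[[key]] <- val
    } else if (key == "require_partner") {
      args[[key]] <- as.logical(val)
    } else {
      args[[key]] <- as.numeric(val)
    }
  }
  if (length(overrides) > 0) args$mass_overrides <- overrides
  do.call(denovo_config, args)
}
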