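# Step 1: the spectrum graph. Every deisotoped product ion (including the
# zero-mass anchor) is exactly one vertex. For a vertex pair with masses
# m_i < m_j, parent mass P and residue mass M, four typed relations are
# tested at tolerance delta:
#   arrow        | (m_j - m_i) - M |      adjacent ions of the same series
#   vertical_bar | (m_j + m_i) - P |      complementary y/b pair
#   forward_slash| P - (m_j + m_i) - M |  ion and the next complementary ion
#   backslash    | (m_j + m_i) - P - M |  ion and the previous complementary ion
# Each qualifying (pair, type, residue) combination is one edge with its own
# relative mass error epsilon and standardized weight.

.edge_types <- c("arrow", "forward_slash", "backslash", "vertical_bar")

#' Standardized weight of a spectrum edge
#'
#' Maps a relative mass error to a weight by
#' `w = 2 * (1 - pnorm(epsilon, 0, delta / 2))`: a folded-normal survival
#' transform in which the error tolerance spans two standard deviations.
#' The weight is 1 at zero error and about 0.05 (exactly
#' `2 * (1 - pnorm(2))`) at `epsilon = delta`, strictly decreasing in
#' between.
#'
#' @param epsilon relative mass error(s) in Da, in `[0, delta]`.
#' @param delta mass error tolerance in Da.
#' @return numeric vector of edge weights.
#' @export
edge_weight <- function(epsilon, delta) {
  if (any(epsilon < 0) || any(epsilon > delta)) {
    stop("epsilon must lie in [0, delta]")
  }
  2 * stats::pnorm(epsilon, mean = 0, sd = delta / 2, lower.tail = FALSE)
}

#' Classify a vertex pair into spectrum-edge types
#'
#' Tests all four edge conditions for every residue of the tag alphabet and
#' returns one row per qualifying (type, residue) combination. The result is
#' empty when no condition holds; a pair may qualify for several edges at
#' once, all of which are reported.
#'
#' @param m_i,m_j neutral ion masses with `m_i < m_j`.
#' @param p neutral parent mass P.
#' @param delta mass error tolerance in Da.
#' @param masses residue-mass table from [residue_masses()].
#' @return data frame with columns `type`, `residue` (NA for vertical-bar
#'   edges) and `epsilon`.
#' @export
classify_pair <- function(m_i, m_j, p, delta, masses = residue_masses()) {
  stopifnot(m_i < m_j, delta > 0)
  type <- character(0); residue <- character(0); eps <- numeric(0)
  d <- m_j - m_i
  s <- m_i + m_j
  e_arr <- abs(d - masses)
  e_fs <- abs(p - s - masses)
  e_bs <- abs(s - p - masses)
  hit <- which(e_arr < delta)
  if (length(hit)) {
    type <- c(type, rep("arrow", length(hit)))
    residue <- c(residue, names(masses)[hit]); eps <- c(eps, e_arr[hit])
  }
  e_vb <- abs(s - p)
  if (e_vb < delta) {
    type <- c(type, "vertical_bar"); residue <- c(residue, NA_character_)
    eps <- c(eps, e_vb)
  }
  hit <- which(e_fs < delta)
  if (length(hit)) {
    type <- c(type, rep("forward_slash", length(hit)))
    residue <- c(residue, names(masses)[hit]); eps <- c(eps, e_fs[hit])
  }
  hit <- which(e_bs < delta)
  if (length(hit)) {
    type <- c(type, rep("backslash", length(hit)))
    residue <- c(residue, names(masses)[hit]); eps <- c(eps, e_bs[hit])
  }
  data.frame(type = type, residue = residue, epsilon = unname(eps))
}

#' Build the spectrum graph of a tandem spectrum
#'
#' Classifies every vertex pair (all ions, anchor included) with
#' [classify_pair()] and attaches the standardized weight
#' [edge_weight()] to each edge.
#'
#' @param spectrum a valid [tandem_spectrum()].
#' @param delta mass error tolerance in Da.
#' @param masses residue-mass table.
#' @return object of class `spectrum_graph`: list with the `spectrum`,
#'   `delta`, `masses` and an `edges` data frame (`i`, `j`, `type`,
#'   `residue`, `epsilon`, `weight`), where `i < j` index `spectrum$ions`.
#' @export
build_spectrum_graph <- function(spectrum, delta = 0.01,
                                 masses = residue_masses()) {
  stopifnot(inherits(spectrum, "tandem_spectrum"), spectrum$valid)
  m <- spectrum$ions$mass
  p <- spectrum$parent_mass
  n <- length(m)
  empty <- data.frame(i = integer(0), j = integer(0), type = character(0),
                      residue = character(0), epsilon = numeric(0),
                      weight = numeric(0))
  if (n < 2) {
    return(structure(list(spectrum = spectrum, delta = delta, masses = masses,
                          edges = empty), class = "spectrum_graph"))
  }
  iu <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  ju <- sequence((n - 1L):1L) + iu
  dvec <- m[ju] - m[iu]
  svec <- m[iu] + m[ju]

  ii <- integer(0); jj <- integer(0); ty <- character(0)
  rr <- character(0); ee <- numeric(0)
  for (res in names(masses)) {
    mm <- masses[[res]]
    for (cond in c("arrow", "forward_slash", "backslash")) {
      eps <- switch(cond,
                    arrow = abs(dvec - mm),
                    forward_slash = abs(p - svec - mm),
                    backslash = abs(svec - p - mm))
      hit <- which(eps < delta)
      if (length(hit)) {
        ii <- c(ii, iu[hit]); jj <- c(jj, ju[hit])
        ty <- c(ty, rep(cond, length(hit)))
        rr <- c(rr, rep(res, length(hit))); ee <- c(ee, eps[hit])
      }
    }
  }
  eps <- abs(svec - p)
  hit <- which(eps < delta)
  if (length(hit)) {
    ii <- c(ii, iu[hit]); jj <- c(jj, ju[hit])
    ty <- c(ty, rep("vertical_bar", length(hit)))
    rr <- c(rr, rep(NA_character_, length(hit))); ee <- c(ee, eps[hit])
  }
  edges <- if (length(ii)) {
    data.frame(i = ii, j = jj, type = ty, residue = rr, epsilon = ee,
               weight = edge_weight(ee, delta))
  } else empty
  ord <- order(edges$i, edges$j, match(edges$type, .edge_types), edges$residue)
  edges <- edges[ord, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(spectrum = spectrum, delta = delta, masses = masses,
                 edges = edges),
            class = "spectrum_graph")
}

#' @export
print.spectrum_graph <- function(x, ...) {
  cat(sprintf("spectrum graph: %d vertices, %d edges (delta = %g Da)\n",
              nrow(x$spectrum$ions), nrow(x$edges), x$delta))
  invisible(x)
}

#' Dump a spectrum graph's edge list as tab-separated text
#'
#' @param graph a `spectrum_graph`.
#' @param path output file path.
#' @export
write_spectrum_graph <- function(graph, path) {
  utils::write.table(graph$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
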