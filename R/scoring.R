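# Step 4: scoring, ranking, residual masses and the consensus tag.
# A path's score is the summed standardized weight of every spectrum edge it
# covers: the residue-labeled edges across each member vertex's two site
# groups plus the vertical bars within them, each edge counted once even
# when shared between adjacent vertices. Residual masses locate the tag
# within the parent mass: mp + sum(M(R_i)) + mq = P up to measurement error.

# ordered cleavage-site ion groups along an oriented path (m vertices ->
# m + 1 sites)
.path_sites <- function(path, graph) {
  v <- path$vertices
  m <- length(v)
  verts <- graph$vertices
  if (m == 1) {
    return(list(verts[[v]]$sites[[1]], verts[[v]]$sites[[2]]))
  }
  ent <- path$entry
  exit <- integer(m)
  exit[1] <- path$exit1
  if (m > 1) for (k in 2:m) exit[k] <- 3L - ent[k]
  sites <- vector("list", m + 1L)
  sites[[1]] <- verts[[v[1]]]$sites[[3L - exit[1]]]
  for (k in seq_len(m - 1L)) {
    sites[[k + 1L]] <- sort(unique(c(verts[[v[k]]]$sites[[exit[k]]],
                                     verts[[v[k + 1L]]]$sites[[ent[k + 1L]]])))
  }
  sites[[m + 1L]] <- verts[[v[m]]]$sites[[exit[m]]]
  sites
}

#' Spectrum edges covered by a sequence path
#'
#' @param path a path from [enumerate_all_paths()].
#' @param graph the [build_sequence_graph()] result it came from.
#' @return sorted integer vector of spectrum-edge row indices.
#' @export
covered_spectrum_edges <- function(path, graph) {
  sort(unique(unlist(lapply(graph$vertices[path$vertices], `[[`, "support"))))
}

#' Score a sequence path
#'
#' Sum of the standardized weights of all covered spectrum edges.
#'
#' @inheritParams covered_spectrum_edges
#' @return numeric score (> 0 for any non-empty path).
#' @export
score_path <- function(path, graph) {
  sum(graph$sgraph$edges$weight[covered_spectrum_edges(path, graph)])
}

#' Residual masses of a sequence path
#'
#' Estimates the prefix fragment mass at the path's first cleavage site.
#' Every ion at every site along the path implies a candidate value for that
#' prefix mass under one of its two readings (the ion is the prefix fragment
#' itself, or the complement read through P); the readings consistent with
#' one direction of the tag agree with each other, so the estimate is the
#' mean of the largest mutually consistent cluster of candidates. The
#' trailing residual follows as `mq = P - mp - sum(M(R_i))`.
#'
#' @inheritParams covered_spectrum_edges
#' @param p neutral parent mass; defaults to the spectrum's.
#' @return named numeric vector `c(mp = , mq = )` for the path read in its
#'   stored direction, with attribute `consistent`: `TRUE` when every ion
#'   at every site reads (directly or through its complement) as the
#'   clustered ladder position, i.e. the path is a genuine monotone run of
#'   cleavage sites rather than a folded reading through coincidental
#'   edges.
#' @export
residual_masses <- function(path, graph, p = NULL) {
  if (is.null(p)) p <- graph$sgraph$spectrum$parent_mass
  masses <- graph$sgraph$masses
  ion_mass <- graph$sgraph$spectrum$ions$mass
  res <- vapply(graph$vertices[path$vertices], `[[`, character(1), "residue")
  m <- length(res)
  sites <- .path_sites(path, graph)
  cum <- c(0, cumsum(unname(masses[res])))
  cand <- numeric(0)
  for (t in seq_along(sites)) {
    ions <- ion_mass[sites[[t]]]
    cand <- c(cand, ions - cum[t], (p - ions) - cum[t])
  }
  tol <- (m + 1) * graph$sgraph$delta
  counts <- rowSums(abs(outer(cand, cand, "-")) <= tol)
  best <- which(counts == max(counts))
  centre <- cand[best[which.min(cand[best])]]
  cluster <- cand[abs(cand - centre) <= tol]
  mp <- mean(cluster)
  mq <- p - mp - sum(masses[res])
  consistent <- TRUE
  for (t in seq_along(sites)) {
    ions <- ion_mass[sites[[t]]]
    expect <- mp + cum[t]
    if (any(pmin(abs(ions - expect), abs((p - ions) - expect)) > tol)) {
      consistent <- FALSE
      break
    }
  }
  structure(c(mp = mp, mq = mq), consistent = consistent)
}

#' Rank the paths of a spectrum into sequence tags
#'
#' Converts each enumerated path into a tag (residue string, residual
#' masses, score), canonicalizes the reading direction (lexicographically
#' smaller of the string and its reverse; tags are direction-free), drops
#' tags shorter than `config$min_tag_length` or with residual masses below
#' zero beyond tolerance, and sorts by score descending with ties broken by
#' length descending then residue string. The spectrum counts as sequenced
#' only when the top tag reaches `config$score_cutoff`.
#'
#' @param paths result of [enumerate_all_paths()].
#' @param graph the corresponding sequence graph.
#' @param config a [denovo_config()].
#' @return data frame with columns `scan`, `mp`, `tag`, `mq`, `score`,
#'   `length`; attribute `sequenced` is `TRUE` when the top tag passes the
#'   score cutoff.
#' @export
rank_tags <- function(paths, graph, config = denovo_config()) {
  masses <- graph$sgraph$masses
  scan <- graph$sgraph$spectrum$scan
  p <- graph$sgraph$spectrum$parent_mass
  delta <- graph$sgraph$delta
  residue_of <- vapply(graph$vertices, `[[`, character(1), "residue")
  n <- length(paths)
  v_mp <- numeric(n); v_mq <- numeric(n); v_tag <- character(n)
  v_score <- numeric(n); v_len <- integer(n); keep <- logical(n)
  for (k in seq_len(n)) {
    path <- paths[[k]]
    m <- length(path$vertices)
    if (m < config$min_tag_length) next
    res <- residue_of[path$vertices]
    tag <- paste(res, collapse = "")
    rm <- residual_masses(path, graph, p)
    mp <- rm[["mp"]]; mq <- rm[["mq"]]
    # geometrically inconsistent placements (negative residuals or folded
    # site readings through coincidental edges) are not legitimate tags
    if (mp < -m * delta || mq < -m * delta) next
    if (!isTRUE(attr(rm, "consistent"))) next
    rtag <- .rev_str(tag)
    if (rtag < tag) { tag <- rtag; tmp <- mp; mp <- mq; mq <- tmp }
    keep[k] <- TRUE
    v_mp[k] <- mp; v_mq[k] <- mq; v_tag[k] <- tag
    v_score[k] <- score_path(path, graph); v_len[k] <- m
  }
  if (!any(keep)) {
    out <- data.frame(scan = integer(0), mp = numeric(0), tag = character(0),
                      mq = numeric(0), score = numeric(0), length = integer(0))
    attr(out, "sequenced") <- FALSE
    return(out)
  }
  out <- data.frame(scan = scan, mp = v_mp[keep], tag = v_tag[keep],
                    mq = v_mq[keep], score = v_score[keep],
                    length = v_len[keep])
  out <- out[order(-out$score, -out$length, out$tag), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sequenced") <- out$score[1] >= config$score_cutoff
  out
}

# all longest common contiguous substrings of two strings (DP over suffixes)
.longest_common_substrings <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  if (na == 0 || nb == 0) return(character(0))
  best <- 0L
  ends <- integer(0)
  prev <- integer(nb)
  for (i in seq_len(na)) {
    curr <- integer(nb)
    for (j in seq_len(nb)) {
      if (ca[i] == cb[j]) {
        curr[j] <- if (j == 1L) 1L else prev[j - 1L] + 1L
        if (curr[j] > best) {
          best <- curr[j]; ends <- i
        } else if (curr[j] == best) {
          ends <- c(ends, i)
        }
      }
    }
    prev <- curr
  }
  if (best == 0L) return(character(0))
  unique(vapply(ends, function(e) paste(ca[(e - best + 1L):e], collapse = ""),
                character(1)))
}

#' Consensus tag of the top two sequence tags
#'
#' The longest common contiguous residue string between the two tags,
#' considering both reading directions of each. Returns `NA` when the
#' common string is shorter than `min_len` or when a second tag does not
#' exist. Because the consensus is a substring of both parents, it is
#' correct whenever at least one parent tag is correct.
#'
#' @param top_tag,second_tag residue strings of the two top-ranked tags;
#'   `second_tag` may be `NA` or missing.
#' @param min_len minimum consensus length (default 3).
#' @return the consensus residue string (canonical direction:
#'   lexicographically smaller of string and reverse), or `NA_character_`.
#' @export
consensus_tag <- function(top_tag, second_tag, min_len = 3L) {
  if (is.null(second_tag) || length(second_tag) == 0 || is.na(second_tag) ||
      is.na(top_tag)) {
    return(NA_character_)
  }
  cands <- c(.longest_common_substrings(top_tag, second_tag),
             .longest_common_substrings(top_tag, .rev_str(second_tag)))
  if (length(cands) == 0) return(NA_character_)
  len <- nchar(cands)
  cands <- cands[len == max(len)]
  if (max(len) < min_len) return(NA_character_)
  canon <- unname(vapply(cands, function(s) min(s, .rev_str(s)), character(1)))
  sort(canon)[1]
}

#' De novo sequence a single spectrum
#'
#' Runs the full per-spectrum chain: spectrum graph, sequence graph, path
#' enumeration, ranking, and (when available) the consensus of the top two
#' tags.
#'
#' @param spectrum a [tandem_spectrum()].
#' @param config a [denovo_config()].
#' @return list with `tags` (ranked tag data frame), `sequenced` (logical)
#'   and `consensus` (residue string or `NA`).
#' @export
sequence_spectrum <- function(spectrum, config = denovo_config()) {
  empty <- list(tags = rank_tags(list(),
                                 structure(list(vertices = list(),
                                                sgraph = list(spectrum = spectrum,
                                                              delta = config$delta,
                                                              masses = config$masses)),
                                           class = "sequence_graph"),
                                 config),
                sequenced = FALSE, consensus = NA_character_)
  if (!spectrum$valid) return(empty)
  sg <- build_spectrum_graph(spectrum, config$delta, config$masses)
  qg <- build_sequence_graph(sg)
  paths <- enumerate_all_paths(qg, config$max_paths)
  if (isTRUE(attr(paths, "overflow"))) return(empty)
  tags <- rank_tags(paths, qg, config)
  consensus <- if (nrow(tags) >= 2) {
    consensus_tag(tags$tag[1], tags$tag[2], config$min_tag_length)
  } else {
    NA_character_
  }
  list(tags = tags, sequenced = isTRUE(attr(tags, "sequenced")),
       consensus = consensus)
}

#' Write a tag table in the standard report layout
#'
#' Tab-separated columns scan, mp, tag, mq, score with residual masses to
#' three decimals and scores to one decimal.
#'
#' @param tags data frame with columns `scan`, `mp`, `tag`, `mq`, `score`.
#' @param path output file path.
#' @export
write_tags <- function(tags, path) {
  out <- data.frame(scan = tags$scan,
                    mp = sprintf("%.3f", tags$mp),
                    tag = tags$tag,
                    mq = sprintf("%.3f", tags$mq),
                    score = sprintf("%.1f", tags$score))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
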