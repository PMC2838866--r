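# Step 3: exhaustive enumeration of valid paths in the sequence graph.
# A valid path repeats no vertex and no traversable edge (simple path rule)
# and contains no two vertices joined by a short-circuit edge (short-circuit
# rule). Additionally, consecutive merges must chain: the cleavage site a
# vertex shares with its successor must be the opposite site group from the
# one it shares with its predecessor, so that the path reads a linear run of
# cleavage sites. Enumeration is a depth-first recursion over every vertex
# pair, pruning as soon as a prefix violates the short-circuit rule.

# adjacency + short-circuit lookup tables for one sequence graph
.path_index <- function(graph) {
  n <- length(graph$vertices)
  sc <- matrix(FALSE, n, n)
  adj <- rep(list(list()), n)
  ed <- graph$edges
  for (r in seq_len(nrow(ed))) {
    a <- as.integer(ed$u[r]); b <- as.integer(ed$w[r])
    if (ed$kind[r] == "short_circuit") {
      sc[a, b] <- TRUE; sc[b, a] <- TRUE
    } else {
      om <- graph$orient[[r]]
      adj[[a]][[length(adj[[a]]) + 1L]] <- list(nb = b, om = om)
      adj[[b]][[length(adj[[b]]) + 1L]] <- list(nb = a, om = om[, 2:1, drop = FALSE])
    }
  }
  # deterministic neighbour order
  for (k in seq_len(n)) {
    if (length(adj[[k]]) > 1) {
      ord <- order(vapply(adj[[k]], `[[`, integer(1), "nb"))
      adj[[k]] <- adj[[k]][ord]
    }
  }
  list(sc = sc, adj = adj)
}

#' Enumerate all valid paths between two sequence vertices
#'
#' Recursive depth-first search over traversable edges. Paths end at the
#' first arrival at `destination`; a prefix containing a short-circuit pair
#' is pruned immediately. When `source == destination` the single-vertex
#' path is returned. Paths are reported as vertex index sequences together
#' with the site-merge orientations used along the way.
#'
#' @param source,destination sequence-vertex indices.
#' @param graph a [build_sequence_graph()] result.
#' @param max_paths cap on the number of emitted paths; exceeding it raises
#'   a condition of class `denovotag_overflow`.
#' @return list of paths; each path is a list with `vertices` (integer
#'   vector), `entry` (site group of each vertex merged with its
#'   predecessor; NA for the first) and `exit1` (site group of the first
#'   vertex merged with the second; NA for single-vertex paths).
#' @export
find_paths_between <- function(source, destination, graph, max_paths = Inf) {
  idx <- .path_index(graph)
  acc <- new.env(parent = emptyenv())
  acc$paths <- list()
  acc$seen <- new.env(parent = emptyenv(), hash = TRUE)
  .find_paths(source, destination, idx, acc, max_paths)
  acc$paths
}

.find_paths <- function(source, destination, idx, acc, max_paths) {
  emit <- function(v, entry, exit1) {
    key <- paste(v, collapse = ",")
    if (!is.null(acc$seen[[key]])) return()
    acc$seen[[key]] <- TRUE
    if (length(acc$paths) + 1L > max_paths) {
      cond <- structure(class = c("denovotag_overflow", "condition"),
                        list(message = "path count exceeded max_paths",
                             call = NULL))
      stop(cond)
    }
    acc$paths[[length(acc$paths) + 1L]] <-
      list(vertices = v, entry = entry, exit1 = exit1)
  }
  if (source == destination) {
    emit(source, NA_integer_, NA_integer_)
    return(invisible(NULL))
  }
  rec <- function(v, entry_v, vlist, entries, exit1) {
    # short-circuit rule: v against every vertex already on the path
    if (any(idx$sc[v, vlist])) return()
    vlist2 <- c(vlist, v)
    entries2 <- c(entries, entry_v)
    if (v == destination) {
      emit(vlist2, entries2, exit1)
      return()
    }
    for (nbr in idx$adj[[v]]) {
      if (nbr$nb %in% vlist2) next
      om <- nbr$om
      for (r in seq_len(nrow(om))) {
        gv <- om[r, 1]; gn <- om[r, 2]
        if (!is.na(entry_v) && gv == entry_v) next
        rec(nbr$nb, gn, vlist2, entries2,
            if (length(vlist2) == 1L) gv else exit1)
      }
    }
  }
  rec(source, NA_integer_, integer(0), integer(0), NA_integer_)
  invisible(NULL)
}

#' Enumerate all valid paths in a sequence graph
#'
#' Iterates over every vertex pair within each traversable component
#' (components are processed independently) and collects all valid paths,
#' deduplicated under reversal: a path and its reverse describe the same
#' tag, so each unordered pair is visited once. Output order is
#' deterministic: longest first, then by residue string, then by vertex
#' sequence. A component whose path count exceeds `max_paths` is skipped
#' with a warning, and the result is flagged with attribute `overflow`.
#'
#' @param graph a [build_sequence_graph()] result.
#' @param max_paths per-component cap on enumerated paths.
#' @return list of paths as in [find_paths_between()], with attribute
#'   `overflow` set to `TRUE` if any component was skipped.
#' @export
enumerate_all_paths <- function(graph, max_paths = 1e6) {
  comps <- sequence_components(graph)
  idx <- .path_index(graph)
  all_paths <- list()
  overflow <- FALSE
  for (comp in comps) {
    acc <- new.env(parent = emptyenv())
    acc$paths <- list()
    comp_paths <- tryCatch({
      for (v in comp) {
        acc$seen <- new.env(parent = emptyenv(), hash = TRUE)
        .find_paths(v, v, idx, acc, max_paths)
      }
      if (length(comp) >= 2) {
        for (pr in utils::combn(comp, 2, simplify = FALSE)) {
          acc$seen <- new.env(parent = emptyenv(), hash = TRUE)
          .find_paths(pr[1], pr[2], idx, acc, max_paths)
        }
      }
      acc$paths
    },
    denovotag_overflow = function(cond) {
      warning(sprintf("component with %d vertices exceeded max_paths = %g; skipped",
                      length(comp), max_paths), call. = FALSE)
      NULL
    })
    if (is.null(comp_paths)) {
      overflow <- TRUE
    } else {
      all_paths <- c(all_paths, comp_paths)
    }
  }
  if (length(all_paths) > 1) {
    res_of <- function(p) paste(vapply(graph$vertices[p$vertices], `[[`,
                                       character(1), "residue"), collapse = "")
    lens <- vapply(all_paths, function(p) length(p$vertices), integer(1))
    strs <- vapply(all_paths, res_of, character(1))
    vstr <- vapply(all_paths, function(p) paste(p$vertices, collapse = ","),
                   character(1))
    all_paths <- all_paths[order(-lens, strs, vstr)]
  }
  attr(all_paths, "overflow") <- overflow
  all_paths
}
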