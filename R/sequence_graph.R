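# Step 2: the sequence graph. A sequence vertex stands for one candidate
# residue and groups 2-4 spectrum vertices into two cleavage-site groups
# (the ions flanking the residue on its two sides). Within a site group the
# ions must be complementary (joined by a vertical-bar spectrum edge);
# across the two groups every ion pair must be joined by a spectrum edge
# labeled with the vertex's residue. Two sequence vertices sharing spectrum
# vertices are joined by a traversable edge when one site group of each can
# merge into a single shared cleavage site, and by a short-circuit edge
# otherwise; short-circuit edges forbid co-occurrence in any tag.

.pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b))

.graph_index <- function(sgraph) {
  ed <- sgraph$edges
  vb_rows <- which(ed$type == "vertical_bar")
  vb_key <- .pair_key(ed$i[vb_rows], ed$j[vb_rows])
  vb_ids <- split(vb_rows, vb_key)
  lab_rows <- which(!is.na(ed$residue))
  lab_key <- paste(.pair_key(ed$i[lab_rows], ed$j[lab_rows]), ed$residue[lab_rows])
  lab_ids <- split(lab_rows, lab_key)
  # vertical-bar partner lists per spectrum vertex, best (lowest error) first
  partners <- list()
  if (length(vb_rows) > 0) {
    pi <- c(ed$i[vb_rows], ed$j[vb_rows])
    po <- c(ed$j[vb_rows], ed$i[vb_rows])
    pe <- c(ed$epsilon[vb_rows], ed$epsilon[vb_rows])
    ord <- order(pi, pe, po)
    partners <- split(po[ord], pi[ord])
  }
  list(vb_ids = vb_ids, lab_ids = lab_ids, partners = partners)
}

#' Build sequence vertices from a spectrum graph
#'
#' Each residue-labeled spectrum edge seeds a candidate vertex with its two
#' endpoints in opposite site groups. The groups are then grown greedily with
#' vertical-bar partners of the endpoints (lowest relative mass error first),
#' accepting a partner only if every cross-group pair keeps a spectrum edge
#' labeled with the seed residue. Identical vertex sets are deduplicated and
#' non-maximal sets (strict subsets of another vertex for the same residue)
#' are removed, so every emitted vertex includes as many consistent spectrum
#' vertices as possible.
#'
#' @param sgraph a [build_spectrum_graph()] result.
#' @return list of sequence vertices; each is a list with `residue`,
#'   `sites` (list of two sorted integer vectors of spectrum-vertex indices)
#'   and `support` (row indices of the supporting spectrum edges).
#' @export
build_sequence_vertices <- function(sgraph) {
  ed <- sgraph$edges
  idx <- .graph_index(sgraph)
  has_lab <- function(a, b, res) !is.null(idx$lab_ids[[paste(.pair_key(a, b), res)]])

  lab_rows <- which(!is.na(ed$residue))
  verts <- list()
  keys <- character(0)
  for (r in lab_rows) {
    i <- ed$i[r]; j <- ed$j[r]; res <- ed$residue[r]
    left <- i; right <- j
    # grow the left site with a complementary partner of i
    for (p in setdiff(idx$partners[[as.character(i)]], c(i, j))) {
      if (has_lab(p, j, res)) { left <- c(left, p); break }
    }
    # grow the right site with a complementary partner of j
    for (q in setdiff(idx$partners[[as.character(j)]], c(i, j, left))) {
      ok <- has_lab(q, i, res) &&
        (length(left) < 2 || has_lab(q, left[2], res))
      if (ok) { right <- c(right, q); break }
    }
    s1 <- sort(left); s2 <- sort(right)
    if (min(s2) < min(s1)) { tmp <- s1; s1 <- s2; s2 <- tmp }
    key <- paste(res, paste(s1, collapse = ","), paste(s2, collapse = ","))
    if (key %in% keys) next
    keys <- c(keys, key)
    verts[[length(verts) + 1L]] <- list(residue = res, sites = list(s1, s2))
  }
  if (length(verts) == 0) return(verts)

  # drop strict subsets of another vertex with the same residue
  is_subset <- function(a, b) all(a %in% b)
  drop <- logical(length(verts))
  for (a in seq_along(verts)) {
    for (b in seq_along(verts)) {
      if (a == b || drop[b]) next
      va <- verts[[a]]; vb <- verts[[b]]
      if (va$residue != vb$residue) next
      straight <- is_subset(va$sites[[1]], vb$sites[[1]]) &&
        is_subset(va$sites[[2]], vb$sites[[2]])
      crossed <- is_subset(va$sites[[1]], vb$sites[[2]]) &&
        is_subset(va$sites[[2]], vb$sites[[1]])
      same <- length(unlist(va$sites)) == length(unlist(vb$sites))
      if ((straight || crossed) && !same) { drop[a] <- TRUE; break }
    }
  }
  verts <- verts[!drop]

  # attach supporting spectrum edges: residue-labeled edges across sites,
  # vertical bars within sites
  for (k in seq_along(verts)) {
    v <- verts[[k]]
    sup <- integer(0)
    for (a in v$sites[[1]]) {
      for (b in v$sites[[2]]) {
        sup <- c(sup, idx$lab_ids[[paste(.pair_key(a, b), v$residue)]])
      }
    }
    for (s in v$sites) {
      if (length(s) == 2) sup <- c(sup, idx$vb_ids[[.pair_key(s[1], s[2])]])
    }
    verts[[k]]$support <- sort(unique(sup))
  }
  verts
}

#' Build sequence edges between sequence vertices
#'
#' Every pair of sequence vertices sharing at least one spectrum vertex gets
#' exactly one edge. The edge is traversable if some orientation merges one
#' site group of each vertex into a single shared cleavage site (union of at
#' most two spectrum vertices which, if two, are vertical-bar partners) while
#' the two remaining site groups stay disjoint from each other and from the
#' shared site; otherwise it is a short-circuit edge.
#'
#' @param vertices output of [build_sequence_vertices()].
#' @param sgraph the originating spectrum graph.
#' @return list with `edges` (data frame `u`, `w`, `kind`) and `orient`
#'   (per-edge matrix of valid orientations; columns are the merged site
#'   index of `u` and of `w`; `NULL` for short-circuit edges).
#' @export
build_sequence_edges <- function(vertices, sgraph) {
  idx <- .graph_index(sgraph)
  has_vb <- function(a, b) !is.null(idx$vb_ids[[.pair_key(a, b)]])
  empty <- list(edges = data.frame(u = integer(0), w = integer(0),
                                   kind = character(0)),
                orient = list())
  if (length(vertices) < 2) return(empty)

  # candidate pairs: vertices sharing a spectrum vertex
  incidence <- list()
  for (k in seq_along(vertices)) {
    for (sv in unlist(vertices[[k]]$sites)) {
      key <- as.character(sv)
      incidence[[key]] <- c(incidence[[key]], k)
    }
  }
  pairs <- unique(do.call(rbind, lapply(incidence, function(ks) {
    ks <- sort(unique(ks))
    if (length(ks) < 2) return(NULL)
    t(utils::combn(ks, 2))
  })))
  if (is.null(pairs) || nrow(pairs) == 0) return(empty)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]

  u <- integer(0); w <- integer(0); kind <- character(0); orient <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    va <- vertices[[a]]; vb <- vertices[[b]]
    om <- matrix(integer(0), ncol = 2)
    for (ga in 1:2) {
      for (gb in 1:2) {
        shared <- sort(unique(c(va$sites[[ga]], vb$sites[[gb]])))
        if (length(shared) > 2) next
        if (length(shared) == 2 && !has_vb(shared[1], shared[2])) next
        oa <- va$sites[[3 - ga]]; ob <- vb$sites[[3 - gb]]
        if (length(intersect(oa, ob)) > 0) next
        if (length(intersect(oa, shared)) > 0) next
        if (length(intersect(ob, shared)) > 0) next
        om <- rbind(om, c(ga, gb))
      }
    }
    u <- c(u, a); w <- c(w, b)
    if (nrow(om) > 0) {
      kind <- c(kind, "traversable")
      orient[[length(kind)]] <- om
    } else {
      kind <- c(kind, "short_circuit")
      orient[length(kind)] <- list(NULL)
    }
  }
  list(edges = data.frame(u = u, w = w, kind = kind), orient = orient)
}

#' Build the full sequence graph of a spectrum
#'
#' @param sgraph a [build_spectrum_graph()] result.
#' @return object of class `sequence_graph`: list with `vertices`, `edges`,
#'   `orient` and the originating `sgraph`.
#' @export
build_sequence_graph <- function(sgraph) {
  vertices <- build_sequence_vertices(sgraph)
  se <- build_sequence_edges(vertices, sgraph)
  structure(list(vertices = vertices, edges = se$edges, orient = se$orient,
                 sgraph = sgraph),
            class = "sequence_graph")
}

#' @export
print.sequence_graph <- function(x, ...) {
  cat(sprintf("sequence graph: %d vertices, %d traversable / %d short-circuit edges\n",
              length(x$vertices), sum(x$edges$kind == "traversable"),
              sum(x$edges$kind == "short_circuit")))
  invisible(x)
}

#' Connected components of a sequence graph
#'
#' Components are maximal subgraphs connected by traversable edges;
#' short-circuit edges play no role in the partition (but still apply to
#' path validity inside and across components). Components are returned
#' largest first.
#'
#' @param graph a [build_sequence_graph()] result.
#' @return list of integer vectors of sequence-vertex indices.
#' @export
sequence_components <- function(graph) {
  n <- length(graph$vertices)
  if (n == 0) return(list())
  trav <- graph$edges[graph$edges$kind == "traversable", , drop = FALSE]
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (nrow(trav) > 0) {
    g <- igraph::add_edges(g, rbind(trav$u, trav$w))
  }
  memb <- igraph::components(g)$membership
  comps <- split(seq_len(n), memb)
  comps <- comps[order(-lengths(comps), vapply(comps, min, integer(1)))]
  unname(comps)
}

#' Dump a sequence graph as tab-separated vertex and edge tables
#'
#' Vertices are annotated with their residue and the masses of the included
#' spectrum vertices per site group; edges with their kind.
#'
#' @param graph a `sequence_graph`.
#' @param vertex_path,edge_path output file paths.
#' @export
write_sequence_graph <- function(graph, vertex_path, edge_path) {
  m <- graph$sgraph$spectrum$ions$mass
  vd <- data.frame(
    vertex = seq_along(graph$vertices),
    residue = vapply(graph$vertices, `[[`, character(1), "residue"),
    site1 = vapply(graph$vertices, function(v)
      paste(sprintf("%.5f", m[v$sites[[1]]]), collapse = ","), character(1)),
    site2 = vapply(graph$vertices, function(v)
      paste(sprintf("%.5f", m[v$sites[[2]]]), collapse = ","), character(1))
  )
  utils::write.table(vd, vertex_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(graph$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}
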