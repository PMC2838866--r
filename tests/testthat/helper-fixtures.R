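# Shared fixture builders. Everything is generated in code; spectra are
# exact unless a test perturbs them.

# zero-error spectrum with complete y/b ladders of a peptide
ladder_spectrum <- function(peptide, scan = 1L, charge = 2L) {
  fr <- theoretical_fragments(peptide)
  p <- peptide_neutral_mass(peptide)
  ions <- data.frame(mass = sort(unique(c(fr$b, fr$y))), abundance = 50)
  prepare_spectrum(list(scan = scan, charge = charge,
                        mhplus = p + proton_mass), ions)
}

# spectrum from a bare neutral-mass list (anchor added by prepare_spectrum)
mass_spectrum <- function(masses, p, scan = 1L, charge = 2L) {
  ions <- data.frame(mass = sort(masses),
                     abundance = rep(50, length(masses)))
  prepare_spectrum(list(scan = scan, charge = charge,
                        mhplus = p + proton_mass), ions)
}

# abstract sequence graph whose traversable edges allow every site-merge
# orientation; used to exercise the path rules in isolation
abstract_sequence_graph <- function(n, traversable = NULL,
                                    short_circuit = NULL, residues = NULL) {
  if (is.null(residues)) residues <- rep(LETTERS[1:19], length.out = n)
  all_orient <- matrix(c(1L, 1L, 1L, 2L, 2L, 1L, 2L, 2L), ncol = 2,
                       byrow = TRUE)
  vertices <- lapply(seq_len(n), function(k) {
    list(residue = residues[k], sites = list(2L * k - 1L, 2L * k),
         support = integer(0))
  })
  u <- integer(0); w <- integer(0); kind <- character(0); orient <- list()
  if (!is.null(traversable)) {
    for (r in seq_len(nrow(traversable))) {
      u <- c(u, traversable[r, 1]); w <- c(w, traversable[r, 2])
      kind <- c(kind, "traversable")
      orient[[length(kind)]] <- all_orient
    }
  }
  if (!is.null(short_circuit)) {
    for (r in seq_len(nrow(short_circuit))) {
      u <- c(u, short_circuit[r, 1]); w <- c(w, short_circuit[r, 2])
      kind <- c(kind, "short_circuit")
      orient[length(kind)] <- list(NULL)
    }
  }
  structure(list(vertices = vertices,
                 edges = data.frame(u = u, w = w, kind = kind),
                 orient = orient, sgraph = NULL),
            class = "sequence_graph")
}

# sparse by default: real sequence graphs are near-linear chains with a few
# branches, and dense random graphs make brute-force path counts explode
random_sequence_graph <- function(n, p_trav = min(0.6, 2.5 / n),
                                  p_sc = min(0.25, 0.9 / n)) {
  trav <- NULL; sc <- NULL
  if (n >= 2) {
    for (pair in utils::combn(n, 2, simplify = FALSE)) {
      r <- stats::runif(1)
      if (r < p_trav) trav <- rbind(trav, pair)
      else if (r < p_trav + p_sc) sc <- rbind(sc, pair)
    }
  }
  abstract_sequence_graph(n, trav, sc)
}

# canonical (reversal-invariant) keys for a path list
path_keys <- function(paths) {
  if (length(paths) == 0) return(character(0))
  sort(unique(vapply(paths, function(p) {
    f <- paste(p$vertices, collapse = ",")
    b <- paste(rev(p$vertices), collapse = ",")
    min(f, b)
  }, character(1))))
}

# independent brute-force oracle for valid-path enumeration: igraph's
# all_simple_paths post-filtered by the short-circuit rule
oracle_path_keys <- function(graph) {
  n <- length(graph$vertices)
  trav <- graph$edges[graph$edges$kind == "traversable", , drop = FALSE]
  sc <- graph$edges[graph$edges$kind == "short_circuit", , drop = FALSE]
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(trav) > 0) g <- igraph::add_edges(g, rbind(trav$u, trav$w))
  scmat <- matrix(FALSE, n, n)
  if (nrow(sc) > 0) {
    scmat[cbind(sc$u, sc$w)] <- TRUE
    scmat[cbind(sc$w, sc$u)] <- TRUE
  }
  keys <- as.character(seq_len(n))
  for (u in seq_len(n)) {
    for (w in seq_len(n)) {
      if (u >= w) next
      sps <- suppressWarnings(igraph::all_simple_paths(g, from = u, to = w))
      for (sp in sps) {
        vs <- as.integer(sp)
        ok <- TRUE
        if (length(vs) > 2) {
          prs <- utils::combn(vs, 2)
          ok <- !any(scmat[cbind(prs[1, ], prs[2, ])])
        } else if (length(vs) == 2) {
          ok <- !scmat[vs[1], vs[2]]
        }
        if (ok) {
          keys <- c(keys, min(paste(vs, collapse = ","),
                              paste(rev(vs), collapse = ",")))
        }
      }
    }
  }
  sort(unique(keys))
}

# invariant checks for sequence vertices against their spectrum graph
expect_valid_vertices <- function(qg) {
  ed <- qg$sgraph$edges
  has_edge <- function(a, b, type = NULL, res = NULL) {
    sel <- ed$i == min(a, b) & ed$j == max(a, b)
    if (!is.null(type)) sel <- sel & ed$type == type
    if (!is.null(res)) sel <- sel & !is.na(ed$residue) & ed$residue == res
    any(sel)
  }
  for (v in qg$vertices) {
    expect_gte(length(v$sites[[1]]), 1)
    expect_gte(length(v$sites[[2]]), 1)
    expect_lte(length(v$sites[[1]]) + length(v$sites[[2]]), 4)
    expect_length(intersect(v$sites[[1]], v$sites[[2]]), 0)
    for (s in v$sites) {
      if (length(s) == 2) expect_true(has_edge(s[1], s[2], "vertical_bar"))
    }
    for (a in v$sites[[1]]) {
      for (b in v$sites[[2]]) {
        expect_true(has_edge(a, b, res = v$residue))
      }
    }
  }
  invisible(qg)
}
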