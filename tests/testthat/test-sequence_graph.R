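test_that("a full four-ion interconnection pattern becomes one sequence vertex", {
  m <- residue_masses()
  p <- 1000
  b0 <- 300; b1 <- b0 + m[["A"]]
  sp <- mass_spectrum(c(b0, b1, p - b0, p - b1), p = p)
  qg <- build_sequence_graph(build_spectrum_graph(sp))
  expect_length(qg$vertices, 1)
  v <- qg$vertices[[1]]
  expect_equal(v$residue, "A")
  expect_equal(lengths(v$sites), c(2L, 2L))
  expect_length(v$support, 6)
  expect_valid_vertices(qg)
})

test_that("a lone arrow edge yields a two-ion vertex; a vertical bar alone none", {
  m <- residue_masses()
  sp <- mass_spectrum(c(300, 300 + m[["A"]]), p = 1500)
  qg <- build_sequence_graph(build_spectrum_graph(sp))
  expect_length(qg$vertices, 1)
  expect_equal(lengths(qg$vertices[[1]]$sites), c(1L, 1L))
  expect_length(qg$vertices[[1]]$support, 1)

  sp2 <- mass_spectrum(c(400, 600), p = 1000)
  qg2 <- build_sequence_graph(build_spectrum_graph(sp2))
  expect_length(qg2$vertices, 0)
})

test_that("adjacent residues with full ion support share a traversable edge", {
  m <- residue_masses()
  p <- 1200
  c0 <- 300; c1 <- c0 + m[["A"]]; c2 <- c1 + m[["P"]]
  ions <- c(c0, c1, c2, p - c0, p - c1, p - c2)
  qg <- build_sequence_graph(build_spectrum_graph(mass_spectrum(ions, p = p)))
  expect_length(qg$vertices, 2)
  expect_setequal(vapply(qg$vertices, `[[`, character(1), "residue"),
                  c("A", "P"))
  expect_equal(nrow(qg$edges), 1)
  expect_equal(qg$edges$kind, "traversable")
  expect_valid_vertices(qg)

  # the two-vertex path covers the union of both support sets: 4 + 4
  # residue-labeled edges and 3 distinct vertical bars (one shared)
  paths <- enumerate_all_paths(qg)
  two <- paths[[which(vapply(paths, function(p) length(p$vertices),
                             integer(1)) == 2)[1]]]
  expect_length(covered_spectrum_edges(two, qg), 11)
  expect_equal(score_path(two, qg), 11, tolerance = 1e-9)
})

test_that("inconsistently overlapping site groups give a short-circuit edge", {
  # u spans sites {1,2}|{3}; w spans {1,4}|{5}; the shared ion 1 has
  # different vertical-bar partners in the two vertices, so no orientation
  # can merge a single cleavage site
  sg <- structure(list(edges = data.frame(
    i = c(1L, 1L), j = c(2L, 4L), type = "vertical_bar",
    residue = NA_character_, epsilon = 0, weight = 1)), class = "spectrum_graph")
  vertices <- list(
    list(residue = "A", sites = list(c(1L, 2L), 3L), support = integer(0)),
    list(residue = "G", sites = list(c(1L, 4L), 5L), support = integer(0))
  )
  se <- build_sequence_edges(vertices, sg)
  expect_equal(nrow(se$edges), 1)
  expect_equal(se$edges$kind, "short_circuit")

  # vertices sharing no spectrum vertex get no edge at all
  vertices2 <- list(
    list(residue = "A", sites = list(1L, 2L), support = integer(0)),
    list(residue = "G", sites = list(3L, 4L), support = integer(0))
  )
  expect_equal(nrow(build_sequence_edges(vertices2, sg)$edges), 0)
})

test_that("components partition by traversable edges only, largest first", {
  g <- abstract_sequence_graph(5,
                               traversable = rbind(c(1, 2), c(2, 3)),
                               short_circuit = rbind(c(1, 4)))
  comps <- sequence_components(g)
  expect_length(comps, 3)
  expect_equal(comps[[1]], c(1L, 2L, 3L))
  expect_setequal(unlist(comps[2:3]), c(4L, 5L))

  empty <- abstract_sequence_graph(0)
  expect_length(sequence_components(empty), 0)
})

test_that("a zero-error complete ladder yields one maximal vertex per internal residue", {
  pep <- "SPVTMEK"
  sp <- ladder_spectrum(pep)
  qg <- build_sequence_graph(build_spectrum_graph(sp))
  expect_valid_vertices(qg)
  fr <- theoretical_fragments(pep)
  p <- peptide_neutral_mass(pep)
  masses <- sp$ions$mass
  aa <- strsplit(pep, "")[[1]]
  n <- length(aa)
  chain <- integer(0)
  for (k in 2:(n - 1)) {
    # internal residue k is flanked by the full pairs at sites k-1 and k
    want <- sort(c(which(abs(masses - fr$b[k - 1]) < 1e-6),
                   which(abs(masses - (p - fr$b[k - 1])) < 1e-6),
                   which(abs(masses - fr$b[k]) < 1e-6),
                   which(abs(masses - (p - fr$b[k])) < 1e-6)))
    hits <- which(vapply(qg$vertices, function(v) {
      v$residue == aa[k] && setequal(unlist(v$sites), want)
    }, logical(1)))
    expect_length(hits, 1)
    expect_length(qg$vertices[[hits]]$support, 6)
    chain <- c(chain, hits)
  }
  # consecutive internal residues are linked by traversable edges, with no
  # short-circuit edge anywhere among them
  key <- paste(pmin(qg$edges$u, qg$edges$w), pmax(qg$edges$u, qg$edges$w))
  for (t in seq_len(length(chain) - 1)) {
    row <- match(paste(min(chain[t], chain[t + 1]),
                       max(chain[t], chain[t + 1])), key)
    expect_equal(qg$edges$kind[row], "traversable")
  }
  prs <- utils::combn(chain, 2)
  sc <- qg$edges$kind == "short_circuit"
  expect_false(any(key[sc] %in% paste(pmin(prs[1, ], prs[2, ]),
                                      pmax(prs[1, ], prs[2, ]))))
})

test_that("sequence vertices are maximal: no further ion can be absorbed", {
  pep <- "SPVTMEK"
  sp <- ladder_spectrum(pep)
  sg <- build_spectrum_graph(sp)
  qg <- build_sequence_graph(sg)
  ed <- sg$edges
  has_edge <- function(a, b, type = NULL, res = NULL) {
    sel <- ed$i == min(a, b) & ed$j == max(a, b)
    if (!is.null(type)) sel <- sel & ed$type == type
    if (!is.null(res)) sel <- sel & !is.na(ed$residue) & ed$residue == res
    any(sel)
  }
  n_ions <- nrow(sp$ions)
  for (v in qg$vertices) {
    used <- unlist(v$sites)
    for (x in setdiff(seq_len(n_ions), used)) {
      for (side in 1:2) {
        if (length(v$sites[[side]]) >= 2) next
        other <- v$sites[[3 - side]]
        ok <- all(vapply(v$sites[[side]], function(s)
          has_edge(x, s, "vertical_bar"), logical(1))) &&
          all(vapply(other, function(o)
            has_edge(x, o, res = v$residue), logical(1)))
        expect_false(ok)
      }
    }
  }
})
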