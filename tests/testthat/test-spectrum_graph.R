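test_that("pair classification reproduces the four edge conditions", {
  m <- residue_masses()
  hits <- classify_pair(200.0, 200.0 + m[["A"]], 1500, 0.01)
  expect_equal(hits$type, "arrow")
  expect_equal(hits$residue, "A")
  expect_lt(hits$epsilon, 1e-9)

  vb <- classify_pair(400.0, 600.0, 1000.0, 0.01)
  expect_equal(vb$type, "vertical_bar")
  expect_true(is.na(vb$residue))
  expect_equal(vb$epsilon, 0)

  # no residue fits any condition for this pair
  expect_equal(nrow(classify_pair(300.0, 571.96289, 1000.0, 0.01)), 0)

  # a mass gap equal to M(Q) is a single Q arrow, not a two-residue edge
  q <- classify_pair(150.0, 150.0 + m[["Q"]], 1500, 0.01)
  expect_equal(q$type, "arrow")
  expect_equal(q$residue, "Q")
  expect_equal(nrow(q), 1)
})

test_that("pair classification agrees with an independent brute-force check", {
  brute <- function(mi, mj, p, delta, masses) {
    rows <- list()
    for (res in names(masses)) {
      for (cond in c("arrow", "forward_slash", "backslash")) {
        eps <- switch(cond,
                      arrow = abs((mj - mi) - masses[[res]]),
                      forward_slash = abs(p - (mj + mi) - masses[[res]]),
                      backslash = abs((mj + mi) - p - masses[[res]]))
        if (eps < delta) {
          rows[[length(rows) + 1L]] <- data.frame(type = cond, residue = res,
                                                  epsilon = eps)
        }
      }
    }
    eps <- abs((mj + mi) - p)
    if (eps < delta) {
      rows[[length(rows) + 1L]] <- data.frame(type = "vertical_bar",
                                              residue = NA_character_,
                                              epsilon = eps)
    }
    if (length(rows) == 0) {
      return(data.frame(type = character(0), residue = character(0),
                        epsilon = numeric(0)))
    }
    do.call(rbind, rows)
  }
  canon <- function(df) {
    df <- df[order(df$type, df$residue, df$epsilon), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  masses <- residue_masses()
  set.seed(401)
  for (k in 1:300) {
    p <- runif(1, 600, 2500)
    mi <- runif(1, 0, p / 2)
    mj <- mi + runif(1, 1e-3, p - mi)
    # bias some pairs onto exact conditions so hits actually occur
    if (k %% 3 == 0) mj <- mi + sample(masses, 1) + rnorm(1, 0, 0.005)
    if (k %% 5 == 0) mj <- p - mi + rnorm(1, 0, 0.005)
    if (mj <= mi) next
    got <- canon(classify_pair(mi, mj, p, 0.01, masses))
    want <- canon(brute(mi, mj, p, 0.01, masses))
    expect_equal(got, want)
  }
})

test_that("edge weights follow the folded-normal standardization", {
  expect_equal(edge_weight(0, 0.01), 1.0)
  expect_equal(edge_weight(0.01, 0.01), 2 * (1 - pnorm(2)), tolerance = 1e-12)
  expect_equal(round(edge_weight(0.01, 0.01), 2), 0.05)
  expect_equal(edge_weight(0.005, 0.01), 2 * (1 - pnorm(1)), tolerance = 1e-12)
  eps <- seq(0, 0.01, length.out = 50)
  w <- edge_weight(eps, 0.01)
  expect_true(all(diff(w) < 0))
  expect_true(all(w >= 2 * (1 - pnorm(2)) - 1e-12 & w <= 1))
  expect_error(edge_weight(-1e-6, 0.01), "epsilon")
  expect_error(edge_weight(0.02, 0.01), "epsilon")
})

test_that("the spectrum graph of a complete ladder shows the six-edge pattern", {
  pep <- "GAS"
  sp <- ladder_spectrum(pep)
  g <- build_spectrum_graph(sp)
  m <- residue_masses()
  masses <- sp$ions$mass
  idx_of <- function(x) which(abs(masses - x) < 1e-6)
  fr <- theoretical_fragments(pep)
  has_edge <- function(a, b, type, res = NULL) {
    i <- idx_of(min(a, b)); j <- idx_of(max(a, b))
    sel <- g$edges$i == i & g$edges$j == j & g$edges$type == type
    if (!is.null(res)) sel <- sel & !is.na(g$edges$residue) & g$edges$residue == res
    any(sel)
  }
  # b-ladder and y-ladder arrows (anchor plays the role of b0)
  expect_true(has_edge(0, fr$b[1], "arrow", "G"))
  expect_true(has_edge(fr$b[1], fr$b[2], "arrow", "A"))
  expect_true(has_edge(fr$y[1], fr$y[2], "arrow", "A"))
  # complementary verticals at the two internal cleavage sites
  expect_true(has_edge(fr$b[1], fr$y[2], "vertical_bar"))
  expect_true(has_edge(fr$b[2], fr$y[1], "vertical_bar"))
  # slashes across the series for the internal residue A
  expect_true(has_edge(fr$b[1], fr$y[1], "forward_slash", "A"))
  expect_true(has_edge(fr$b[2], fr$y[2], "backslash", "A"))
  # anchor participates in the complementary conditions too
  expect_true(has_edge(0, fr$y[2], "forward_slash", "G"))

  # every stored weight equals the standardization of its epsilon
  expect_equal(g$edges$weight, edge_weight(g$edges$epsilon, g$delta))
})

test_that("degenerate and coincidental inputs are handled arithmetically", {
  anchor_only <- mass_spectrum(numeric(0), p = 900)
  g <- build_spectrum_graph(anchor_only)
  expect_equal(nrow(g$edges), 0)

  # a false edge from two unrelated masses 71.041 apart is legal
  g2 <- build_spectrum_graph(mass_spectrum(c(200.0, 271.041), p = 1500))
  arr <- g2$edges[g2$edges$type == "arrow", ]
  expect_equal(arr$residue, "A")
  expect_equal(arr$epsilon, 271.041 - 200 - residue_masses()[["A"]],
               tolerance = 1e-9)
})
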