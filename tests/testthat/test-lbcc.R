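test_that("IDC sums in-complex PPI degrees with the 0.001 floor", {
  g <- toy_graph(rbind(c("v", "u"), c("v", "w"), c("u", "x"), c("x", "y")))
  # v in one complex with both its partners
  expect_equal(idc(g, list(c1 = c("v", "u", "w")))[["v"]], 2)
  # two complexes: in-complex degrees add up
  cx <- list(c1 = c("v", "u", "w"), c2 = c("v", "u"))
  expect_equal(idc(g, cx)[["v"]], 3)
  # protein in no complex -> floor
  expect_equal(idc(g, cx)[["y"]], 0.001)
  # member with no in-complex edge -> floored too
  expect_equal(idc(g, list(c1 = c("w", "y")))[["w"]], 0.001)
  # members absent from the network contribute nothing
  expect_equal(idc(g, list(c1 = c("v", "u", "GHOST")))[["v"]], 1)
})

test_that("IDC additivity under complex splitting and duplication", {
  set.seed(111)
  for (trial in 1:10) {
    g <- random_named_graph(10, 0.4)
    ids <- igraph::V(g)$name
    members <- sample(ids, 6)
    whole <- list(c1 = members)
    halves <- list(c1 = members[1:3], c2 = members[4:6])
    iw <- idc(g, whole)
    ih <- idc(g, halves)
    # splitting partitions the member set, so in-complex edges can only be lost
    expect_true(all(ih[members] <= iw[members] + 1e-12))
    # exact duplication doubles every member's contribution
    dup <- idc(g, list(c1 = members, c2 = members))
    raw <- iw[members]
    raw[raw == 0.001] <- 0 # undo floor before doubling
    expected <- 2 * raw
    expected[expected == 0] <- 0.001
    expect_equal(dup[members], expected, tolerance = 1e-12)
  }
})

test_that("weight validation enforces the 0-10 range and positive floor", {
  expect_error(lbcc_weights(a = -1), "\\[0, 10\\]")
  expect_error(lbcc_weights(b = 11), "\\[0, 10\\]")
  expect_error(lbcc_weights(floor_value = 0), "floor_value")
  expect_error(lbcc_weights(log_base = 1), "log_base")
  w <- lbcc_weights()
  expect_equal(c(w$a, w$b, w$c, w$d), c(1, 4, 3, 1))
  expect_equal(w$floor_value, 0.001)
})

test_that("lbcc_combine evaluates the weighted log sum", {
  ids <- c("p1", "p2", "p3")
  ones <- stats::setNames(rep(1, 3), ids)
  expect_equal(unname(lbcc_combine(ones, ones, ones, ones)), rep(0, 3))

  es <- stats::setNames(rep(exp(1), 3), ids)
  expect_equal(unname(lbcc_combine(es, es, es, es)), rep(9, 3))

  # flooring path: BC = 0 contributes d * log(0.001)
  bc0 <- stats::setNames(c(0, 1, 1), ids)
  w <- lbcc_weights(a = 0, b = 0, c = 0, d = 1)
  out <- lbcc_combine(ones, ones, ones, bc0, w)
  expect_equal(out[["p1"]], -log(1000), tolerance = 1e-12)
  expect_equal(out[["p2"]], 0)

  expect_error(lbcc_combine(ones, ones, ones, ones[1:2]), "protein set")
  neg <- stats::setNames(c(-1, 1, 1), ids)
  expect_error(lbcc_combine(ones, ones, neg, ones), "negative")
})

test_that("ranking is descending with identifier tie-break", {
  expect_identical(rank_proteins(c(A = 2, B = 1, C = 3))$protein,
                   c("C", "A", "B"))
  expect_identical(rank_proteins(c(B = 1, A = 1))$protein, c("A", "B"))
  expect_identical(nrow(rank_proteins(stats::setNames(numeric(0),
                                                      character(0)))), 0L)
})

test_that("LBCC ranking is invariant to the log base", {
  set.seed(222)
  for (trial in 1:8) {
    fix <- generate_fixture(fixture_spec(n_modules = 3, module_size = 8,
                                         n_background = 15,
                                         n_complexes = 4, seed = 5000 + trial))
    base_e <- lbcc_score(fix$network, fix$complexes)
    for (b in c(2, 10)) {
      alt <- lbcc_score(fix$network, fix$complexes,
                        lbcc_weights(log_base = b))
      expect_identical(rank_proteins(alt)$protein,
                       rank_proteins(base_e)$protein)
      # and the scores differ only by the constant 1/log(b)
      expect_equal(alt, base_e / log(b), tolerance = 1e-12)
    }
  }
})

test_that("raising one factor never lowers a node's LBCC score", {
  set.seed(333)
  ids <- sprintf("p%d", 1:6)
  mk <- function() stats::setNames(stats::runif(6, 0, 5), ids)
  for (trial in 1:10) {
    d1 <- mk(); d2 <- mk(); ic <- mk(); bc <- mk()
    w <- lbcc_weights(a = stats::runif(1, 0.1, 10),
                      b = stats::runif(1, 0.1, 10),
                      c = stats::runif(1, 0.1, 10),
                      d = stats::runif(1, 0.1, 10))
    before <- lbcc_combine(d1, d2, ic, bc, w)
    pick <- sample(ids, 1)
    which_vec <- sample(4, 1)
    bump <- list(d1, d2, ic, bc)
    bump[[which_vec]][pick] <- bump[[which_vec]][pick] + stats::runif(1, 0, 3)
    after <- lbcc_combine(bump[[1]], bump[[2]], bump[[3]], bump[[4]], w)
    expect_gte(after[[pick]], before[[pick]] - 1e-12)
  }
})

test_that("with weights (0,0,0,1) LBCC ranks exactly like BC", {
  set.seed(444)
  for (trial in 1:5) {
    g <- random_named_graph(12, 0.35)
    bc <- betweenness_centrality(g)
    # restrict to graphs without tied/floored BC values, where the
    # correspondence is exact
    if (anyDuplicated(pmax(bc, 0.001))) next
    s <- lbcc_combine(den1(g), den2(g),
                      idc(g, list(c1 = igraph::V(g)$name[1:4])), bc,
                      lbcc_weights(a = 0, b = 0, c = 0, d = 1))
    expect_identical(rank_proteins(s)$protein, rank_proteins(bc)$protein)
  }
})

test_that("lbcc_score wires the four ingredients together", {
  g <- toy_graph(rbind(c("A", "B"), c("B", "C"), c("C", "A"), c("C", "D")))
  cx <- list(c1 = c("A", "B", "C"))
  manual <- lbcc_combine(den1(g), den2(g), idc(g, cx),
                         betweenness_centrality(g))
  expect_equal(lbcc_score(g, cx), manual)
})
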