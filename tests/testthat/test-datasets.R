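# Negative-pair dataset construction and pair annotation helpers.

test_that("random negative sampling avoids native edges and is uniform", {
  g <- make_network(40, 4, seed = 21)
  neg <- sample_negative_random(g, 50, seed = 22)
  expect_equal(nrow(neg), 50)
  eid <- igraph::get_edge_ids(g, rbind(match(neg$id_a, igraph::V(g)$name),
                                       match(neg$id_b, igraph::V(g)$name)))
  expect_true(all(eid == 0))
  expect_false(any(neg$id_a == neg$id_b))
  expect_false(any(duplicated(structprec:::pair_key(neg$id_a, neg$id_b))))
  expect_identical(neg, sample_negative_random(g, 50, seed = 22))
  # uniformity over non-edges of a 10-node graph
  g10 <- igraph::make_ring(10)
  igraph::V(g10)$name <- letters[1:10]
  nonedges <- choose(10, 2) - 10
  draws <- unlist(lapply(1:2500, function(i) {
    s <- sample_negative_random(g10, 4, seed = 1000 + i)
    structprec:::pair_key(s$id_a, s$id_b)
  }))
  counts <- table(draws)
  expect_equal(length(counts), nonedges)
  p <- chisq.test(as.vector(counts))$p.value
  expect_gt(p, 0.01)
  expect_error(sample_negative_random(g10, nonedges + 1, seed = 1), "non-edges")
})

test_that("balanced sampling preserves the degree multiset when feasible", {
  # 6-cycle: the complement contains a 2-regular set (two triangles)
  g6 <- igraph::make_ring(6)
  igraph::V(g6)$name <- letters[1:6]
  neg <- sample_negative_balanced(g6, seed = 23)
  degn <- table(factor(c(neg$id_a, neg$id_b), levels = letters[1:6]))
  expect_true(all(degn == 2))
  eid <- igraph::get_edge_ids(g6, rbind(match(neg$id_a, letters[1:6]),
                                        match(neg$id_b, letters[1:6])))
  expect_true(all(eid == 0))
  # a heavier graph (hubs well below half the node count, so an exact
  # degree-preserving non-edge set exists)
  g <- make_network(80, 4, seed = 24)
  negb <- sample_negative_balanced(g, seed = 25)
  d1 <- sort(igraph::degree(g))
  d2 <- sort(table(factor(c(negb$id_a, negb$id_b),
                          levels = igraph::V(g)$name)))
  expect_equal(as.integer(d2), as.integer(d1))
})

test_that("the 4-cycle has no exact balanced set; partial mode forces the diagonals", {
  g4 <- igraph::make_ring(4)
  igraph::V(g4)$name <- as.character(1:4)
  expect_error(sample_negative_balanced(g4, seed = 26, max_restarts = 50),
               "no feasible")
  part <- sample_negative_balanced(g4, seed = 26, allow_partial = TRUE)
  keys <- sort(structprec:::pair_key(part$id_a, part$id_b))
  expect_equal(keys, sort(structprec:::pair_key(c("1", "2"), c("3", "4"))))
})

test_that("the false-negative-reduction filter is strict at the cutoff", {
  p12 <- igraph::make_graph(rbind(1:11, 2:12), n = 12, directed = FALSE)
  igraph::V(p12)$name <- sprintf("n%02d", 1:12)
  pairs <- data.frame(id_a = c("n01", "n01", "n01"),
                      id_b = c("n12", "n11", "n02"),
                      stringsAsFactors = FALSE)
  kept <- filter_fnr(pairs, p12, min_path = 10)
  # distance 11 kept; distance 10 removed (strictly greater); distance 1
  # removed
  expect_equal(kept$id_b, "n12")
  # disconnected endpoints (infinite distance) are kept
  g2 <- igraph::add_vertices(p12, 1, name = "iso")
  kept2 <- filter_fnr(data.frame(id_a = "n01", id_b = "iso"), g2, 10)
  expect_equal(nrow(kept2), 1L)
  # absent endpoints are dropped with a warning
  expect_warning(
    none <- filter_fnr(data.frame(id_a = "n01", id_b = "gone"), p12),
    "absent")
  expect_equal(nrow(none), 0L)
  # idempotence
  expect_equal(filter_fnr(kept, p12, 10), kept)
})

test_that("non-colocalized filtering drops multi-localized proteins", {
  loc <- list(a = "nucleus", b = "cytoplasm", c = "nucleus",
              d = c("nucleus", "mitochondrion"))
  pairs <- data.frame(id_a = c("a", "a", "d", "a"),
                      id_b = c("b", "c", "b", "zz"),
                      stringsAsFactors = FALSE)
  kept <- filter_noncolocalized(pairs, loc)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$id_a, "a"); expect_equal(kept$id_b, "b")
  expect_equal(filter_noncolocalized(kept, loc), kept)
})

test_that("direct-method filtering keeps the allowed evidence", {
  pairs <- data.frame(id_a = c("a", "b", "c"), id_b = c("x", "y", "z"),
                      stringsAsFactors = FALSE)
  methods <- list(c("Two-hybrid"), c("Affinity Capture-MS"), character(0))
  kept <- filter_direct(pairs, methods)
  expect_equal(kept$id_a, "a")
})

test_that("pair abundance is the minimum of the two classes", {
  cls <- c(p1 = "high", p2 = "low", p3 = "medium", p4 = "high")
  expect_equal(pair_abundance(c("p1", "p2"), cls), "low")
  expect_equal(pair_abundance(c("p3", "p4"), cls), "medium")
  expect_equal(pair_abundance(c("p3", "p3"), cls), "medium")
  expect_equal(pair_abundance(c("p1", "nope"), cls), "unknown")
  df <- data.frame(id_a = c("p1", "p3"), id_b = c("p2", "p4"))
  expect_equal(pair_abundance(df, cls), c("low", "medium"))
})

test_that("sampled outputs never contain self or duplicate pairs", {
  g <- make_network(30, 4, seed = 27)
  for (s in 1:3) {
    r <- sample_negative_random(g, 40, seed = s)
    b <- sample_negative_balanced(g, seed = s, allow_partial = TRUE)
    for (df in list(r, b)) {
      expect_false(any(df$id_a == df$id_b))
      expect_false(any(duplicated(structprec:::pair_key(df$id_a, df$id_b))))
    }
  }
})
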