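# Edge betweenness, extra-edge centrality and bottleneck enrichment.

path_graph <- function(n) {
  igraph::make_graph(rbind(1:(n - 1), 2:n), n = n, directed = FALSE)
}

test_that("edge betweenness matches hand enumeration on small motifs", {
  p3 <- path_graph(3)
  eb <- edge_betweenness(p3)
  expect_equal(eb$betweenness, c(2, 2))
  star4 <- igraph::make_star(4, mode = "undirected", center = 1)
  ebs <- edge_betweenness(star4)
  expect_equal(ebs$betweenness, rep(3, 3))
})

test_that("edge betweenness matches the all-pairs BFS oracle", {
  set.seed(201)
  for (rep in 1:6) {
    n <- sample(6:12, 1)
    g <- igraph::sample_gnp(n, 0.4)
    if (igraph::ecount(g) == 0) next
    expect_equal(edge_betweenness(g)$betweenness, bfs_edge_betweenness(g),
                 tolerance = 1e-9)
  }
})

test_that("betweenness credit sums to the number of connected pairs", {
  set.seed(202)
  for (rep in 1:4) {
    g <- igraph::sample_gnp(10, 0.35)
    if (igraph::ecount(g) == 0) next
    comp <- igraph::components(g)
    pairs_connected <- sum(choose(comp$csize, 2))
    # each connected pair spreads one unit of credit along one shortest
    # path of length d: total credit = sum over pairs of d
    d <- igraph::distances(g)
    total_credit <- sum(d[upper.tri(d)][is.finite(d[upper.tri(d)])])
    expect_equal(sum(edge_betweenness(g)$betweenness), total_credit)
    expect_gte(total_credit, pairs_connected)
  }
})

test_that("largest connected component selection and ties", {
  g <- igraph::make_graph(c("a", "b", "b", "c", "c", "a",  # triangle
                            "x", "y"), directed = FALSE)
  lcc <- largest_connected_component(g)
  expect_setequal(igraph::V(lcc)$name, c("a", "b", "c"))
  conn <- make_network(30, 4, seed = 8)
  lcc2 <- largest_connected_component(conn)
  expect_equal(igraph::vcount(lcc2),
               max(igraph::components(conn)$csize))
  # sizes match a union-find oracle on random graphs
  set.seed(203)
  for (rep in 1:4) {
    gr <- igraph::sample_gnp(14, 0.12)
    expect_equal(igraph::vcount(largest_connected_component(gr)),
                 uf_component_sizes(gr)[1])
  }
  expect_error(largest_connected_component(igraph::make_empty_graph(0,
    directed = FALSE)), "empty")
})

test_that("extra-edge betweenness equals recomputation on the augmented graph", {
  g <- make_network(40, 4, seed = 9)
  nm <- igraph::V(g)$name
  cand <- NULL
  for (i in seq_along(nm)) {
    for (j in seq_along(nm)) {
      if (i < j && !igraph::are_adjacent(g, nm[i], nm[j])) {
        cand <- c(nm[i], nm[j]); break
      }
    }
    if (!is.null(cand)) break
  }
  v <- extra_edge_betweenness(g, cand)
  g2 <- igraph::add_edges(g, cand)
  eb2 <- igraph::edge_betweenness(g2, directed = FALSE)
  expect_equal(v, eb2[igraph::ecount(g2)])
  expect_error(extra_edge_betweenness(g, c(nm[1], "ZZZ")), "present")
  e1 <- igraph::as_edgelist(g)[1, ]
  expect_error(extra_edge_betweenness(g, e1), "already present")
})

test_that("path chords carry the centrality that enumeration predicts", {
  n <- 8
  p <- path_graph(n)
  igraph::V(p)$name <- letters[1:n]
  # endpoint chord closes the path into an 8-ring: by symmetry every ring
  # edge carries (8*1 + 8*2 + 8*3 + 4*4) / 8 = 8 units of credit
  expect_equal(extra_edge_betweenness(p, c("a", "h")), 8)
  # a short interior chord (c, e) is crossed by every pair spanning the
  # c..e segment: {a,b,c} x {e,f,g,h} = 12 unique shortest paths
  expect_equal(extra_edge_betweenness(p, c("c", "e")), 12)
  # a chord parallel to a triangle's remaining path carries at least its
  # own endpoint pair
  tri <- igraph::make_graph(c("u", "v", "v", "w"), directed = FALSE)
  expect_gte(extra_edge_betweenness(tri, c("u", "w")), 1)
})

test_that("bottleneck log-odds follow the declared definition", {
  g <- make_network(60, 4, seed = 10)
  neg <- sample_negative_random(g, 30, seed = 11)
  neg$category <- rep(c("one", "two"), 15)
  enr <- bottleneck_enrichment(g, neg, top_fraction = 0.10)
  expect_setequal(enr$category, c("one", "two"))
  expect_true(all(enr$n_bottlenecks <= enr$n_edges))
  expect_equal(enr$log_odds,
               log2(enr$observed_fraction / enr$expected_fraction))
  calls <- attr(enr, "calls")
  expect_equal(nrow(calls), 30)
  # single category: chi-squared undefined and flagged
  neg1 <- neg; neg1$category <- "only"
  expect_warning(e1 <- bottleneck_enrichment(g, neg1), "one category")
  expect_true(is.na(attr(e1, "chisq_p")))
})

test_that("inter-community candidates are enriched in bottlenecks", {
  g1 <- make_network(50, 4, seed = 12)
  g2 <- make_network(50, 4, seed = 13)
  igraph::V(g2)$name <- sub("^Y", "Z", igraph::V(g2)$name)
  g <- igraph::disjoint_union(g1, g2)
  bridges <- c("Y0001", "Z0001", "Y0002", "Z0002")
  g <- igraph::add_edges(g, bridges)
  nm1 <- igraph::V(g1)$name; nm2 <- igraph::V(g2)$name
  set.seed(204)
  inter <- data.frame(id_a = sample(nm1[-(1:2)], 15),
                      id_b = sample(nm2[-(1:2)], 15),
                      category = "inter", stringsAsFactors = FALSE)
  intra <- sample_negative_random(g1, 15, seed = 205)
  intra <- data.frame(id_a = intra$id_a, id_b = intra$id_b,
                      category = "intra", stringsAsFactors = FALSE)
  enr <- bottleneck_enrichment(g, rbind(inter, intra))
  li <- enr$log_odds[enr$category == "inter"]
  lw <- enr$log_odds[enr$category == "intra"]
  expect_gt(li, 0)
  expect_gt(li, lw)
  calls <- attr(enr, "calls")
  expect_gt(median(calls$betweenness[calls$category == "inter"]),
            median(calls$betweenness[calls$category == "intra"]))
})

test_that("bottleneck calls are invariant to node relabelling", {
  g <- make_network(40, 4, seed = 14)
  neg <- sample_negative_random(g, 12, seed = 15)
  neg$category <- "c"
  e1 <- suppressWarnings(bottleneck_enrichment(g, neg))
  perm <- igraph::V(g)$name
  relab <- setNames(paste0("N", rev(seq_along(perm))), perm)
  g2 <- g
  igraph::V(g2)$name <- unname(relab[perm])
  neg2 <- neg
  neg2$id_a <- unname(relab[neg$id_a]); neg2$id_b <- unname(relab[neg$id_b])
  e2 <- suppressWarnings(bottleneck_enrichment(g2, neg2))
  expect_equal(attr(e1, "calls")$bottleneck, attr(e2, "calls")$bottleneck)
})
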