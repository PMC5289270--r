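# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the package code.

# --- quaternion (Horn) rigid superposition -------------------------------
quaternion_rmsd <- function(a, b) {
  ac <- sweep(a, 2, colMeans(a)); bc <- sweep(b, 2, colMeans(b))
  M <- t(ac) %*% bc
  K <- matrix(c(
    M[1, 1] + M[2, 2] + M[3, 3], M[2, 3] - M[3, 2],
    M[3, 1] - M[1, 3], M[1, 2] - M[2, 1],
    M[2, 3] - M[3, 2], M[1, 1] - M[2, 2] - M[3, 3],
    M[1, 2] + M[2, 1], M[3, 1] + M[1, 3],
    M[3, 1] - M[1, 3], M[1, 2] + M[2, 1],
    -M[1, 1] + M[2, 2] - M[3, 3], M[2, 3] + M[3, 2],
    M[1, 2] - M[2, 1], M[3, 1] + M[1, 3],
    M[2, 3] + M[3, 2], -M[1, 1] - M[2, 2] + M[3, 3]
  ), 4, 4, byrow = TRUE)
  ev <- eigen(K, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  sqrt(mean(rowSums((ac %*% t(R) - bc)^2)))
}

# --- all-pairs BFS shortest-path enumeration edge betweenness ------------
bfs_edge_betweenness <- function(g) {
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(igraph::vcount(g)))
  n <- length(nm)
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  el <- igraph::as_edgelist(g, names = FALSE)
  ekey <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  eb <- setNames(numeric(nrow(el)), ekey)
  all_shortest <- function(s, t) {
    # BFS layers from s, then enumerate paths backwards from t
    dist <- rep(Inf, n); dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in adj[[v]]) {
        if (dist[w] == Inf) { dist[w] <- dist[v] + 1; queue <- c(queue, w) }
      }
    }
    if (!is.finite(dist[t])) return(list())
    paths <- list()
    walk <- function(v, acc) {
      if (v == s) { paths[[length(paths) + 1L]] <<- rev(acc); return() }
      for (w in adj[[v]]) {
        if (dist[w] == dist[v] - 1) walk(w, c(acc, w))
      }
    }
    walk(t, t)
    paths
  }
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_shortest(s, t)
      if (!length(paths)) next
      credit <- 1 / length(paths)
      for (p in paths) {
        for (k in seq_len(length(p) - 1)) {
          key <- paste(min(p[k], p[k + 1]), max(p[k], p[k + 1]))
          eb[key] <- eb[key] + credit
        }
      }
    }
  }
  unname(eb[ekey])
}

# --- exhaustive Fisher 2x2 two-sided p (probability-mass rule) -----------
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a <- max(0, c1 - r2):min(r1, c1)
  pr <- dhyper(a, r1, r2, c1)
  pobs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# --- exhaustive monotone-mapping alignment score -------------------------
# Objective mirrored from the package DP: sum of S over aligned pairs
# minus gap_open per internal gap opening on either chain, free ends.
enum_best_alignment <- function(S, gap_open = 0.6) {
  n <- nrow(S); m <- ncol(S)
  best <- -Inf
  rec <- function(li, lj, sc) {
    if (sc > best) best <<- sc
    if (li >= n || lj >= m) return()
    for (i in (li + 1):n) {
      for (j in (lj + 1):m) {
        pen <- if (li == 0L) 0 else {
          gap_open * ((i - li > 1) + (j - lj > 1))
        }
        rec(i, j, sc + S[i, j] - pen)
      }
    }
  }
  rec(0L, 0L, 0)
  best
}

mapping_alignment_score <- function(S, mapping, gap_open = 0.6) {
  k <- nrow(mapping)
  if (k == 0L) return(0)
  sc <- sum(S[mapping])
  if (k > 1L) {
    di <- diff(mapping[, 1]); dj <- diff(mapping[, 2])
    sc <- sc - gap_open * (sum(di > 1) + sum(dj > 1))
  }
  sc
}

# --- union-find connected components -------------------------------------
uf_component_sizes <- function(g) {
  n <- igraph::vcount(g)
  parent <- seq_len(n)
  find <- function(x) {
    x <- as.integer(x)
    while (parent[x] != x) x <- parent[x]
    x
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  for (r in seq_len(nrow(el))) {
    ra <- find(el[r, 1]); rb <- find(el[r, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, integer(1))
  sort(as.integer(table(roots)), decreasing = TRUE)
}

# --- brute-force interface scans -----------------------------------------
brute_interface_residues <- function(st, cutoff = 5) {
  a <- st$chains[[1]]$atoms; b <- st$chains[[2]]$atoms
  res_a <- integer(0); res_b <- integer(0)
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      if (d < cutoff) {
        res_a <- union(res_a, a$resno[i])
        res_b <- union(res_b, b$resno[j])
      }
    }
  }
  list(sort(res_a), sort(res_b))
}

brute_ca_contact_count <- function(st, cutoff = 12) {
  a <- st$chains[[1]]$atoms; a <- a[a$name == "CA", ]
  b <- st$chains[[2]]$atoms; b <- b[b$name == "CA", ]
  cnt <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a$x[i] - b$x[j])^2 + (a$y[i] - b$y[j])^2 +
                  (a$z[i] - b$z[j])^2)
      std <- structprec:::is_standard_aa(a$resname[i]) &&
        structprec:::is_standard_aa(b$resname[j])
      if (d < cutoff && std) cnt <- cnt + 1L
    }
  }
  cnt
}
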