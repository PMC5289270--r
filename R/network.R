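## Network impact of candidate interactions: extra-edge betweenness and
## bottleneck enrichment. Graph machinery is igraph throughout; networks
## are simple undirected igraph objects with named vertices.

as_network <- function(g) {
  if (igraph::is_igraph(g)) {
    if (igraph::is_directed(g)) stop("network must be undirected")
    return(g)
  }
  if (is.data.frame(g)) return(igraph::graph_from_data_frame(g[, 1:2],
                                                             directed = FALSE))
  stop("expected an igraph object or an edge data.frame")
}

#' Largest connected component
#'
#' Induced subgraph on the largest component; size ties are broken in
#' favour of the component containing the lexicographically smallest
#' vertex name.
#'
#' @param g undirected igraph object (non-empty).
#' @return igraph object.
#' @export
largest_connected_component <- function(g) {
  g <- as_network(g)
  if (igraph::vcount(g) == 0L) stop("empty graph")
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
    first_name <- vapply(best, function(k) min(nm[comp$membership == k]),
                         character(1))
    best <- best[order(first_name)][1L]
  } else {
    best <- best[1L]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Edge betweenness of every edge
#'
#' Brandes-style accumulation over unordered vertex pairs on unweighted
#' shortest paths; when several shortest paths tie, credit is split
#' fractionally among them.
#'
#' @param g undirected igraph object.
#' @return data.frame with columns `from`, `to`, `betweenness` (edge order
#'   as in `g`).
#' @export
edge_betweenness <- function(g) {
  g <- as_network(g)
  eb <- igraph::edge_betweenness(g, directed = FALSE)
  el <- igraph::as_edgelist(g)
  data.frame(from = el[, 1], to = el[, 2], betweenness = eb,
             stringsAsFactors = FALSE)
}

#' Betweenness of a candidate extra edge
#'
#' Adds the candidate edge to a copy of the native network and returns the
#' betweenness of that edge in the augmented graph. The native network is
#' left unmodified.
#'
#' @param native undirected igraph object.
#' @param candidate length-2 vector of vertex names (or a 1-row
#'   data.frame with two columns).
#' @return the extra edge's betweenness value.
#' @export
extra_edge_betweenness <- function(native, candidate) {
  native <- as_network(native)
  if (is.data.frame(candidate)) candidate <- as.character(candidate[1, 1:2])
  candidate <- as.character(candidate)
  stopifnot(length(candidate) == 2L)
  nm <- igraph::V(native)$name
  if (!all(candidate %in% nm)) {
    stop("candidate endpoints must be present in the native network: ",
         paste(setdiff(candidate, nm), collapse = ", "))
  }
  if (candidate[1] == candidate[2]) stop("self-loops are not allowed")
  if (igraph::are_adjacent(native, candidate[1], candidate[2])) {
    stop("candidate edge already present in the native network")
  }
  g2 <- igraph::add_edges(native, candidate)
  eb <- igraph::edge_betweenness(g2, directed = FALSE)
  eb[igraph::ecount(g2)]
}

#' Bottleneck enrichment of candidate edge categories
#'
#' Each candidate (non-interacting) pair is added separately to the native
#' network; its extra-edge betweenness is compared with the distribution
#' of all edge betweenness values. A candidate is a *bottleneck* when its
#' value reaches the `1 - top_fraction` quantile of the edge betweenness
#' values (by default of the augmented graph the candidate lives in;
#' `threshold_scope = "native"` uses the unperturbed network's
#' distribution instead). Per category the enrichment is summarized as
#' `log_odds = log2(observed bottleneck fraction / top_fraction)`, with a
#' chi-squared test on the category x bottleneck contingency table and
#' standardized-residual p-values.
#'
#' @param native undirected igraph object.
#' @param candidates data.frame with columns `id_a`, `id_b`, `category`.
#' @param top_fraction bottleneck quantile (default 0.10: top 10% of edges
#'   by betweenness).
#' @param threshold_scope `"augmented"` (default) or `"native"`.
#' @return data.frame with one row per category: `category`, `n_edges`,
#'   `n_bottlenecks`, `observed_fraction`, `expected_fraction`,
#'   `log_odds`, `residual_p`. The candidate-level calls are attached as
#'   attribute `"calls"`, the global chi-squared p as attribute
#'   `"chisq_p"` (`NA` when undefined).
#' @export
bottleneck_enrichment <- function(native, candidates, top_fraction = 0.10,
                                  threshold_scope = c("augmented", "native")) {
  native <- as_network(native)
  threshold_scope <- match.arg(threshold_scope)
  stopifnot(is.data.frame(candidates),
            all(c("id_a", "id_b", "category") %in% names(candidates)))
  empty <- !nzchar(as.character(candidates$category)) |
    is.na(candidates$category)
  if (any(empty)) {
    warning(sum(empty), " candidates without category omitted")
    candidates <- candidates[!empty, , drop = FALSE]
  }
  if (!nrow(candidates)) stop("no candidates to test")
  eb_native <- igraph::edge_betweenness(native, directed = FALSE)
  thr_native <- quantile(eb_native, 1 - top_fraction, names = FALSE)
  vals <- numeric(nrow(candidates))
  isbn <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cand <- c(as.character(candidates$id_a[i]),
              as.character(candidates$id_b[i]))
    g2 <- igraph::add_edges(native, cand)
    eb2 <- igraph::edge_betweenness(g2, directed = FALSE)
    vals[i] <- eb2[igraph::ecount(g2)]
    thr <- if (threshold_scope == "augmented") {
      quantile(eb2, 1 - top_fraction, names = FALSE)
    } else thr_native
    isbn[i] <- vals[i] >= thr
  }
  calls <- cbind(candidates,
                 betweenness = vals, bottleneck = isbn,
                 stringsAsFactors = FALSE)
  cats <- unique(as.character(candidates$category))
  res <- do.call(rbind, lapply(cats, function(ct) {
    sel <- candidates$category == ct
    nb <- sum(isbn[sel])
    obs <- nb / sum(sel)
    data.frame(category = ct, n_edges = sum(sel), n_bottlenecks = nb,
               observed_fraction = obs, expected_fraction = top_fraction,
               log_odds = log2(obs / top_fraction),
               stringsAsFactors = FALSE)
  }))
  if (length(cats) >= 2L && length(unique(isbn)) == 2L) {
    tab <- table(factor(as.character(candidates$category), levels = cats),
                 factor(isbn, levels = c(FALSE, TRUE)))
    cs <- suppressWarnings(chisq.test(tab))
    sr <- cs$stdres[, "TRUE"]
    res$residual_p <- 2 * pnorm(-abs(sr[res$category]))
    attr(res, "chisq_p") <- cs$p.value
  } else {
    if (length(cats) < 2L) {
      warning("only one category: chi-squared test undefined")
    }
    res$residual_p <- NA_real_
    attr(res, "chisq_p") <- NA_real_
  }
  attr(res, "calls") <- calls
  res
}
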