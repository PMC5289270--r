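## Construction of non-interacting (negative) pair datasets by the five
## selection strategies, plus pair-level annotation helpers.

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

## drop self pairs and duplicate unordered pairs, preserving order
normalize_pairs <- function(pairs) {
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  keep <- pairs$id_a != pairs$id_b
  pairs <- pairs[keep, , drop = FALSE]
  pairs[!duplicated(pair_key(pairs$id_a, pairs$id_b)), , drop = FALSE]
}

#' Random sampling of non-interacting pairs
#'
#' Uniform sample, without replacement, from the non-adjacent vertex pairs
#' of the native network.
#'
#' @param native undirected igraph object.
#' @param n number of pairs to draw.
#' @param seed integer seed.
#' @return data.frame `id_a`, `id_b`, `label = "non-interacting"`,
#'   `source = "random"`.
#' @export
sample_negative_random <- function(native, n, seed = 1L) {
  native <- as_network(native)
  nm <- igraph::V(native)$name
  nv <- length(nm)
  n_nonedges <- choose(nv, 2) - igraph::ecount(native)
  if (n > n_nonedges) {
    stop("requested ", n, " pairs but only ", n_nonedges, " non-edges exist")
  }
  with_seed(seed, {
    chosen <- character(0)
    out_a <- character(0); out_b <- character(0)
    while (length(out_a) < n) {
      need <- n - length(out_a)
      ia <- sample.int(nv, 2 * need + 10, replace = TRUE)
      ib <- sample.int(nv, 2 * need + 10, replace = TRUE)
      ok <- ia != ib
      ia <- ia[ok]; ib <- ib[ok]
      if (!length(ia)) next
      eid <- igraph::get_edge_ids(native, rbind(ia, ib))
      ok <- eid == 0
      ia <- ia[ok]; ib <- ib[ok]
      key <- pair_key(nm[ia], nm[ib])
      ok <- !duplicated(key) & !(key %in% chosen)
      ia <- ia[ok]; ib <- ib[ok]; key <- key[ok]
      take <- seq_len(min(need, length(ia)))
      out_a <- c(out_a, nm[ia[take]])
      out_b <- c(out_b, nm[ib[take]])
      chosen <- c(chosen, key[take])
    }
    data.frame(id_a = out_a, id_b = out_b, label = "non-interacting",
               source = "random", stringsAsFactors = FALSE)
  })
}

#' Degree-preserving (balanced) negative sampling
#'
#' Builds a negative edge set in which every node keeps its native degree,
#' by stub matching with rejection of self-loops, duplicate pairs and
#' native edges, restarting on dead ends. When no exact degree-preserving
#' non-edge set can be found within `max_restarts`, the default is an
#' error; with `allow_partial = TRUE` unmatchable stubs are dropped and
#' the maximal set found is returned (each node then ends with at most
#' its native degree).
#'
#' @param native undirected igraph object.
#' @param seed integer seed.
#' @param max_restarts restart budget (default 1000).
#' @param allow_partial return a maximal partial matching instead of
#'   erroring on infeasibility.
#' @return data.frame `id_a`, `id_b`, `label`, `source = "balanced"`.
#' @export
sample_negative_balanced <- function(native, seed = 1L,
                                     max_restarts = 1000L,
                                     allow_partial = FALSE) {
  native <- as_network(native)
  nm <- igraph::V(native)$name
  deg <- igraph::degree(native)
  adj <- lapply(igraph::adjacent_vertices(native, igraph::V(native)),
                as.integer)
  with_seed(seed, {
    for (restart in seq_len(max_restarts)) {
      pool <- sample(rep(seq_along(nm), deg))
      ## hubs are the scarce resource: match their stubs first
      pool <- pool[order(-deg[pool], sample.int(length(pool)))]
      edges <- matrix(integer(0), ncol = 2)
      used <- character(0)
      failed <- FALSE
      while (length(pool) >= 2L) {
        a <- pool[1L]
        rest <- pool[-1L]
        valid <- which(rest != a &
                         !(rest %in% adj[[a]]) &
                         !(pair_key(nm[a], nm[rest]) %in% used))
        if (!length(valid)) {
          if (allow_partial) {  # drop the unmatchable stub, keep going
            pool <- rest
            next
          }
          failed <- TRUE
          break
        }
        pick <- valid[sample.int(length(valid), 1L)]
        b <- rest[pick]
        edges <- rbind(edges, c(a, b))
        used <- c(used, pair_key(nm[a], nm[b]))
        pool <- rest[-pick]
      }
      if (!failed) {
        return(data.frame(id_a = nm[edges[, 1]], id_b = nm[edges[, 2]],
                          label = "non-interacting", source = "balanced",
                          stringsAsFactors = FALSE))
      }
    }
    stop("no feasible degree-preserving negative edge set found within ",
         max_restarts, " restarts")
  })
}

#' Keep pairs far apart in the interaction network
#'
#' Retains pairs whose unweighted shortest-path distance in the native
#' network is strictly greater than `min_path`; pairs in different
#' components (infinite distance) are kept. Pairs with an endpoint absent
#' from the network are dropped with a warning.
#'
#' @param pairs data.frame with `id_a`, `id_b`.
#' @param native undirected igraph object.
#' @param min_path strict distance threshold (default 10).
#' @return the retained pairs.
#' @export
filter_fnr <- function(pairs, native, min_path = 10) {
  native <- as_network(native)
  nm <- igraph::V(native)$name
  present <- pairs$id_a %in% nm & pairs$id_b %in% nm
  if (any(!present)) {
    warning(sum(!present), " pairs with endpoints absent from the network ",
            "dropped")
    pairs <- pairs[present, , drop = FALSE]
  }
  if (!nrow(pairs)) return(pairs)
  d <- igraph::distances(native, v = unique(pairs$id_a),
                         to = unique(pairs$id_b))
  dist <- d[cbind(match(pairs$id_a, rownames(d)),
                  match(pairs$id_b, colnames(d)))]
  pairs[dist > min_path, , drop = FALSE]
}

#' Keep pairs with different, unique subcellular localization
#'
#' Drops any pair in which either protein is unannotated or annotated to
#' several compartments; keeps pairs whose two single localizations
#' differ.
#'
#' @param pairs data.frame with `id_a`, `id_b`.
#' @param annotations an [make_annotations()] result or a named list of
#'   localization vectors.
#' @return the retained pairs.
#' @export
filter_noncolocalized <- function(pairs, annotations) {
  loc <- if (inherits(annotations, "annotation_table")) {
    annotations$localization
  } else annotations
  one <- function(id) {
    l <- loc[[id]]
    if (is.null(l) || length(l) != 1L) NA_character_ else l
  }
  la <- vapply(pairs$id_a, one, character(1))
  lb <- vapply(pairs$id_b, one, character(1))
  keep <- !is.na(la) & !is.na(lb) & la != lb
  pairs[keep, , drop = FALSE]
}

#' Keep pairs supported by a direct detection method
#'
#' @param pairs data.frame with `id_a`, `id_b`.
#' @param method_sets list (parallel to the rows of `pairs`) of detection
#'   method strings per pair.
#' @param allowed method names accepted as direct evidence.
#' @return the retained pairs.
#' @export
filter_direct <- function(pairs, method_sets,
                          allowed = c("Two-hybrid", "PCA",
                                      "Biochemical Activity",
                                      "Co-crystal Structure",
                                      "Reconstituted Complex",
                                      "Far Western", "FRET")) {
  stopifnot(length(method_sets) == nrow(pairs))
  keep <- vapply(method_sets, function(m) {
    length(m) > 0L && any(m %in% allowed)
  }, logical(1))
  pairs[keep, , drop = FALSE]
}

#' Abundance class of a protein pair
#'
#' The pair abundance is the lowest abundance in the pair (a low-abundance
#' partner limits complex formation): ordering low < medium < high.
#' Pairs with an unclassified protein are flagged `"unknown"`.
#'
#' @param pairs data.frame with `id_a`, `id_b` (or a length-2 character
#'   vector for a single pair).
#' @param annotations an [make_annotations()] result or a named character
#'   vector of classes (`"low"`, `"medium"`, `"high"`).
#' @return character vector of pair classes.
#' @export
pair_abundance <- function(pairs, annotations) {
  cls <- if (inherits(annotations, "annotation_table")) {
    setNames(annotations$abundance$class, annotations$abundance$id)
  } else annotations
  if (!is.data.frame(pairs)) {
    pairs <- data.frame(id_a = pairs[1], id_b = pairs[2],
                        stringsAsFactors = FALSE)
  }
  lv <- c("low", "medium", "high")
  ca <- cls[pairs$id_a]; cb <- cls[pairs$id_b]
  out <- rep("unknown", nrow(pairs))
  okr <- !is.na(ca) & !is.na(cb) & ca %in% lv & cb %in% lv
  out[okr] <- lv[pmin(match(ca[okr], lv), match(cb[okr], lv))]
  out
}
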