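## Rigid-body superposition, TM-score, and a heuristic sequential
## structural aligner (threading seeds + iterative superpose/score/DP).
## Not a re-implementation of any published executable: the aim is
## TM-align-like behaviour at desk scale, with the exact scoring formula.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sum ||R a_i + t - b_i||^2`. Reflections are never returned.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices (n >= 3), matched
#'   row-wise.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length-3)
#'   and `rmsd` (Angstrom over the n pairs).
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (ncol(coords_a) != 3L || ncol(coords_b) != 3L) {
    stop("coordinate matrices must have 3 columns")
  }
  n <- nrow(coords_a)
  if (n != nrow(coords_b)) stop("point counts differ")
  if (n < 3L) stop("at least 3 points are required")
  if (!all(is.finite(coords_a)) || !all(is.finite(coords_b))) {
    stop("coordinates must be finite")
  }
  ca <- colMeans(coords_a); cb <- colMeans(coords_b)
  A <- sweep(coords_a, 2, ca); B <- sweep(coords_b, 2, cb)
  rank2 <- function(M) {
    ev <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
    sum(ev > 1e-16 * max(ev[1], 1)) >= 2L
  }
  if (!rank2(A) || !rank2(B)) stop("degenerate (collinear) point set")
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- as.numeric(cb - R %*% ca)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' TM-score distance scale d0
#'
#' `d0 = max(0.5, 1.24 (L - 15)^(1/3) - 1.8)`, floored at 0.5 Angstrom for
#' short chains.
#'
#' @param norm_length normalization length L (residues).
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(norm_length) {
  L <- norm_length - 15
  cb <- sign(L) * abs(L)^(1 / 3)
  max(0.5, 1.24 * cb - 1.8)
}

apply_rt <- function(xyz, R, tr) sweep(xyz %*% t(R), 2, tr, "+")

## TM-sum of a mapped pair set under a fixed transform, divided by norm.
tm_sum <- function(xa, xb, R, tr, d0, norm_length) {
  d2 <- rowSums((apply_rt(xa, R, tr) - xb)^2)
  sum(1 / (1 + d2 / d0^2)) / norm_length
}

## Iterative distance-cut refinement from a starting transform; returns the
## best (score, rotation, translation) encountered.
tm_refine <- function(xa, xb, R, tr, d0, norm_length, max_iter = 30L) {
  best <- list(score = -Inf, rotation = R, translation = tr)
  prev_sel <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- rowSums((apply_rt(xa, R, tr) - xb)^2)
    sc <- sum(1 / (1 + d2 / d0^2)) / norm_length
    if (sc > best$score) best <- list(score = sc, rotation = R, translation = tr)
    dcut <- max(d0, 1.5)
    sel <- d2 < dcut^2
    while (sum(sel) < 3L && dcut < 50) {
      dcut <- dcut + 0.5
      sel <- d2 < dcut^2
    }
    if (sum(sel) < 3L) break
    if (!is.null(prev_sel) && identical(sel, prev_sel)) break
    prev_sel <- sel
    fit <- tryCatch(kabsch_superpose(xa[sel, , drop = FALSE],
                                     xb[sel, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) break
    R <- fit$rotation; tr <- fit$translation
  }
  best
}

#' TM-score of a fixed residue mapping
#'
#' `score = (1 / L) * sum over mapped pairs of 1 / (1 + (d_i / d0)^2)`,
#' maximized over rigid transforms of the first point set. The maximization
#' seeds superpositions from the full mapping and from contiguous mapping
#' fragments, each followed by iterative distance-cut refinement, as in the
#' usual TM-score protocol.
#'
#' @param coords_a,coords_b CA coordinate matrices of the two chains
#'   (full chains; rows indexed by the mapping).
#' @param mapping k x 2 matrix of aligned residue indices (column 1 into
#'   `coords_a`, column 2 into `coords_b`), strictly increasing.
#' @param norm_length normalization length L (>= k).
#' @return list with `score`, `d0`, `rotation`, `translation`.
#' @export
tm_score <- function(coords_a, coords_b, mapping, norm_length) {
  mapping <- matrix(as.integer(mapping), ncol = 2)
  k <- nrow(mapping)
  if (k == 0L) stop("mapping must be non-empty")
  if (norm_length < k) stop("norm_length must be >= number of mapped pairs")
  d0 <- tm_d0(norm_length)
  xa <- as.matrix(coords_a)[mapping[, 1], , drop = FALSE]
  xb <- as.matrix(coords_b)[mapping[, 2], , drop = FALSE]
  if (k == 1L) {
    ## a single pair can always be moved onto its partner
    return(list(score = 1 / norm_length, d0 = d0,
                rotation = diag(3), translation = xb[1, ] - xa[1, ]))
  }
  if (k == 2L) {
    ## two pairs: the residual is set by the segment-length mismatch
    la <- vnorm(xa[2, ] - xa[1, ]); lb <- vnorm(xb[2, ] - xb[1, ])
    d <- abs(la - lb) / 2
    return(list(score = 2 / (1 + (d / d0)^2) / norm_length, d0 = d0,
                rotation = diag(3), translation = c(0, 0, 0)))
  }
  seeds <- list(seq_len(k))
  for (w in unique(pmax(4L, c(ceiling(k / 2), ceiling(k / 4))))) {
    if (w >= k) next
    starts <- unique(c(seq(1L, k - w + 1L, by = max(1L, floor(w / 2))),
                       k - w + 1L))
    for (s in starts) seeds[[length(seeds) + 1L]] <- s:(s + w - 1L)
  }
  best <- list(score = -Inf)
  for (sel in seeds) {
    fit <- tryCatch(kabsch_superpose(xa[sel, , drop = FALSE],
                                     xb[sel, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    res <- tm_refine(xa, xb, fit$rotation, fit$translation, d0, norm_length)
    if (res$score > best$score) best <- res
  }
  if (!is.finite(best$score)) stop("could not superpose the mapped pairs")
  list(score = min(1, best$score), d0 = d0,
       rotation = best$rotation, translation = best$translation)
}

## Gapless threading seed mappings: i -> i + o for all offsets with at
## least `min_overlap` aligned pairs.
threading_seeds <- function(n, m, min_overlap = 5L) {
  min_overlap <- min(min_overlap, n, m)
  offs <- seq(min_overlap - n, m - min_overlap)
  lapply(offs, function(o) {
    i <- max(1L, 1L - o):min(n, m - o)
    cbind(i, i + o)
  })
}

#' Align two chains by structure
#'
#' Heuristic sequential CA alignment. Seeds come from gapless threading at
#' every offset and from fragment-pair superpositions; each seed transform
#' is turned into a mapping by scoring all residue pairs with
#' `1 / (1 + (d_ij / d0)^2)` and running a sequential dynamic program
#' (gap opening penalty 0.6, no extension penalty, ties toward the
#' diagonal). The best seeds are then iterated
#' (superpose on the mapped pairs, re-score, re-align) until the mapping
#' repeats or `max_iter` rounds. The returned TM-score is normalized by
#' the length of chain `a` and never falls below the score of any
#' threading seed.
#'
#' @param a,b `prot_chain` (or single-chain `prot_structure`) with at
#'   least 5 CA-bearing residues each.
#' @param gap_open gap opening penalty used by the dynamic program.
#' @param max_iter iteration cap per seed.
#' @param n_starts number of top-scoring seeds iterated.
#' @return an object of class `structal_alignment`: list with `mapping`
#'   (k x 2), `rotation`, `translation`, `rmsd` (over mapped CA pairs),
#'   `tm_score`, `d0`, `norm_length`.
#' @export
align_structures <- function(a, b, gap_open = 0.6, max_iter = 20L,
                             n_starts = 3L) {
  a <- as_chain(a); b <- as_chain(b)
  xa <- ca_xyz(a); xb <- ca_xyz(b)
  n <- nrow(xa); m <- nrow(xb)
  if (n < 5L || m < 5L) stop("both chains need at least 5 CA residues")
  d0 <- tm_d0(n)
  d0s <- max(d0, 1.0)  # search scale for the DP score matrix

  score_of <- function(mapping, R, tr) {
    sel_a <- xa[mapping[, 1], , drop = FALSE]
    sel_b <- xb[mapping[, 2], , drop = FALSE]
    if (nrow(mapping) >= 3L) {
      fit <- tryCatch(kabsch_superpose(sel_a, sel_b), error = function(e) NULL)
      if (!is.null(fit)) { R <- fit$rotation; tr <- fit$translation }
    }
    list(score = tm_sum(sel_a, sel_b, R, tr, d0, n), rotation = R,
         translation = tr)
  }
  dp_from <- function(R, tr) {
    d2 <- cross_dist2(apply_rt(xa, R, tr), xb)
    S <- 1 / (1 + d2 / d0s^2)
    dp_align_cpp(S, gap_open)
  }

  candidates <- list()

  ## threading seeds: candidate = the gapless mapping itself, scored
  ## under its own superposition (no re-fit needed)
  thr <- threading_seeds(n, m)
  seed_transforms <- list()
  for (mp in thr) {
    if (nrow(mp) < 3L) next
    sel_a <- xa[mp[, 1], , drop = FALSE]
    sel_b <- xb[mp[, 2], , drop = FALSE]
    fit <- tryCatch(kabsch_superpose(sel_a, sel_b),
                    error = function(e) NULL)
    if (is.null(fit)) next
    sc <- tm_sum(sel_a, sel_b, fit$rotation, fit$translation, d0, n)
    candidates[[length(candidates) + 1L]] <-
      list(mapping = mp, score = sc, rotation = fit$rotation,
           translation = fit$translation)
    seed_transforms[[length(seed_transforms) + 1L]] <-
      list(rotation = fit$rotation, translation = fit$translation,
           quick = sc)
  }
  ## only the most promising threading transforms feed the DP
  if (length(seed_transforms) > 10L) {
    qs <- vapply(seed_transforms, `[[`, numeric(1), "quick")
    seed_transforms <- seed_transforms[order(qs, decreasing = TRUE)[1:10]]
  }
  ## fragment-pair seeds (secondary-structure-agnostic)
  w <- min(15L, n, m)
  if (w >= 5L) {
    for (i0 in unique(c(seq(1L, n - w + 1L, by = 10L), n - w + 1L))) {
      for (j0 in unique(c(seq(1L, m - w + 1L, by = 10L), m - w + 1L))) {
        mp <- cbind(i0:(i0 + w - 1L), j0:(j0 + w - 1L))
        fit <- tryCatch(kabsch_superpose(xa[mp[, 1], , drop = FALSE],
                                         xb[mp[, 2], , drop = FALSE]),
                        error = function(e) NULL)
        if (is.null(fit)) next
        seed_transforms[[length(seed_transforms) + 1L]] <-
          list(rotation = fit$rotation, translation = fit$translation,
               quick = NA_real_)
      }
    }
  }
  ## one DP pass per seed transform, then iterate the best few
  dp_cands <- list()
  for (st in seed_transforms) {
    mp <- dp_from(st$rotation, st$translation)
    if (nrow(mp) == 0L) next
    sc <- score_of(mp, st$rotation, st$translation)
    dp_cands[[length(dp_cands) + 1L]] <-
      list(mapping = mp, score = sc$score, rotation = sc$rotation,
           translation = sc$translation)
  }
  if (length(dp_cands)) {
    ord <- order(vapply(dp_cands, `[[`, numeric(1), "score"),
                 decreasing = TRUE)
    for (ci in ord[seq_len(min(n_starts, length(ord)))]) {
      cur <- dp_cands[[ci]]
      candidates[[length(candidates) + 1L]] <- cur
      seen <- list(cur$mapping)
      for (it in seq_len(max_iter)) {
        mp <- dp_from(cur$rotation, cur$translation)
        if (nrow(mp) == 0L) break
        if (any(vapply(seen, identical, logical(1), mp))) break
        seen[[length(seen) + 1L]] <- mp
        sc <- score_of(mp, cur$rotation, cur$translation)
        cur <- list(mapping = mp, score = sc$score, rotation = sc$rotation,
                    translation = sc$translation)
        candidates[[length(candidates) + 1L]] <- cur
      }
    }
  }
  if (!length(candidates)) stop("alignment failed: no usable seed")
  scores <- vapply(candidates, `[[`, numeric(1), "score")
  best <- candidates[[which.max(scores)]]
  refined <- tm_score(xa, xb, best$mapping, n)
  sel_a <- xa[best$mapping[, 1], , drop = FALSE]
  sel_b <- xb[best$mapping[, 2], , drop = FALSE]
  rmsd <- if (nrow(best$mapping) >= 3L) {
    tryCatch(kabsch_superpose(sel_a, sel_b)$rmsd, error = function(e) NA_real_)
  } else NA_real_
  structure(list(
    mapping = best$mapping,
    rotation = refined$rotation,
    translation = refined$translation,
    rmsd = rmsd,
    tm_score = max(refined$score, best$score),
    d0 = refined$d0,
    norm_length = n
  ), class = "structal_alignment")
}

#' @export
print.structal_alignment <- function(x, ...) {
  cat(sprintf(
    "<alignment: %d pairs, TM-score %.3f (L=%d, d0=%.2f), rmsd %.2f A>\n",
    nrow(x$mapping), x$tm_score, x$norm_length, x$d0, x$rmsd))
  invisible(x)
}
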