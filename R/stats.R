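## Rate curves, the extrapolation arithmetic, and the statistical tests:
## Fisher exact on 2x2 tables, the Cramer (Baringhaus-Franz) two-sample
## test with resampled p-values, and hypergeometric term enrichment with
## Benjamini-Hochberg correction.

#' Precedent rate as a function of the TMmin threshold
#'
#' `rate(t)` is the fraction of pairs (with 3D models) whose best valid
#' precedent has TMmin at or above `t`; by construction it is
#' non-increasing in `t`.
#'
#' @param tmmin numeric vector of best valid TMmin per pair (`NA` for
#'   pairs without a valid precedent). Length = number of pairs with
#'   models.
#' @param thresholds ascending TMmin cutoffs in \[0, 1\].
#' @return data.frame with columns `threshold`, `n_pairs`, `n_hits`,
#'   `rate`.
#' @export
precedent_rate_curve <- function(tmmin, thresholds = c(0.4, 0.5, 0.6)) {
  n <- length(tmmin)
  if (n == 0L) stop("no pairs")
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  hits <- vapply(thresholds, function(t) sum(!is.na(tmmin) & tmmin >= t),
                 numeric(1))
  data.frame(threshold = thresholds, n_pairs = n, n_hits = hits,
             rate = hits / n)
}

#' Interactome density
#'
#' Percentage of realized interactions among all protein pairs:
#' `100 * n_interactions / (n_proteins * (n_proteins - 1) / 2)`.
#'
#' @param n_interactions number of (direct) interactions.
#' @param n_proteins number of proteins (>= 2).
#' @return density in percent.
#' @export
network_density <- function(n_interactions, n_proteins) {
  if (n_proteins < 2) stop("n_proteins must be >= 2")
  possible <- n_proteins * (n_proteins - 1) / 2
  if (n_interactions < 0 || n_interactions > possible) {
    stop("n_interactions must lie in [0, ", possible, "]")
  }
  100 * n_interactions / possible
}

#' Expected precedent contamination from false negatives
#'
#' If negative datasets were contaminated by unreported true interactions
#' purely at random, the expected precedent rate would be the positive
#' rate scaled by the interactome density:
#' `positive_rate * density / 100` (all three in percent).
#'
#' @param positive_rate precedent rate of interacting pairs, percent.
#' @param density interactome density, percent.
#' @return expected rate in percent.
#' @export
expected_contamination <- function(positive_rate, density) {
  if (positive_rate < 0 || density < 0) stop("rates must be >= 0")
  positive_rate * density / 100
}

#' Enrichment factor of an observed rate over an expected rate
#'
#' @param observed_rate,expected_rate rates in percent
#'   (`expected_rate > 0`).
#' @return the ratio `observed_rate / expected_rate`.
#' @export
enrichment_factor <- function(observed_rate, expected_rate) {
  if (expected_rate <= 0) stop("expected_rate must be > 0")
  observed_rate / expected_rate
}

#' Completeness-corrected precedent rate
#'
#' Using the positive-pair precedent rate as a proxy for the completeness
#' of the template library, the negative rate extrapolated to a complete
#' library is `100 * negative_rate / positive_rate`.
#'
#' @param negative_rate,positive_rate observed rates in percent
#'   (`positive_rate > 0`).
#' @return corrected rate in percent.
#' @export
completeness_corrected_rate <- function(negative_rate, positive_rate) {
  if (positive_rate <= 0) stop("positive_rate must be > 0")
  if (negative_rate < 0) stop("negative_rate must be >= 0")
  100 * negative_rate / positive_rate
}

#' Extrapolation summary
#'
#' Bundles the extrapolation arithmetic for one scenario: expected
#' contamination under random false negatives, the enrichment of the
#' observed negative rate over it, and the completeness-corrected
#' negative rate.
#'
#' @param negative_rate,positive_rate observed precedent rates, percent.
#' @param density interactome density, percent.
#' @return list with `negative_rate`, `positive_rate`, `density`,
#'   `expected_contamination`, `enrichment_factor`,
#'   `completeness_corrected_rate` (all percentages except the factor).
#' @export
extrapolation_summary <- function(negative_rate, positive_rate, density) {
  exp_c <- expected_contamination(positive_rate, density)
  list(negative_rate = negative_rate,
       positive_rate = positive_rate,
       density = density,
       expected_contamination = exp_c,
       enrichment_factor = enrichment_factor(negative_rate, exp_c),
       completeness_corrected_rate =
         completeness_corrected_rate(negative_rate, positive_rate))
}

#' Round to the printed precision
#'
#' Helper so extrapolated percentages can be compared at the precision
#' they are usually reported with (1 decimal, or whole numbers).
#'
#' @param x numeric.
#' @param digits decimals kept (default 1).
#' @return rounded numeric.
#' @export
round_printed <- function(x, digits = 1L) round(x, digits)

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass rule: the sum of
#' hypergeometric probabilities of all tables (at fixed margins) no more
#' probable than the observed one.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`
#'   (one-sided tests on the first cell).
#' @return the p-value.
#' @export
fisher_exact_2x2 <- function(table,
                             alternative = c("two.sided", "greater",
                                             "less")) {
  alternative <- match.arg(alternative)
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2")
  if (any(table < 0) || any(abs(table - round(table)) > 1e-9)) {
    stop("counts must be non-negative integers")
  }
  stats::fisher.test(round(table), alternative = alternative)$p.value
}

#' Cramer two-sample test
#'
#' Baringhaus-Franz statistic with kernel `phi(z) = |z| / 2`:
#' `T = mn/(m+n) * (2/(mn) SS_xy - 1/m^2 SS_xx - 1/n^2 SS_yy)` where
#' `SS_ab` are double sums of `phi` over the respective samples. The
#' p-value is obtained by label permutation of the pooled sample
#' (default) or by an ordinary bootstrap.
#'
#' @param x,y numeric samples (each non-empty; p-values need at least 2
#'   pooled observations).
#' @param n_boot resamples for the p-value (default 1000; 0 skips the
#'   p-value).
#' @param seed optional integer seed for the resampling.
#' @param method `"permutation"` (default) or `"ordinary"` bootstrap.
#' @return an object of class `htest` with the statistic and p-value.
#' @export
cramer_two_sample <- function(x, y, n_boot = 1000L, seed = NULL,
                              method = c("permutation", "ordinary")) {
  method <- match.arg(method)
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  if (n_boot > 0 && length(x) + length(y) < 2L) {
    stop("p-value needs at least 2 pooled observations")
  }
  run <- function() cramer_perm_cpp(x, y, as.integer(n_boot),
                                    method == "ordinary")
  res <- if (is.null(seed)) run() else with_seed(seed, run())
  structure(list(
    statistic = c(T = res$statistic),
    p.value = res$p_value,
    method = sprintf("Cramer two-sample test (%s, %d resamples)",
                     method, n_boot),
    data.name = paste(deparse(substitute(x)), "and",
                      deparse(substitute(y)))
  ), class = "htest")
}

#' Hypergeometric term enrichment with Benjamini-Hochberg correction
#'
#' For every annotation term, the upper-tail hypergeometric p-value of the
#' overlap between the study set and the term's annotated proteins within
#' the universe; p-values are BH-adjusted across terms and terms with
#' adjusted p at or below `alpha` are returned.
#'
#' @param study_set character vector of study proteins (subset of
#'   `universe`).
#' @param term_map named list: term -> annotated protein ids.
#' @param universe character vector of background proteins.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame of enriched terms: `term`, `n_study`, `n_term`,
#'   `n_overlap`, `p`, `p_adj`; the full table over all tested terms is
#'   attached as attribute `"all_terms"`.
#' @export
hypergeom_enrichment <- function(study_set, term_map, universe,
                                 alpha = 0.05) {
  study_set <- unique(as.character(study_set))
  universe <- unique(as.character(universe))
  if (!all(study_set %in% universe)) {
    stop("study_set must be a subset of the universe")
  }
  N <- length(universe); n <- length(study_set)
  rows <- list()
  for (term in names(term_map)) {
    ann <- intersect(unique(as.character(term_map[[term]])), universe)
    if (!length(ann)) {
      warning("term ", term, " annotates nothing in the universe; skipped")
      next
    }
    K <- length(ann)
    k <- length(intersect(ann, study_set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      term = term, n_study = n, n_term = K, n_overlap = k, p = p,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no testable terms")
  tab <- do.call(rbind, rows)
  tab$p_adj <- p.adjust(tab$p, method = "BH")
  enriched <- tab[tab$p_adj <= alpha, , drop = FALSE]
  rownames(enriched) <- NULL
  attr(enriched, "all_terms") <- tab
  enriched
}
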