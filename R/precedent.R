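## Structural-precedent search: screen a candidate pair of monomers
## against a dimer template library by TMmin, build interaction models by
## rigid superposition onto the template, and validate their interfaces.

#' Inter-chain residue contacts
#'
#' Number of residue pairs (one residue per chain) having any atom-atom
#' distance below `cutoff`.
#'
#' @param chain_a,chain_b `prot_chain` objects.
#' @param cutoff distance threshold in Angstrom (default 5).
#' @param pairs if `TRUE` also return the contacting residue index pairs.
#' @return integer count, or (with `pairs = TRUE`) a list with `count` and
#'   a two-column matrix `pairs` of residue numbers.
#' @export
residue_contacts <- function(chain_a, chain_b, cutoff = 5, pairs = FALSE) {
  d2 <- cross_dist2(atom_xyz(chain_a), atom_xyz(chain_b))
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    pr <- matrix(integer(0), ncol = 2)
  } else {
    pr <- unique(cbind(chain_a$atoms$resno[hit[, 1]],
                       chain_b$atoms$resno[hit[, 2]]))
  }
  if (pairs) list(count = nrow(pr), pairs = pr) else nrow(pr)
}

#' Create a dimer template record
#'
#' A library dimer must satisfy the inclusion rule of the representative
#' set: more than `min_contacts` inter-chain residue contacts at 5
#' Angstrom.
#'
#' @param id template identifier.
#' @param chain_x,chain_y the two chains (`prot_chain`).
#' @param is_homodimer,is_obligate,from_higher_order classification flags.
#' @param min_contacts inclusion threshold (strict; default 10).
#' @return an object of class `dimer_record`.
#' @export
dimer_record <- function(id, chain_x, chain_y, is_homodimer = FALSE,
                         is_obligate = FALSE, from_higher_order = FALSE,
                         min_contacts = 10L) {
  stopifnot(inherits(chain_x, "prot_chain"), inherits(chain_y, "prot_chain"))
  nc <- residue_contacts(chain_x, chain_y, cutoff = 5)
  if (nc <= min_contacts) {
    stop("dimer ", id, " has only ", nc,
         " inter-chain residue contacts at 5 A (need > ", min_contacts, ")")
  }
  structure(list(id = id, chain_x = chain_x, chain_y = chain_y,
                 is_homodimer = isTRUE(is_homodimer),
                 is_obligate = isTRUE(is_obligate),
                 from_higher_order = isTRUE(from_higher_order),
                 n_contacts = nc),
            class = "dimer_record")
}

#' TMmin of a candidate pair against one template
#'
#' Aligns both monomers against both template chains and evaluates the two
#' chain assignments (A->X, B->Y) and (A->Y, B->X). The assignment with
#' the larger `min(tm_a, tm_b)` wins (ties keep the first assignment).
#' TM-scores are normalized by the candidate (query) chain lengths.
#'
#' @param model_a,model_b monomer models (`prot_chain` or single-chain
#'   `prot_structure`).
#' @param dimer a [dimer_record()].
#' @param pair_id identifier carried into the hit.
#' @return an object of class `precedent_hit` with fields `pair_id`,
#'   `template_id`, `assignment` (`"AX/BY"` or `"AY/BX"`), `tm_a`, `tm_b`,
#'   `tmmin`, the two alignments, and (until validation) `NA` interface
#'   fields.
#' @export
tmmin_for_template <- function(model_a, model_b, dimer, pair_id = "pair") {
  stopifnot(inherits(dimer, "dimer_record"))
  A <- as_chain(model_a); B <- as_chain(model_b)
  al <- list(
    ax = align_structures(A, dimer$chain_x),
    by = align_structures(B, dimer$chain_y),
    ay = align_structures(A, dimer$chain_y),
    bx = align_structures(B, dimer$chain_x)
  )
  s1 <- min(al$ax$tm_score, al$by$tm_score)
  s2 <- min(al$ay$tm_score, al$bx$tm_score)
  if (s1 >= s2) {
    hit <- list(pair_id = pair_id, template_id = dimer$id,
                assignment = "AX/BY",
                tm_a = al$ax$tm_score, tm_b = al$by$tm_score, tmmin = s1,
                alignment_a = al$ax, alignment_b = al$by)
  } else {
    hit <- list(pair_id = pair_id, template_id = dimer$id,
                assignment = "AY/BX",
                tm_a = al$ay$tm_score, tm_b = al$bx$tm_score, tmmin = s2,
                alignment_a = al$ay, alignment_b = al$bx)
  }
  hit$valid_interface <- NA
  hit$interface_size <- NA_integer_
  hit$clash_count <- NA_integer_
  class(hit) <- "precedent_hit"
  hit
}

#' @export
print.precedent_hit <- function(x, ...) {
  cat(sprintf(
    "<precedent hit %s ~ %s (%s): TMmin %.3f (tm_a %.3f, tm_b %.3f)>\n",
    x$pair_id, x$template_id, x$assignment, x$tmmin, x$tm_a, x$tm_b))
  invisible(x)
}

#' Build the interaction model for a precedent hit
#'
#' Each monomer is moved by its alignment's rigid transform into the
#' template frame; the result is a hypothetical two-chain complex (chain
#' ids "A" and "B"). Template coordinates themselves are not part of the
#' model.
#'
#' @param model_a,model_b the monomer models used to produce `hit`.
#' @param dimer the template [dimer_record()].
#' @param hit the [tmmin_for_template()] result for this pair/template.
#' @return an object of class `interaction_model`: list with `structure`
#'   (two-chain `prot_structure`) and `provenance` (the hit).
#' @export
build_interaction_model <- function(model_a, model_b, dimer, hit) {
  stopifnot(inherits(hit, "precedent_hit"), inherits(dimer, "dimer_record"))
  if (hit$template_id != dimer$id) {
    stop("hit refers to template ", hit$template_id, ", not ", dimer$id)
  }
  if (is.null(hit$alignment_a) || is.null(hit$alignment_b)) {
    stop("hit carries no alignments")
  }
  A <- as_chain(model_a); B <- as_chain(model_b)
  ca <- transform_chain(A, hit$alignment_a$rotation,
                        hit$alignment_a$translation)
  cb <- transform_chain(B, hit$alignment_b$rotation,
                        hit$alignment_b$translation)
  ca$id <- "A"; cb$id <- "B"
  st <- new_structure(paste(hit$pair_id, dimer$id, sep = "__"),
                      list(ca, cb))
  structure(list(structure = st, provenance = hit),
            class = "interaction_model")
}

#' Validate the interface of an interaction model
#'
#' An interaction model is accepted when its interface has at least
#' `min_interface` residues (both chains pooled, any-atom distance below
#' `contact_cutoff`) and no more than `max_clashes` inter-chain CA pairs
#' closer than `clash_cutoff` ("less than three clashes" by default).
#'
#' @param model an [build_interaction_model()] result (or a two-chain
#'   `prot_structure`).
#' @param contact_cutoff interface distance cutoff, Angstrom.
#' @param min_interface minimum pooled interface residue count.
#' @param clash_cutoff CA-CA clash distance, Angstrom.
#' @param max_clashes maximum tolerated clash count.
#' @return list with `valid`, `interface_size`, `clash_count` and the
#'   per-chain counts `interface_a`, `interface_b`.
#' @export
validate_interface <- function(model, contact_cutoff = 5,
                               min_interface = 20L, clash_cutoff = 3.0,
                               max_clashes = 2L) {
  st <- if (inherits(model, "interaction_model")) model$structure else model
  stopifnot(inherits(st, "prot_structure"))
  if (length(st$chains) != 2L) stop("model must have exactly two chains")
  ir <- interface_residues(st, cutoff = contact_cutoff)
  n_a <- length(ir[[1]]); n_b <- length(ir[[2]])
  size <- n_a + n_b
  clashes <- ca_clash_count(st$chains[[1]], st$chains[[2]],
                            cutoff = clash_cutoff)
  list(valid = (size >= min_interface) && (clashes <= max_clashes),
       interface_size = size, clash_count = clashes,
       interface_a = n_a, interface_b = n_b)
}

## normalize a models argument to a list of chains
as_model_list <- function(x) {
  if (is.null(x)) return(list())
  if (inherits(x, "prot_chain") || inherits(x, "prot_structure")) {
    x <- list(x)
  }
  lapply(x, as_chain)
}

#' Find the best structural precedent for a protein pair
#'
#' Every combination of a model for protein A, a model for protein B and a
#' library dimer is scored by TMmin (both chain assignments). Hits with
#' TMmin at or above `threshold` are ranked by decreasing TMmin (ties:
#' template id lexicographic, then assignment order, then model
#' combination order) and the first hit whose built interaction model
#' passes [validate_interface()] is returned.
#'
#' @param models_a,models_b lists of candidate monomer models (several
#'   homology models per protein are allowed); empty lists yield the
#'   distinct `"no_models"` outcome.
#' @param library list of [dimer_record()] templates (non-empty).
#' @param threshold TMmin cutoff (default 0.6).
#' @param pair_id identifier carried into hits.
#' @return an object of class `precedent_result`: list with `status`
#'   (`"precedent"`, `"no_precedent"` or `"no_models"`), `hit` (validated
#'   `precedent_hit` or `NULL`) and `model` (the accepted
#'   `interaction_model` or `NULL`).
#' @export
find_precedents <- function(models_a, models_b, library, threshold = 0.6,
                            pair_id = "pair") {
  if (!length(library)) stop("template library is empty")
  ma <- as_model_list(models_a); mb <- as_model_list(models_b)
  if (!length(ma) || !length(mb)) {
    return(structure(list(status = "no_models", hit = NULL, model = NULL),
                     class = "precedent_result"))
  }
  hits <- list(); keys <- list()
  for (ia in seq_along(ma)) {
    for (ib in seq_along(mb)) {
      for (dm in library) {
        hit <- tmmin_for_template(ma[[ia]], mb[[ib]], dm, pair_id = pair_id)
        hits[[length(hits) + 1L]] <- hit
        keys[[length(keys) + 1L]] <-
          list(tmmin = hit$tmmin, template = dm$id,
               assign = hit$assignment, combo = (ia - 1L) * length(mb) + ib,
               dimer = dm, ia = ia, ib = ib)
      }
    }
  }
  tm <- vapply(keys, `[[`, numeric(1), "tmmin")
  keep <- which(tm >= threshold)
  if (!length(keep)) {
    return(structure(list(status = "no_precedent", hit = NULL, model = NULL),
                     class = "precedent_result"))
  }
  ord <- keep[order(-tm[keep],
                    vapply(keys[keep], `[[`, character(1), "template"),
                    vapply(keys[keep], `[[`, character(1), "assign"),
                    vapply(keys[keep], `[[`, numeric(1), "combo"))]
  for (i in ord) {
    k <- keys[[i]]
    im <- build_interaction_model(ma[[k$ia]], mb[[k$ib]], k$dimer, hits[[i]])
    v <- validate_interface(im)
    hit <- hits[[i]]
    hit$valid_interface <- v$valid
    hit$interface_size <- v$interface_size
    hit$clash_count <- v$clash_count
    if (v$valid) {
      im$provenance <- hit
      return(structure(list(status = "precedent", hit = hit, model = im),
                       class = "precedent_result"))
    }
  }
  structure(list(status = "no_precedent", hit = NULL, model = NULL),
            class = "precedent_result")
}

#' @export
print.precedent_result <- function(x, ...) {
  cat("<precedent result:", x$status, ">\n")
  if (!is.null(x$hit)) print(x$hit)
  invisible(x)
}

#' Screen every pair of a benchmark (or pair table) for precedents
#'
#' Runs [find_precedents()] for each pair at a low scan floor and records
#' the best *valid* hit, so detection rates at any threshold at or above
#' the floor can be read off the result (a pair counts at threshold t iff
#' its best valid TMmin is >= t).
#'
#' @param pairs data.frame with columns `pair_id`, `id_a`, `id_b` (e.g.
#'   `benchmark$pairs`), or a `precedent_benchmark` (then `models` and
#'   `library` default to its components).
#' @param models named list: protein id -> list of monomer models.
#' @param library list of [dimer_record()].
#' @param threshold_floor lowest TMmin recorded (default 0.3).
#' @return data.frame with one row per pair: `pair_id`, `status`,
#'   `template_id`, `tmmin`, `tm_a`, `tm_b`, `interface_size`,
#'   `clash_count` (`tmmin` is `NA` when no valid precedent exists at the
#'   floor).
#' @export
precedent_scan <- function(pairs, models = NULL, library = NULL,
                           threshold_floor = 0.3) {
  if (inherits(pairs, "precedent_benchmark")) {
    models <- models %||% pairs$models
    library <- library %||% pairs$library
    pairs <- pairs$pairs
  }
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "id_a", "id_b") %in% names(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pid <- pairs$pair_id[i]
    res <- find_precedents(models[[pairs$id_a[i]]], models[[pairs$id_b[i]]],
                           library, threshold = threshold_floor,
                           pair_id = pid)
    if (res$status == "precedent") {
      h <- res$hit
      data.frame(pair_id = pid, status = "precedent",
                 template_id = h$template_id, tmmin = h$tmmin,
                 tm_a = h$tm_a, tm_b = h$tm_b,
                 interface_size = h$interface_size,
                 clash_count = h$clash_count, stringsAsFactors = FALSE)
    } else {
      data.frame(pair_id = pid, status = res$status,
                 template_id = NA_character_, tmmin = NA_real_,
                 tm_a = NA_real_, tm_b = NA_real_,
                 interface_size = NA_integer_, clash_count = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
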