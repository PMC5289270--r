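## Containers for macromolecular coordinates.
##
## A chain stores its atoms in one data.frame (resno, resname, name, elem,
## x, y, z) with residues numbered sequentially from 1; a structure is an
## ordered list of chains with unique one-character ids.

#' Create a protein chain
#'
#' A chain is an ordered set of residues, each with named atoms and 3D
#' coordinates in Angstrom. Residue numbers must be strictly increasing and
#' atoms of one residue must be contiguous.
#'
#' @param id single-character chain identifier.
#' @param atoms data.frame with columns `resno` (integer), `resname`
#'   (3-letter code), `name` (atom label, e.g. `"CA"`), `elem` (element
#'   symbol) and coordinates `x`, `y`, `z` in Angstrom.
#' @param auth_resno optional vector of author residue numbers (recorded,
#'   not used by any computation).
#' @return an object of class `prot_chain`.
#' @export
new_chain <- function(id, atoms, auth_resno = NULL) {
  if (!is.character(id) || length(id) != 1L || nchar(id) != 1L) {
    stop("chain id must be a single character")
  }
  req <- c("resno", "resname", "name", "elem", "x", "y", "z")
  if (!is.data.frame(atoms) || !all(req %in% names(atoms))) {
    stop("atoms must be a data.frame with columns ",
         paste(req, collapse = ", "))
  }
  if (nrow(atoms) < 1L) stop("chain must contain at least one atom")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("atom coordinates must be finite")
  r <- rle(as.integer(atoms$resno))$values
  if (any(diff(r) <= 0L)) {
    stop("residue numbers must be strictly increasing within a chain")
  }
  atoms$resno <- as.integer(atoms$resno)
  rownames(atoms) <- NULL
  obj <- list(id = id, atoms = atoms)
  if (!is.null(auth_resno)) obj$auth_resno <- auth_resno
  class(obj) <- "prot_chain"
  obj
}

#' Create a structure from chains
#'
#' @param id structure identifier.
#' @param chains list of [new_chain()] objects with unique ids.
#' @return an object of class `prot_structure`.
#' @export
new_structure <- function(id, chains) {
  if (!is.character(id) || length(id) != 1L) stop("id must be a string")
  if (!length(chains)) stop("a structure needs at least one chain")
  if (!all(vapply(chains, inherits, logical(1), "prot_chain"))) {
    stop("chains must be prot_chain objects")
  }
  ids <- vapply(chains, function(ch) ch$id, character(1))
  if (anyDuplicated(ids)) stop("chain ids must be unique within a structure")
  names(chains) <- ids
  structure(list(id = id, chains = chains), class = "prot_structure")
}

#' @export
print.prot_chain <- function(x, ...) {
  cat(sprintf("<chain %s: %d residues, %d atoms>\n",
              x$id, chain_length(x), nrow(x$atoms)))
  invisible(x)
}

#' @export
print.prot_structure <- function(x, ...) {
  cat(sprintf("<structure %s: %d chain(s)>\n", x$id, length(x$chains)))
  for (ch in x$chains) print(ch)
  invisible(x)
}

#' Number of residues in a chain
#' @param chain a `prot_chain`.
#' @export
chain_length <- function(chain) {
  stopifnot(inherits(chain, "prot_chain"))
  length(unique(chain$atoms$resno))
}

#' C-alpha coordinates of a chain
#'
#' @param chain a `prot_chain`.
#' @return numeric matrix (one row per residue carrying a CA atom), in
#'   residue order.
#' @export
ca_xyz <- function(chain) {
  stopifnot(inherits(chain, "prot_chain"))
  ca <- chain$atoms[chain$atoms$name == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("chain ", chain$id, " has no CA atoms")
  as.matrix(ca[, c("x", "y", "z")])
}

## per-residue table (resno, resname) in order
residue_table <- function(chain) {
  a <- chain$atoms
  keep <- !duplicated(a$resno)
  data.frame(resno = a$resno[keep], resname = a$resname[keep],
             stringsAsFactors = FALSE)
}

atom_xyz <- function(chain) as.matrix(chain$atoms[, c("x", "y", "z")])

## Apply a rigid transform y = R x + t to every atom of a chain.
transform_chain <- function(chain, rotation, translation) {
  xyz <- atom_xyz(chain) %*% t(rotation)
  xyz <- sweep(xyz, 2, translation, "+")
  chain$atoms$x <- xyz[, 1]
  chain$atoms$y <- xyz[, 2]
  chain$atoms$z <- xyz[, 3]
  chain
}

## Accept a prot_chain or a single-chain prot_structure.
as_chain <- function(x) {
  if (inherits(x, "prot_chain")) return(x)
  if (inherits(x, "prot_structure")) {
    if (length(x$chains) != 1L) {
      stop("expected a single-chain structure, got ", length(x$chains),
           " chains")
    }
    return(x$chains[[1L]])
  }
  stop("expected a prot_chain or single-chain prot_structure")
}

#' Declare a homology model and its target coverage
#'
#' Homology models rarely span the full target sequence; models covering
#' too little of the target are excluded from precedent searches by
#' [filter_models_by_coverage()].
#'
#' @param structure a `prot_structure` holding the modelled coordinates.
#' @param target_length residue count of the full-length target protein.
#' @return an object of class `homology_model` with fields `structure`,
#'   `target_length` and `coverage` (modelled residues / target length).
#' @export
homology_model <- function(structure, target_length) {
  stopifnot(inherits(structure, "prot_structure"))
  if (!is.numeric(target_length) || length(target_length) != 1L ||
      target_length < 1) {
    stop("target_length must be a positive count")
  }
  modelled <- sum(vapply(structure$chains, chain_length, integer(1)))
  coverage <- modelled / target_length
  if (coverage <= 0 || coverage > 1) {
    stop("coverage must lie in (0, 1]; got ", signif(coverage, 3))
  }
  structure(list(structure = structure, target_length = as.integer(target_length),
                 coverage = coverage), class = "homology_model")
}

#' Filter homology models by target coverage
#'
#' Retains models whose coverage (modelled residues over full target
#' length) is at least `min_coverage`; a model covering exactly the
#' threshold is kept. Order is preserved.
#'
#' @param models list of [homology_model()] objects.
#' @param min_coverage minimum retained coverage fraction (default 0.4,
#'   i.e. models covering less than 40% of the target are excluded).
#' @return the retained sublist.
#' @export
filter_models_by_coverage <- function(models, min_coverage = 0.4) {
  if (!length(models)) return(models)
  if (!all(vapply(models, inherits, logical(1), "homology_model"))) {
    stop("models must be homology_model objects")
  }
  cov <- vapply(models, function(m) m$coverage, numeric(1))
  if (any(cov <= 0 | cov > 1)) stop("model coverage must lie in (0, 1]")
  models[cov >= min_coverage]
}
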