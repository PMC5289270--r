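## PDB and table I/O. Coordinate files go through bio3d; a light pre-scan
## gives line-numbered errors for malformed ATOM records.

#' Read a PDB file into a structure
#'
#' Reads ATOM records only: HETATM groups and waters are skipped, alternate
#' locations other than the first and atoms with insertion codes are
#' dropped (with a warning). Residues are renumbered sequentially from 1
#' within each chain; the author numbering is kept in the chain's
#' `auth_resno` field but never used by computations.
#'
#' @param path path to a PDB-format file.
#' @return a [new_structure()] object.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_atom <- startsWith(lines, "ATOM  ") | startsWith(lines, "ATOM ")
  if (!any(is_atom)) stop("no ATOM records in ", path)
  ## validate the coordinate columns of every ATOM record
  for (i in which(is_atom)) {
    ln <- lines[i]
    for (cols in list(c(31, 38), c(39, 46), c(47, 54))) {
      fld <- substr(ln, cols[1], cols[2])
      if (is.na(suppressWarnings(as.numeric(fld)))) {
        stop(sprintf("malformed coordinate field at line %d of %s: '%s'",
                     i, path, fld))
      }
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, verbose = FALSE))
  at <- pdb$atom
  n_het <- sum(at$type != "ATOM")
  if (n_het > 0) {
    warning(n_het, " HETATM/water records skipped in ", basename(path))
  }
  at <- at[at$type == "ATOM" & !(at$resid %in% c("HOH", "WAT")), ,
           drop = FALSE]
  ins <- !is.na(at$insert) & at$insert != ""
  if (any(ins)) {
    warning(sum(ins), " atoms with insertion codes dropped in ",
            basename(path))
    at <- at[!ins, , drop = FALSE]
  }
  if (nrow(at) == 0L) stop("no usable ATOM records in ", path)
  chains <- list()
  for (ch in unique(at$chain)) {
    sub <- at[at$chain %in% ch, , drop = FALSE]
    ## sequential residue index in order of appearance
    key <- sub$resno
    blocks <- c(TRUE, key[-1] != key[-length(key)])
    seq_res <- cumsum(blocks)
    elem <- sub$elesy
    if (is.null(elem) || all(is.na(elem)) || all(elem == "")) {
      elem <- substr(trimws(sub$elety), 1, 1)
    } else {
      miss <- is.na(elem) | elem == ""
      elem[miss] <- substr(trimws(sub$elety[miss]), 1, 1)
    }
    atoms <- data.frame(
      resno = as.integer(seq_res),
      resname = sub$resid,
      name = trimws(sub$elety),
      elem = toupper(trimws(elem)),
      x = sub$x, y = sub$y, z = sub$z,
      stringsAsFactors = FALSE
    )
    id <- if (is.na(ch) || ch == "" || ch == " ") "A" else ch
    chains[[length(chains) + 1L]] <-
      new_chain(id, atoms, auth_resno = sub$resno[blocks])
  }
  nonstd <- unique(unlist(lapply(chains, function(c2) {
    rt <- residue_table(c2)
    rt$resname[!is_standard_aa(rt$resname)]
  })))
  if (length(nonstd)) {
    warning("nonstandard residue names kept for geometry, excluded from ",
            "class-based descriptors: ", paste(nonstd, collapse = ", "))
  }
  id <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  new_structure(id, chains)
}

#' Write a structure to a PDB file
#'
#' Emits standard ATOM records (coordinates to 3 decimals) with one TER
#' record between consecutive chains.
#'
#' @param structure a `prot_structure`.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pdb <- function(structure, path) {
  stopifnot(inherits(structure, "prot_structure"))
  atoms <- do.call(rbind, lapply(structure$chains, function(ch) {
    cbind(ch$atoms, chain = ch$id, stringsAsFactors = FALSE)
  }))
  n <- nrow(atoms)
  if (n > 99999L) stop("PDB format limit exceeded: ", n, " atoms (> 99999)")
  xyz <- as.vector(t(as.matrix(atoms[, c("x", "y", "z")])))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    resno = atoms$resno, resid = atoms$resname,
    eleno = seq_len(n), elety = atoms$name,
    chain = atoms$chain, elesy = atoms$elem,
    chainter = TRUE, end = TRUE
  )
  invisible(path)
}

#' Read / write protein pair tables
#'
#' Pair tables are TSV files with a header and columns `id_a`, `id_b` and
#' optionally `label` (plus any further annotation columns, which are kept).
#'
#' @param path file path.
#' @return data.frame of pairs.
#' @export
read_pairs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id_a", "id_b") %in% names(df))) {
    stop("pair table must have columns id_a and id_b: ", path)
  }
  df
}

#' @param pairs data.frame with columns `id_a`, `id_b` (and extras).
#' @rdname read_pairs
#' @export
write_pairs <- function(pairs, path) {
  stopifnot(all(c("id_a", "id_b") %in% names(pairs)))
  write.table(pairs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write long-format annotation tables
#'
#' Annotations are TSV files with header columns `id`, `key`, `value`;
#' repeated keys per id (e.g. several localizations or terms) occupy
#' several rows.
#'
#' @param path file path.
#' @return data.frame with columns id, key, value.
#' @export
read_annotations <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id", "key", "value") %in% names(df))) {
    stop("annotation table must have columns id, key, value: ", path)
  }
  df
}

#' @param annotations data.frame with columns `id`, `key`, `value`.
#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  stopifnot(all(c("id", "key", "value") %in% names(annotations)))
  write.table(annotations, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read / write an edge-list network
#'
#' Two-column TSV (`id_a`, `id_b`), one undirected edge per row.
#'
#' @param path file path.
#' @return an igraph object.
#' @export
read_network_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs two columns: ", path)
  igraph::graph_from_data_frame(df[, 1:2], directed = FALSE)
}

#' @param g an igraph object.
#' @rdname read_network_tsv
#' @export
write_network_tsv <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(id_a = el[, 1], id_b = el[, 2],
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
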