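## Interface descriptors: interface residues, Shrake-Rupley accessible
## surface area, buried-surface hydrophobicity, grid-based gap volume /
## gap index, and amino-acid-class contact signatures.

two_chains <- function(x) {
  st <- if (inherits(x, "interaction_model")) x$structure else x
  stopifnot(inherits(st, "prot_structure"))
  if (length(st$chains) != 2L) stop("expected a two-chain model")
  st
}

#' Interface residues of a two-chain model
#'
#' Residues having any atom within `cutoff` of any atom of the partner
#' chain.
#'
#' @param model an `interaction_model` or two-chain `prot_structure`.
#' @param cutoff distance threshold in Angstrom (default 5).
#' @return named list (by chain id) of interface residue numbers.
#' @export
interface_residues <- function(model, cutoff = 5) {
  st <- two_chains(model)
  a <- st$chains[[1]]; b <- st$chains[[2]]
  d2 <- cross_dist2(atom_xyz(a), atom_xyz(b))
  hit <- which(d2 < cutoff^2, arr.ind = TRUE)
  res_a <- sort(unique(a$atoms$resno[hit[, 1]]))
  res_b <- sort(unique(b$atoms$resno[hit[, 2]]))
  setNames(list(res_a, res_b), c(a$id, b$id))
}

## deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

atom_radii <- function(elem, context = "") {
  r <- VDW_RADII[elem]
  if (anyNA(r)) {
    bad <- unique(elem[is.na(r)])
    stop("no van der Waals radius for element(s): ",
         paste(bad, collapse = ", "), if (nzchar(context)) paste0(" (", context, ")"))
  }
  unname(r)
}

#' Solvent accessible surface area (Shrake-Rupley)
#'
#' Numerical sphere-sampling ASA with a water-sized probe. Radii: C 1.87,
#' N 1.65, O 1.40, S 1.85 Angstrom.
#'
#' @param structure a `prot_structure` (all chains pooled) or
#'   `prot_chain`.
#' @param probe probe radius, Angstrom (default 1.4).
#' @param n_points sample points per atom sphere (default 960).
#' @return data.frame with one row per residue: `chain`, `resno`,
#'   `resname`, `asa` (Angstrom^2); total ASA as attribute `total`.
#' @export
accessible_surface <- function(structure, probe = 1.4, n_points = 960L) {
  if (inherits(structure, "prot_chain")) {
    structure <- new_structure("chain", list(structure))
  }
  stopifnot(inherits(structure, "prot_structure"))
  atoms <- do.call(rbind, lapply(structure$chains, function(ch) {
    cbind(ch$atoms, chain = ch$id, stringsAsFactors = FALSE)
  }))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  rad <- atom_radii(atoms$elem, context = "accessible_surface")
  n <- nrow(atoms)
  pts <- sphere_points(n_points)
  ## neighbor lists: atoms whose expanded spheres can intersect
  d2 <- cross_dist2(xyz, xyz)
  rsum <- outer(rad + probe, rad + probe, "+")
  nb <- d2 < rsum^2
  diag(nb) <- FALSE
  asa <- numeric(n)
  for (i in seq_len(n)) {
    ri <- rad[i] + probe
    js <- which(nb[i, ])
    area_i <- 4 * pi * ri^2
    if (!length(js)) { asa[i] <- area_i; next }
    p <- sweep(pts * ri, 2, xyz[i, ], "+")
    buried <- rep(FALSE, n_points)
    for (j in js) {
      rj <- rad[j] + probe
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      buried <- buried | (dj2 < rj^2)
      if (all(buried)) break
    }
    asa[i] <- area_i * (1 - mean(buried))
  }
  key <- paste(atoms$chain, atoms$resno)
  keep <- !duplicated(key)
  out <- data.frame(chain = atoms$chain[keep], resno = atoms$resno[keep],
                    resname = atoms$resname[keep],
                    asa = as.numeric(tapply(asa, factor(key, levels = key[keep]),
                                            sum)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "total") <- sum(asa)
  out
}

#' Interface hydrophobicity and buried surface area
#'
#' Per-residue buried area `dASA = ASA(isolated chain) - ASA(complex)`
#' (floored at 0). Hydrophobicity is the fraction of total buried area
#' contributed by hydrophobic residues (A, V, L, I, P, F, M, W, C);
#' nonstandard residues are excluded from this class-based descriptor.
#' The interface ASA uses the symmetric convention `sum(dASA) / 2`.
#'
#' @param model an `interaction_model` or two-chain `prot_structure`.
#' @param probe,n_points passed to [accessible_surface()].
#' @return list with `hydrophobicity` (fraction, `NA` if there is no
#'   buried surface), `interface_asa` (Angstrom^2, halved sum),
#'   `delta_total` (unhalved sum), and `per_residue` (data.frame with the
#'   dASA terms).
#' @export
interface_hydrophobicity <- function(model, probe = 1.4, n_points = 960L) {
  st <- two_chains(model)
  cpx <- accessible_surface(st, probe = probe, n_points = n_points)
  iso <- do.call(rbind, lapply(st$chains, function(ch) {
    accessible_surface(ch, probe = probe, n_points = n_points)
  }))
  key_c <- paste(cpx$chain, cpx$resno)
  key_i <- paste(iso$chain, iso$resno)
  m <- match(key_c, key_i)
  stopifnot(!anyNA(m))
  d <- pmax(iso$asa[m] - cpx$asa, 0)
  per <- data.frame(chain = cpx$chain, resno = cpx$resno,
                    resname = cpx$resname, asa_iso = iso$asa[m],
                    asa_cpx = cpx$asa, dasa = d, stringsAsFactors = FALSE)
  std <- is_standard_aa(per$resname)
  denom <- sum(d[std])
  if (denom <= 0) {
    warning("no buried surface area: hydrophobicity undefined")
    hyd <- NA_real_
  } else {
    hyd <- sum(d[std & aa_one_letter(per$resname) %in% HYDROPHOBIC_AA]) /
      denom
  }
  list(hydrophobicity = hyd, interface_asa = sum(d) / 2,
       delta_total = sum(d), per_residue = per)
}

#' Gap volume between the two interface surfaces
#'
#' Grid method: a regular grid covers the overlap of the two chains'
#' bounding boxes (padded by `shell`). A voxel is *gap* when it lies
#' outside every atom's probe-expanded sphere and its nearest-atom
#' distance to chain 1 and to chain 2 are both at most `shell`.
#' `gap_volume = gap voxel count x spacing^3`. This is a comparable but
#' not identical quantity to sphere-shrinking gap volumes.
#'
#' @param model an `interaction_model` or two-chain `prot_structure`.
#' @param grid_spacing voxel edge, Angstrom (default 1.0).
#' @param shell maximum distance from each chain, Angstrom (default 5.0).
#' @param probe sphere expansion added to atom radii (default 1.4).
#' @param interface_asa optional interface ASA (Angstrom^2) used to derive
#'   the gap index; when missing, `gap_index` is `NA`.
#' @return list with `gap_volume` (Angstrom^3), `gap_index`
#'   (`gap_volume / interface_asa`, Angstrom) and `n_voxels`.
#' @export
gap_volume <- function(model, grid_spacing = 1.0, shell = 5.0, probe = 1.4,
                       interface_asa = NULL) {
  st <- two_chains(model)
  x1 <- atom_xyz(st$chains[[1]]); x2 <- atom_xyz(st$chains[[2]])
  r1 <- atom_radii(st$chains[[1]]$atoms$elem, "gap_volume")
  r2 <- atom_radii(st$chains[[2]]$atoms$elem, "gap_volume")
  pad <- shell + grid_spacing
  lo <- pmax(apply(x1, 2, min), apply(x2, 2, min)) - pad
  hi <- pmin(apply(x1, 2, max), apply(x2, 2, max)) + pad
  empty <- list(gap_volume = 0, gap_index = if (is.null(interface_asa))
    NA_real_ else 0, n_voxels = 0L)
  if (any(hi <= lo)) return(empty)
  gx <- seq(lo[1], hi[1], by = grid_spacing)
  gy <- seq(lo[2], hi[2], by = grid_spacing)
  gz <- seq(lo[3], hi[3], by = grid_spacing)
  grid <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  ## only atoms near the box matter
  near_box <- function(x, r) {
    inb <- x[, 1] > lo[1] - (r + probe + shell) &
      x[, 1] < hi[1] + (r + probe + shell) &
      x[, 2] > lo[2] - (r + probe + shell) &
      x[, 2] < hi[2] + (r + probe + shell) &
      x[, 3] > lo[3] - (r + probe + shell) &
      x[, 3] < hi[3] + (r + probe + shell)
    which(inb)
  }
  k1 <- near_box(x1, max(r1)); k2 <- near_box(x2, max(r2))
  if (!length(k1) || !length(k2)) return(empty)
  ## nearest-atom distance is measured to the atom surface (d - r), so the
  ## shell tracks the chain surface rather than atom centers; the nearest
  ## atom itself is kept to decide whether the voxel lies *between* the
  ## chains (and not in the solvent shell wrapped around both)
  min_and_clear <- function(xs, rs) {
    nv <- nrow(grid)
    dmin <- rep(Inf, nv)
    nearest <- rep(1L, nv)
    outside <- rep(TRUE, nv)
    for (j in seq_len(nrow(xs))) {
      dj <- sqrt((grid[, 1] - xs[j, 1])^2 + (grid[, 2] - xs[j, 2])^2 +
                   (grid[, 3] - xs[j, 3])^2)
      upd <- dj - rs[j] < dmin
      dmin[upd] <- dj[upd] - rs[j]
      nearest[upd] <- j
      outside <- outside & (dj >= rs[j] + probe)
    }
    list(dmin = dmin, nearest = nearest, outside = outside)
  }
  xs1 <- x1[k1, , drop = FALSE]; xs2 <- x2[k2, , drop = FALSE]
  a1 <- min_and_clear(xs1, r1[k1])
  a2 <- min_and_clear(xs2, r2[k2])
  v1 <- xs1[a1$nearest, , drop = FALSE] - grid
  v2 <- xs2[a2$nearest, , drop = FALSE] - grid
  between <- rowSums(v1 * v2) < 0
  gap <- a1$outside & a2$outside & a1$dmin <= shell & a2$dmin <= shell &
    between
  vol <- sum(gap) * grid_spacing^3
  gi <- if (is.null(interface_asa)) NA_real_ else {
    if (interface_asa <= 0) {
      warning("zero interface ASA: gap index undefined")
      NA_real_
    } else vol / interface_asa
  }
  list(gap_volume = vol, gap_index = gi, n_voxels = sum(gap))
}

#' Contact signature of an interface
#'
#' Symmetric 7 x 7 matrix counting inter-chain residue contacts (CA-CA
#' distance below `cutoff`) by amino-acid class pair. Classes:
#' \{V,I,M,C,L\}, \{A,S,P,T\}, \{G\}, \{Y,F,W\}, \{K,R,H\}, \{D,E\},
#' \{N,Q\}; nonstandard residues are skipped. A same-class contact counts
#' once on the diagonal; a cross-class contact fills both mirror cells.
#'
#' @param model an `interaction_model` or two-chain `prot_structure`.
#' @param cutoff CA-CA contact distance, Angstrom (default 12).
#' @return an integer matrix of class `contact_signature`.
#' @export
contact_signature <- function(model, cutoff = 12) {
  st <- two_chains(model)
  a <- st$chains[[1]]; b <- st$chains[[2]]
  cls_a <- aa_class(residue_table(a)$resname)
  cls_b <- aa_class(residue_table(b)$resname)
  ## CA per residue (residues without CA cannot contribute)
  ca_a <- a$atoms[a$atoms$name == "CA", , drop = FALSE]
  ca_b <- b$atoms[b$atoms$name == "CA", , drop = FALSE]
  ia <- match(ca_a$resno, residue_table(a)$resno)
  ib <- match(ca_b$resno, residue_table(b)$resno)
  M <- matrix(0L, 7, 7,
              dimnames = list(names(AA_CLASS_GROUPS), names(AA_CLASS_GROUPS)))
  if (nrow(ca_a) && nrow(ca_b)) {
    d2 <- cross_dist2(as.matrix(ca_a[, c("x", "y", "z")]),
                      as.matrix(ca_b[, c("x", "y", "z")]))
    hit <- which(d2 < cutoff^2, arr.ind = TRUE)
    for (r in seq_len(nrow(hit))) {
      ci <- cls_a[ia[hit[r, 1]]]; cj <- cls_b[ib[hit[r, 2]]]
      if (is.na(ci) || is.na(cj)) next
      M[ci, cj] <- M[ci, cj] + 1L
      if (ci != cj) M[cj, ci] <- M[cj, ci] + 1L
    }
  }
  class(M) <- c("contact_signature", class(M))
  M
}

#' Distance between two contact signatures
#'
#' Cosine distance on the flattened upper triangle (diagonal included):
#' 0 when the interfaces have identical contact-type composition, 1 when
#' they share no contact type.
#'
#' @param s1,s2 [contact_signature()] matrices (7 x 7, non-negative; at
#'   least one non-zero entry each).
#' @return distance in \[0, 1\].
#' @export
signature_distance <- function(s1, s2) {
  s1 <- unclass(s1); s2 <- unclass(s2)
  stopifnot(is.matrix(s1), is.matrix(s2),
            all(dim(s1) == dim(s2)))
  ut <- upper.tri(s1, diag = TRUE)
  v1 <- as.numeric(s1[ut]); v2 <- as.numeric(s2[ut])
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    stop("signature distance is undefined for an all-zero contact matrix")
  }
  d <- 1 - sum(v1 * v2) / (n1 * n2)
  min(max(d, 0), 1)
}

#' All interface descriptors of an interaction model
#'
#' Convenience wrapper computing interface size, interface ASA,
#' hydrophobicity, gap volume and gap index in one pass.
#'
#' @param model an `interaction_model` or two-chain `prot_structure`.
#' @param contact_cutoff interface residue cutoff (default 5 Angstrom).
#' @param n_points ASA sampling density.
#' @param grid_spacing gap-volume voxel edge.
#' @return one-row data.frame: `interface_size`, `interface_asa`,
#'   `hydrophobicity`, `gap_volume`, `gap_index`.
#' @export
interface_descriptors <- function(model, contact_cutoff = 5,
                                  n_points = 960L, grid_spacing = 1.0) {
  ir <- interface_residues(model, cutoff = contact_cutoff)
  hy <- interface_hydrophobicity(model, n_points = n_points)
  gv <- gap_volume(model, grid_spacing = grid_spacing,
                   interface_asa = hy$interface_asa)
  data.frame(interface_size = length(ir[[1]]) + length(ir[[2]]),
             interface_asa = hy$interface_asa,
             hydrophobicity = hy$hydrophobicity,
             gap_volume = gv$gap_volume,
             gap_index = gv$gap_index)
}
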