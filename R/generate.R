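## Synthetic-data generators: backbone chains built from ideal secondary
## structure segments, rigid-body-docked dimers, perturbed "homology
## model" copies, benchmark sets with planted precedents, scale-free
## networks and annotation tables. Everything is deterministic given
## (config, seed) and never touches the caller's RNG stream.

#' Generator configuration
#'
#' Bundles the knobs of the synthetic benchmark. Defaults describe a small
#' dimer library whose members all satisfy the library inclusion rule
#' (more than 10 inter-chain residue contacts at 5 Angstrom) and monomer
#' models perturbed by sub-Angstrom noise, i.e. good homology models.
#'
#' @param seed integer seed; all generator randomness flows from it.
#' @param noise_sigma per-coordinate Gaussian noise (Angstrom) applied when
#'   deriving monomer models from template chains.
#' @param n_dimers number of dimer templates in the library.
#' @param chain_length_range integer 2-vector, min/max residues per chain
#'   (both at least 20).
#' @param contact_target minimum inter-chain residue contacts at 5 Angstrom
#'   a generated dimer must reach (strictly more than 10).
#' @param compat_frac fraction of negative pairs built as
#'   structure-compatible negatives (chains drawn from two different dimers
#'   of one fold family).
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L, noise_sigma = 0.3, n_dimers = 6L,
                             chain_length_range = c(30L, 60L),
                             contact_target = 40L, compat_frac = 0.2) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (length(chain_length_range) != 2L ||
      any(chain_length_range < 20L) ||
      chain_length_range[1] > chain_length_range[2]) {
    stop("chain_length_range must be (min, max) with min >= 20")
  }
  if (contact_target <= 10) stop("contact_target must be > 10")
  if (n_dimers < 1) stop("n_dimers must be >= 1")
  if (compat_frac < 0 || compat_frac > 1) stop("compat_frac must be in [0,1]")
  structure(list(seed = as.integer(seed), noise_sigma = noise_sigma,
                 n_dimers = as.integer(n_dimers),
                 chain_length_range = as.integer(chain_length_range),
                 contact_target = as.integer(contact_target),
                 compat_frac = compat_frac),
            class = "generator_config")
}

#' Read a generator configuration from a YAML file
#'
#' The file may define any subset of the [generator_config()] fields;
#' unspecified fields keep their defaults.
#'
#' @param path YAML file path.
#' @return a `generator_config`.
#' @export
read_generator_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(generator_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config fields: ", paste(extra, collapse = ", "))
  do.call(generator_config, vals)
}

## uniform random rotation matrix (via a random unit quaternion)
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

random_unit_vector <- function() unit(rnorm(3))

## Ideal-geometry local CA traces.
## helix: 1.5 A rise per residue, 100 deg per residue, 2.3 A radius
## (consecutive CA-CA = 3.83 A); strand: 3.3 A rise with a 1.885 A
## alternating lateral offset (consecutive CA-CA = 3.80 A).
segment_ca_local <- function(type, len) {
  k <- seq_len(len) - 1L
  if (type == "H") {
    th <- k * 100 * pi / 180
    cbind(2.3 * cos(th), 2.3 * sin(th), 1.5 * k)
  } else {
    cbind(1.885 * (k %% 2), rep(0, len), 3.3 * k)
  }
}

## Derive full backbone atoms (N, CA, C, O and CB except Gly) from a CA
## trace. The geometry is idealized: only distances matter downstream.
ca_to_atoms <- function(ca, resnames) {
  n <- nrow(ca)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    p <- if (i == 1L) ca[1, ] else ca[i - 1L, ]
    q <- if (i == n) ca[n, ] else ca[i + 1L, ]
    tv <- q - p
    tv <- if (vnorm(tv) < 1e-9) c(0, 0, 1) else unit(tv)
    ref <- if (abs(tv[3]) > 0.9) c(1, 0, 0) else c(0, 0, 1)
    nv <- unit(ref - sum(ref * tv) * tv)
    bv <- cross3(tv, nv)
    cai <- ca[i, ]
    at <- rbind(
      N  = cai - 1.2 * tv + 0.6 * nv,
      CA = cai,
      C  = cai + 1.2 * tv + 0.6 * nv,
      O  = cai + 1.2 * tv + 1.83 * nv
    )
    if (resnames[i] != "GLY") {
      cb <- cai + 1.53 * unit(-0.4 * tv + 0.6 * nv - 0.7 * bv)
      at <- rbind(at, CB = cb)
    }
    rows[[i]] <- data.frame(
      resno = i, resname = resnames[i], name = rownames(at),
      elem = substr(rownames(at), 1, 1),
      x = at[, 1], y = at[, 2], z = at[, 3],
      stringsAsFactors = FALSE
    )
  }
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  atoms
}

#' Generate a synthetic protein chain
#'
#' Builds a self-avoiding CA trace from ideal secondary-structure segments
#' (alpha-helix and beta-strand geometry) joined at random orientations,
#' then decorates it with N, CA, C, O and CB (except glycine) atoms.
#' Residue names are drawn uniformly from the 20 standard codes. No two CA
#' atoms come closer than 3.6 Angstrom and consecutive CA-CA distances stay
#' near 3.8 Angstrom.
#'
#' @param n_res number of residues (at least 5).
#' @param motif_seed integer seed; the same seed reproduces the chain
#'   bit-identically.
#' @param chain_id chain identifier (default "A").
#' @return a `prot_chain`.
#' @export
make_chain <- function(n_res, motif_seed, chain_id = "A") {
  if (n_res < 5) stop("n_res must be >= 5")
  n_res <- as.integer(n_res)
  with_seed(motif_seed, {
    ca <- NULL
    remaining <- n_res
    while (remaining > 0L) {
      type <- sample(c("H", "E"), 1L, prob = c(0.6, 0.4))
      len <- if (type == "H") sample(5:12, 1L) else sample(4:8, 1L)
      len <- min(len, remaining)
      local <- segment_ca_local(type, len)
      placed <- NULL
      best <- NULL
      best_clear <- -Inf
      for (try in 1:200) {
        rot <- random_rotation()
        seg <- local %*% t(rot)
        if (is.null(ca)) {
          seg <- sweep(seg, 2, seg[1, ], "-")
        } else {
          d <- random_unit_vector()
          anchor <- ca[nrow(ca), ] + 3.8 * d
          seg <- sweep(seg, 2, anchor - seg[1, ], "+")
        }
        if (is.null(ca)) { placed <- seg; break }
        clear <- sqrt(min(cross_dist2(seg, ca)))
        if (clear >= 3.6) { placed <- seg; break }
        if (clear > best_clear) { best_clear <- clear; best <- seg }
      }
      if (is.null(placed)) {
        stop("chain generation failed to avoid CA clashes (seed ",
             motif_seed, ")")
      }
      ca <- rbind(ca, placed)
      remaining <- remaining - len
    }
    resnames <- sample(names(AA_321), n_res, replace = TRUE)
    new_chain(chain_id, ca_to_atoms(ca, resnames))
  })
}

## Count of CA-CA inter-chain pairs below `cutoff` (0 when a chain has no
## CA atoms).
ca_clash_count <- function(chain_a, chain_b, cutoff = 3.0) {
  ga <- chain_a$atoms[chain_a$atoms$name == "CA", c("x", "y", "z")]
  gb <- chain_b$atoms[chain_b$atoms$name == "CA", c("x", "y", "z")]
  if (!nrow(ga) || !nrow(gb)) return(0L)
  sum(cross_dist2(as.matrix(ga), as.matrix(gb)) < cutoff^2)
}

## Rigid-body docking: rotate chain b randomly and slide it toward chain a
## until the inter-chain residue-contact count first reaches
## >= contact_target with zero CA pairs under 3 Angstrom.
dock_chains <- function(chain_a, chain_b, contact_target,
                        max_trials = 500L, step = 0.25) {
  xa <- atom_xyz(chain_a)
  ctr_a <- colMeans(xa)
  ra <- sqrt(max(rowSums(sweep(xa, 2, ctr_a)^2)))
  xb0 <- atom_xyz(chain_b)
  ctr_b <- colMeans(xb0)
  xb0 <- sweep(xb0, 2, ctr_b)
  rb <- sqrt(max(rowSums(xb0^2)))
  ca_a <- ca_xyz(chain_a)
  res_b <- chain_b$atoms$resno
  ca_rows_b <- which(chain_b$atoms$name == "CA")
  far <- ra + rb + 6
  for (trial in seq_len(max_trials)) {
    rot <- random_rotation()
    xb_rot <- xb0 %*% t(rot)
    u <- random_unit_vector()
    for (off in seq(far, 1, by = -step)) {
      shift <- ctr_a + off * u
      xb <- sweep(xb_rot, 2, shift, "+")
      ca_b <- xb[ca_rows_b, , drop = FALSE]
      dca2 <- cross_dist2(ca_a, ca_b)
      if (min(dca2) > 11^2) next        # no atom can be within 5 A yet
      if (any(dca2 < 3.0^2)) break      # clash before reaching target
      d2 <- cross_dist2(xa, xb)
      hit <- which(d2 < 25, arr.ind = TRUE)
      if (nrow(hit) == 0L) next
      npairs <- nrow(unique(cbind(chain_a$atoms$resno[hit[, 1]],
                                  res_b[hit[, 2]])))
      if (npairs >= contact_target) {
        out <- chain_b
        xyz <- sweep(atom_xyz(chain_b), 2, ctr_b) %*% t(rot)
        xyz <- sweep(xyz, 2, shift, "+")
        out$atoms$x <- xyz[, 1]; out$atoms$y <- xyz[, 2]
        out$atoms$z <- xyz[, 3]
        return(out)
      }
    }
  }
  stop("docking failed to reach ", contact_target,
       " residue contacts within ", max_trials, " trials")
}

#' Generate a synthetic dimer template
#'
#' Two chains are generated with [make_chain()] and rigid-body docked:
#' chain Y is rotated randomly and translated along a random contact axis
#' until the inter-chain residue-contact count at 5 Angstrom first reaches
#' the configured target, with no CA-CA pair under 3 Angstrom. Metadata
#' flags (homodimer, obligate, part of a higher-order complex) are drawn
#' from the generator stream.
#'
#' @param len_a,len_b chain lengths (at least 20 residues).
#' @param config a [generator_config()]; `config$seed` makes the dimer
#'   reproducible.
#' @param id template identifier.
#' @return a [dimer_record()].
#' @export
make_dimer <- function(len_a, len_b, config, id = "D001") {
  stopifnot(inherits(config, "generator_config"))
  if (len_a < 20 || len_b < 20) stop("chain lengths must be >= 20")
  with_seed(config$seed, {
    seeds <- sample.int(1e6, 2L)
    cx <- make_chain(len_a, seeds[1], chain_id = "A")
    cy <- make_chain(len_b, seeds[2], chain_id = "B")
    cy <- dock_chains(cx, cy, config$contact_target)
    dimer_record(id, cx, cy,
                 is_homodimer = runif(1) < 0.3,
                 is_obligate = runif(1) < 0.5,
                 from_higher_order = runif(1) < 0.2)
  })
}

#' Perturb a structure with coordinate noise and a random rigid move
#'
#' Adds i.i.d. Gaussian noise (standard deviation `sigma` per coordinate)
#' to every atom, then applies one random rotation and translation to the
#' whole structure. Topology (chains, residues, atom names) is unchanged.
#' Stands in for homology-model imperfection.
#'
#' @param s a `prot_structure` or `prot_chain`.
#' @param sigma noise level in Angstrom (>= 0).
#' @param seed integer seed.
#' @return an object of the same class as `s`.
#' @export
perturb_structure <- function(s, sigma, seed) {
  if (sigma < 0) stop("sigma must be >= 0")
  single <- inherits(s, "prot_chain")
  st <- if (single) new_structure("chain", list(s)) else s
  stopifnot(inherits(st, "prot_structure"))
  out <- with_seed(seed, {
    rot <- random_rotation()
    tr <- rnorm(3, sd = 15)
    chains <- lapply(st$chains, function(ch) {
      xyz <- atom_xyz(ch)
      xyz <- xyz + matrix(rnorm(length(xyz), sd = sigma), ncol = 3)
      xyz <- xyz %*% t(rot)
      xyz <- sweep(xyz, 2, tr, "+")
      ch$atoms$x <- xyz[, 1]; ch$atoms$y <- xyz[, 2]; ch$atoms$z <- xyz[, 3]
      ch
    })
    new_structure(st$id, chains)
  })
  if (single) out$chains[[1L]] else out
}

#' Generate a benchmark with planted structural precedents
#'
#' Builds a dimer library organized in *fold families* of two: consecutive
#' templates share both chain folds but differ in docking geometry.
#' Positive pairs are noise-perturbed copies of the two chains of one
#' library dimer (the planted precedent). Negative pairs are either
#' unrelated fresh chains (no precedent) or, for a fraction
#' `config$compat_frac`, structure-compatible negatives whose chains are
#' perturbed copies of chains from the two *different* dimers of one fold
#' family (so a precedent exists even though the pair is labelled
#' non-interacting). Planted templates/families are assigned round-robin,
#' and the truth table records them.
#'
#' @param n_templates number of dimer templates (even numbers give
#'   complete fold families).
#' @param n_pos_pairs,n_neg_pairs counts of positive / negative pairs.
#' @param config a [generator_config()].
#' @return a list of class `precedent_benchmark` with elements
#'   `library` (list of [dimer_record()], each with a `family` field),
#'   `models` (named list: protein id -> list of single-chain
#'   `prot_structure` models), `pairs` (data.frame id_a, id_b) and
#'   `truth` (data.frame pair_id, id_a, id_b, label, neg_type,
#'   template_id, family).
#' @export
make_benchmark <- function(n_templates, n_pos_pairs, n_neg_pairs, config) {
  stopifnot(inherits(config, "generator_config"))
  if (n_templates < 1 || n_pos_pairs < 1 || n_neg_pairs < 1) {
    stop("counts must be >= 1")
  }
  with_seed(config$seed, {
    rng <- function() sample.int(1e6, 1L)
    lo <- config$chain_length_range[1]; hi <- config$chain_length_range[2]
    n_fam <- ceiling(n_templates / 2)
    library <- list()
    fam_of <- integer(n_templates)
    for (k in seq_len(n_fam)) {
      n_side <- min(2L, n_templates - 2L * (k - 1L))
      ## not every pair of fold shapes can reach the contact target
      ## clash-free: redraw the family's chains until docking succeeds
      built <- NULL
      for (attempt in 1:25) {
        len_x <- sample(lo:hi, 1L); len_y <- sample(lo:hi, 1L)
        cx <- make_chain(len_x, rng(), chain_id = "A")
        cy <- make_chain(len_y, rng(), chain_id = "B")
        docks <- vector("list", n_side)
        ok <- TRUE
        for (side in seq_len(n_side)) {
          res <- tryCatch(
            with_seed(rng(), dock_chains(cx, cy, config$contact_target,
                                         max_trials = 200L)),
            error = function(e) NULL)
          if (is.null(res)) { ok <- FALSE; break }
          docks[[side]] <- res
        }
        if (ok) { built <- list(cx = cx, docks = docks); break }
      }
      if (is.null(built)) {
        stop("could not generate a dimer family satisfying the contact ",
             "target; lower contact_target or widen chain_length_range")
      }
      for (side in seq_len(n_side)) {
        idx <- 2L * (k - 1L) + side
        rec <- dimer_record(sprintf("T%03d", idx), built$cx,
                            built$docks[[side]],
                            is_homodimer = runif(1) < 0.3,
                            is_obligate = runif(1) < 0.5,
                            from_higher_order = runif(1) < 0.2)
        rec$family <- k
        library[[idx]] <- rec
        fam_of[idx] <- k
      }
    }
    models <- list()
    truth <- list()
    pairs <- list()
    add_pair <- function(pid, ida, idb, label, neg_type, tpl, fam) {
      pairs[[length(pairs) + 1L]] <<- data.frame(
        pair_id = pid, id_a = ida, id_b = idb, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <<- data.frame(
        pair_id = pid, id_a = ida, id_b = idb, label = label,
        neg_type = neg_type, template_id = tpl, family = fam,
        stringsAsFactors = FALSE)
    }
    ## positives: planted on templates round-robin
    for (i in seq_len(n_pos_pairs)) {
      tpl_idx <- ((i - 1L) %% n_templates) + 1L
      tpl <- library[[tpl_idx]]
      ida <- sprintf("POS%03dA", i); idb <- sprintf("POS%03dB", i)
      ma <- perturb_structure(tpl$chain_x, config$noise_sigma, rng())
      mb <- perturb_structure(tpl$chain_y, config$noise_sigma, rng())
      models[[ida]] <- list(new_structure(ida, list(ma)))
      models[[idb]] <- list(new_structure(idb, list(mb)))
      add_pair(sprintf("pos%03d", i), ida, idb, "positive", NA_character_,
               tpl$id, tpl$family)
    }
    ## negatives: structure-compatible first (round-robin over complete
    ## families), then unrelated
    full_fams <- which(tabulate(fam_of, nbins = n_fam) == 2L)
    n_compat <- round(config$compat_frac * n_neg_pairs)
    if (length(full_fams) == 0L) n_compat <- 0L
    for (j in seq_len(n_neg_pairs)) {
      ida <- sprintf("NEG%03dA", j); idb <- sprintf("NEG%03dB", j)
      if (j <= n_compat) {
        fam <- full_fams[((j - 1L) %% length(full_fams)) + 1L]
        d1 <- library[[2L * (fam - 1L) + 1L]]
        d2 <- library[[2L * fam]]
        ma <- perturb_structure(d1$chain_x, config$noise_sigma, rng())
        mb <- perturb_structure(d2$chain_y, config$noise_sigma, rng())
        models[[ida]] <- list(new_structure(ida, list(ma)))
        models[[idb]] <- list(new_structure(idb, list(mb)))
        add_pair(sprintf("neg%03d", j), ida, idb, "negative", "compatible",
                 NA_character_, fam)
      } else {
        ca <- make_chain(sample(lo:hi, 1L), rng(), chain_id = "A")
        cb <- make_chain(sample(lo:hi, 1L), rng(), chain_id = "B")
        models[[ida]] <- list(new_structure(ida, list(ca)))
        models[[idb]] <- list(new_structure(idb, list(cb)))
        add_pair(sprintf("neg%03d", j), ida, idb, "negative", "unrelated",
                 NA_character_, NA_integer_)
      }
    }
    structure(list(
      library = library,
      models = models,
      pairs = do.call(rbind, pairs),
      truth = do.call(rbind, truth),
      config = config
    ), class = "precedent_benchmark")
  })
}

#' Write a benchmark to disk
#'
#' Layout: `library/<template>.pdb` (two-chain templates),
#' `models/<protein>_<k>.pdb` (monomer models), `pairs.tsv` and
#' `truth.tsv`.
#'
#' @param bench a [make_benchmark()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "precedent_benchmark"))
  dir.create(file.path(dir, "library"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "models"), recursive = TRUE, showWarnings = FALSE)
  for (rec in bench$library) {
    st <- new_structure(rec$id, list(rec$chain_x, rec$chain_y))
    write_pdb(st, file.path(dir, "library", paste0(rec$id, ".pdb")))
  }
  for (pid in names(bench$models)) {
    for (k in seq_along(bench$models[[pid]])) {
      write_pdb(bench$models[[pid]][[k]],
                file.path(dir, "models", sprintf("%s_%d.pdb", pid, k)))
    }
  }
  write_pairs(bench$pairs, file.path(dir, "pairs.tsv"))
  write.table(bench$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Generate a scale-free interaction network
#'
#' Preferential-attachment (Barabasi-Albert) graph: simple, undirected,
#' with a heavy-tailed degree distribution, emulating the topology of a
#' physiological protein-protein interaction network.
#'
#' @param n_nodes number of proteins (at least 10).
#' @param mean_degree target mean degree; each new node attaches with
#'   `round(mean_degree / 2)` edges.
#' @param seed integer seed.
#' @return an igraph object with node names `Y0001`, `Y0002`, ...
#' @export
make_network <- function(n_nodes, mean_degree = 4, seed = 1L) {
  if (n_nodes < 10) stop("n_nodes must be >= 10")
  with_seed(seed, {
    m <- max(1L, round(mean_degree / 2))
    g <- igraph::sample_pa(n_nodes, power = 1, m = m, directed = FALSE)
    g <- igraph::simplify(g)
    igraph::V(g)$name <- sprintf("Y%04d", seq_len(n_nodes))
    g
  })
}

#' Generate an annotation table for a set of proteins
#'
#' Emulates the annotation layers the pair-selection strategies need:
#' subcellular localization (one compartment for most proteins, two for a
#' fraction), protein abundance (log-normal values classed into quartile
#' terciles: bottom 25% low, top 25% high, medium otherwise) and sets of
#' functional annotation terms with a heavy-tailed term frequency.
#'
#' @param ids character vector of protein identifiers.
#' @param seed integer seed.
#' @param n_terms size of the term vocabulary.
#' @param multi_loc_frac fraction of proteins annotated to two
#'   compartments.
#' @return a list of class `annotation_table` with elements `localization`
#'   (named list of compartments), `abundance` (data.frame id, value,
#'   class) and `terms` (named list of term sets).
#' @export
make_annotations <- function(ids, seed = 1L, n_terms = 30L,
                             multi_loc_frac = 0.2) {
  comps <- c("nucleus", "cytoplasm", "mitochondrion", "ER", "membrane")
  with_seed(seed, {
    loc <- lapply(ids, function(id) {
      k <- if (runif(1) < multi_loc_frac) 2L else 1L
      sample(comps, k)
    })
    names(loc) <- ids
    val <- stats::rlnorm(length(ids), meanlog = 3, sdlog = 1.5)
    qs <- quantile(val, c(0.25, 0.75))
    cls <- ifelse(val <= qs[1], "low", ifelse(val >= qs[2], "high", "medium"))
    vocab <- sprintf("TERM%04d", seq_len(n_terms))
    w <- 1 / seq_len(n_terms)  # Zipf-like term popularity
    terms <- lapply(ids, function(id) {
      sample(vocab, sample(2:6, 1L), prob = w)
    })
    names(terms) <- ids
    structure(list(
      localization = loc,
      abundance = data.frame(id = ids, value = val, class = cls,
                             stringsAsFactors = FALSE),
      terms = terms
    ), class = "annotation_table")
  })
}

#' Flatten an annotation table to long format
#'
#' @param ann an [make_annotations()] result.
#' @return data.frame with columns id, key, value (keys `localization`,
#'   `abundance_class`, `term`).
#' @export
annotations_long <- function(ann) {
  stopifnot(inherits(ann, "annotation_table"))
  rows <- list()
  for (id in names(ann$localization)) {
    for (v in ann$localization[[id]]) {
      rows[[length(rows) + 1L]] <- c(id, "localization", v)
    }
  }
  for (i in seq_len(nrow(ann$abundance))) {
    rows[[length(rows) + 1L]] <-
      c(ann$abundance$id[i], "abundance_class", ann$abundance$class[i])
  }
  for (id in names(ann$terms)) {
    for (v in ann$terms[[id]]) {
      rows[[length(rows) + 1L]] <- c(id, "term", v)
    }
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("id", "key", "value")
  df
}
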