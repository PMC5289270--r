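# Interface descriptors: residues, ASA, hydrophobicity, gap volume and
# contact signatures.

test_that("interface residues match brute-force scans", {
  # disjoint chains: empty interface
  st <- new_structure("d", list(ca_chain("A", strand_ca(6)),
                                ca_chain("B", strand_ca(6, y = 30))))
  ir <- interface_residues(st)
  expect_length(ir[[1]], 0L)
  expect_length(ir[[2]], 0L)
  # one CB pair at 4.9 A: exactly one residue per chain
  a <- cb_chain("A", rbind(c(0, 0, 0), c(20, 0, 0)), c("LEU", "ALA"))
  b <- cb_chain("B", rbind(c(0, 4.9, 0), c(-20, 0, 0)), c("ASP", "GLY"))
  st2 <- new_structure("p", list(a, b))
  ir2 <- interface_residues(st2)
  expect_equal(ir2[["A"]], 1L)
  expect_equal(ir2[["B"]], 1L)
  # random two-chain fixtures vs O(n^2) double loop
  for (seed in c(81, 82, 83)) {
    cfg <- generator_config(seed = seed, contact_target = 30,
                            chain_length_range = c(20L, 30L))
    d <- make_dimer(22, 25, cfg)
    stx <- new_structure("x", list(d$chain_x, d$chain_y))
    got <- interface_residues(stx)
    want <- brute_interface_residues(stx)
    expect_equal(unname(got[[1]]), want[[1]])
    expect_equal(unname(got[[2]]), want[[2]])
  }
})

test_that("single-sphere ASA is analytic and occlusion only removes area", {
  lone <- cb_chain("A", matrix(c(0, 0, 0), 1), "ALA")
  asa <- accessible_surface(lone)
  expect_equal(asa$asa, 4 * pi * (1.87 + 1.4)^2, tolerance = 0.02 * 134)
  # far apart: additive
  two_far <- mk_chain("A", 1:2, c("ALA", "ALA"), c("CB", "CB"),
                      c(0, 100), c(0, 0), c(0, 0))
  asa2 <- accessible_surface(two_far)
  expect_equal(sum(asa2$asa), 2 * asa$asa, tolerance = 1e-6)
  # contact distance: occluded
  two_near <- mk_chain("A", 1:2, c("ALA", "ALA"), c("CB", "CB"),
                       c(0, 3.7), c(0, 0), c(0, 0))
  asa3 <- accessible_surface(two_near)
  expect_lt(sum(asa3$asa), 2 * asa$asa)
  # unknown element
  odd <- mk_chain("A", 1, "ALA", "XX", 0, 0, 0)
  odd$atoms$elem <- "Q"
  expect_error(accessible_surface(odd), "radius")
})

test_that("ASA converges with the sampling density", {
  cfg <- generator_config(seed = 84, chain_length_range = c(20L, 25L),
                          contact_target = 25)
  d <- make_dimer(20, 20, cfg)
  st <- new_structure("x", list(d$chain_x, d$chain_y))
  a1 <- attr(accessible_surface(st, n_points = 480L), "total")
  a2 <- attr(accessible_surface(st, n_points = 960L), "total")
  expect_lt(abs(a1 - a2) / a2, 0.01)
})

test_that("hydrophobicity is the hydrophobic share of buried area", {
  leu_a <- cb_chain("A", cbind(3.8 * (0:4), 0, 0), rep("LEU", 5))
  leu_b <- cb_chain("B", cbind(3.8 * (0:4), 4.2, 0), rep("LEU", 5))
  hy <- interface_hydrophobicity(new_structure("l", list(leu_a, leu_b)))
  expect_equal(hy$hydrophobicity, 1.0)
  expect_gt(hy$interface_asa, 0)
  asp_a <- cb_chain("A", cbind(3.8 * (0:4), 0, 0), rep("ASP", 5))
  glu_b <- cb_chain("B", cbind(3.8 * (0:4), 4.2, 0), rep("GLU", 5))
  hy2 <- interface_hydrophobicity(new_structure("d", list(asp_a, glu_b)))
  expect_equal(hy2$hydrophobicity, 0.0)
  # mixed toy interface agrees with a hand ledger of dASA terms
  mix_a <- cb_chain("A", cbind(3.8 * (0:2), 0, 0),
                    c("LEU", "ASP", "PHE"))
  mix_b <- cb_chain("B", cbind(3.8 * (0:2), 4.2, 0),
                    c("SER", "VAL", "LYS"))
  stm <- new_structure("m", list(mix_a, mix_b))
  hy3 <- interface_hydrophobicity(stm)
  per <- hy3$per_residue
  hyd_set <- c("LEU", "PHE", "VAL")
  expect_equal(hy3$hydrophobicity,
               sum(per$dasa[per$resname %in% hyd_set]) / sum(per$dasa))
  expect_equal(hy3$interface_asa, sum(per$dasa) / 2)
  # no interface: undefined and flagged
  far <- new_structure("f", list(leu_a,
                                 cb_chain("B", cbind(3.8 * (0:4), 50, 0),
                                          rep("LEU", 5))))
  expect_warning(hyf <- interface_hydrophobicity(far), "undefined")
  expect_true(is.na(hyf$hydrophobicity))
})

test_that("gap volume grows with plate separation and is grid-stable", {
  sheet <- function(y) {
    xy <- expand.grid(x = 3.8 * (0:4), z = 3.8 * (0:4))
    cb_chain("A", cbind(xy$x, y, xy$z), rep("ALA", nrow(xy)))
  }
  plate_gap <- function(sep, spacing = 1.0) {
    s1 <- sheet(0); s2 <- sheet(sep); s2$id <- "B"
    gap_volume(new_structure("g", list(s1, s2)),
               grid_spacing = spacing)$gap_volume
  }
  g4 <- plate_gap(4); g6 <- plate_gap(6); g7 <- plate_gap(7)
  g8 <- plate_gap(8)
  expect_lt(g4, g8)          # 4 -> 8 A separation opens a gap
  expect_true(g6 < g7 && g7 < g8)
  # separated by 20 A: no voxel within the shell of both chains
  expect_equal(plate_gap(20), 0)
  # refinement changes the estimate by < 15%
  gc1 <- plate_gap(8, spacing = 1.0)
  gc2 <- plate_gap(8, spacing = 0.5)
  expect_lt(abs(gc1 - gc2) / gc2, 0.15)
})

test_that("contact signatures count class pairs symmetrically", {
  leu <- cb_chain("A", matrix(c(0, 0, 0), 1), "LEU")
  leu$atoms$name <- "CA"
  asp <- cb_chain("B", matrix(c(8, 0, 0), 1), "ASP")
  asp$atoms$name <- "CA"
  cs <- contact_signature(new_structure("s", list(leu, asp)))
  expect_equal(unname(cs["aliphatic", "acidic"]), 1L)
  expect_equal(unname(cs["acidic", "aliphatic"]), 1L)
  expect_equal(sum(cs), 2L)
  expect_true(isSymmetric(unclass(cs)))
  # no CA pair below 12 A: all-zero matrix, and the distance is undefined
  far <- ca_chain("B", matrix(c(50, 0, 0), 1), "ASP")
  cs0 <- contact_signature(new_structure("z", list(leu, far)))
  expect_true(all(cs0 == 0L))
  expect_error(signature_distance(cs0, cs), "all-zero")
  # totals agree with a brute-force pair count on random dimers
  for (seed in c(85, 86)) {
    cfg <- generator_config(seed = seed, chain_length_range = c(20L, 28L),
                            contact_target = 30)
    d <- make_dimer(21, 24, cfg)
    st <- new_structure("x", list(d$chain_x, d$chain_y))
    cs2 <- contact_signature(st)
    ut <- upper.tri(cs2, diag = TRUE)
    expect_equal(sum(cs2[ut]), brute_ca_contact_count(st))
    expect_true(isSymmetric(unclass(cs2)))
  }
})

test_that("signature distance has the stated boundary behaviour", {
  m1 <- matrix(0L, 7, 7); m1[1, 1] <- 3L; m1[1, 2] <- 2L; m1[2, 1] <- 2L
  m2 <- matrix(0L, 7, 7); m2[4, 5] <- 1L; m2[5, 4] <- 1L
  expect_equal(signature_distance(m1, m1), 0)
  expect_equal(signature_distance(m1, m2), 1)  # disjoint support
  expect_equal(signature_distance(m1, 2L * m1), 0)  # scale invariance
  expect_equal(signature_distance(m1, m2), signature_distance(m2, m1))
  set.seed(87)
  for (rep in 1:20) {
    a <- matrix(rpois(49, 2), 7); a <- a + t(a)
    b <- matrix(rpois(49, 2), 7); b <- b + t(b)
    if (sum(a) == 0 || sum(b) == 0) next
    d <- signature_distance(a, b)
    expect_true(d >= 0 && d <= 1)
  }
})

test_that("positive and negative model descriptors overlap broadly", {
  b <- small_benchmark()
  lib_ids <- vapply(b$library, `[[`, character(1), "id")
  get_model <- function(row) {
    tpl_id <- if (!is.na(row$template_id)) row$template_id else
      lib_ids[2 * (row$family - 1) + 1]
    d <- b$library[[match(tpl_id, lib_ids)]]
    ma <- b$models[[row$id_a]][[1]]
    mb <- b$models[[row$id_b]][[1]]
    hit <- tmmin_for_template(ma, mb, d, pair_id = row$pair_id)
    build_interaction_model(ma, mb, d, hit)
  }
  tr <- b$truth
  pos_rows <- tr[tr$label == "positive", ][1:4, ]
  neg_rows <- tr[tr$neg_type %in% "compatible", ][1, ]
  pos_asa <- vapply(seq_len(nrow(pos_rows)), function(i) {
    interface_hydrophobicity(get_model(pos_rows[i, ]),
                             n_points = 240L)$interface_asa
  }, numeric(1))
  neg_asa <- interface_hydrophobicity(get_model(neg_rows),
                                      n_points = 240L)$interface_asa
  # the negative model's interface is inside the positive range scaled
  # by a generous factor: the populations are not separable
  expect_gt(neg_asa, min(pos_asa) * 0.5)
  expect_lt(neg_asa, max(pos_asa) * 2)
})
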