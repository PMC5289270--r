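# Precedent identification, interaction-model building and interface
# validation.

test_that("a pair made of the template's own chains scores TMmin 1", {
  b <- small_benchmark()
  d <- b$library[[1]]
  hit <- tmmin_for_template(d$chain_x, d$chain_y, d, pair_id = "self")
  expect_equal(hit$tmmin, 1, tolerance = 1e-6)
  expect_equal(hit$assignment, "AX/BY")
})

test_that("TMmin is symmetric under swapping the pair members", {
  b <- small_benchmark()
  d <- b$library[[3]]
  pa <- b$models[["POS001A"]][[1]]
  pb <- b$models[["POS001B"]][[1]]
  h1 <- tmmin_for_template(pa, pb, d)
  h2 <- tmmin_for_template(pb, pa, d)
  expect_equal(h1$tmmin, h2$tmmin, tolerance = 1e-6)
})

test_that("the better of the two chain assignments is returned", {
  b <- small_benchmark()
  d <- b$library[[1]]
  # model A resembles chain Y, model B resembles chain X: the swapped
  # assignment must win
  ma <- perturb_structure(d$chain_y, 0.3, seed = 71)
  mb <- perturb_structure(d$chain_x, 0.3, seed = 72)
  hit <- tmmin_for_template(ma, mb, d)
  expect_equal(hit$assignment, "AY/BX")
  expect_gt(hit$tmmin, 0.6)
})

test_that("interaction models land on the template frame", {
  b <- small_benchmark()
  d <- b$library[[2]]
  hit <- tmmin_for_template(d$chain_x, d$chain_y, d, pair_id = "exact")
  im <- build_interaction_model(d$chain_x, d$chain_y, d, hit)
  expect_length(im$structure$chains, 2L)
  expect_equal(structprec:::atom_xyz(im$structure$chains[[1]]),
               structprec:::atom_xyz(d$chain_x),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(structprec:::atom_xyz(im$structure$chains[[2]]),
               structprec:::atom_xyz(d$chain_y),
               tolerance = 1e-3, ignore_attr = TRUE)
  # pre-rotating an input monomer does not change the built model
  pre <- perturb_structure(d$chain_x, 0, seed = 77)
  hit2 <- tmmin_for_template(pre, d$chain_y, d, pair_id = "rot")
  im2 <- build_interaction_model(pre, d$chain_y, d, hit2)
  expect_equal(structprec:::atom_xyz(im2$structure$chains[[1]]),
               structprec:::atom_xyz(im$structure$chains[[1]]),
               tolerance = 1e-2, ignore_attr = TRUE)
})

test_that("interface validation applies the size and clash rules", {
  far <- ca_chain("B", strand_ca(10, y = 50))
  near <- ca_chain("A", strand_ca(10))
  st <- new_structure("far", list(near, far))
  v <- validate_interface(st)
  expect_equal(v$interface_size, 0L)
  expect_false(v$valid)
  # exactly 20 pooled interface residues, no clashes -> valid
  a <- cb_chain("A", cbind(3.8 * (0:9), 0, 0), rep("LEU", 10))
  bb <- cb_chain("B", cbind(3.8 * (0:9), 4.5, 0), rep("LEU", 10))
  stv <- new_structure("v", list(a, bb))
  vv <- validate_interface(stv)
  expect_equal(vv$interface_size, 20L)
  expect_equal(vv$clash_count, 0L)
  expect_true(vv$valid)
  bf <- brute_interface_residues(stv)
  expect_equal(vv$interface_size, length(bf[[1]]) + length(bf[[2]]))
  # three CA pairs at 2.0 A: "less than three clashes" is violated
  ca_a <- ca_chain("A", rbind(strand_ca(3), strand_ca(20, y = 30)))
  ca_b <- ca_chain("B", rbind(strand_ca(3, y = 2),
                              strand_ca(20, y = -30)))
  stc <- new_structure("c", list(ca_a, ca_b))
  vc <- validate_interface(stc, min_interface = 1)
  expect_equal(vc$clash_count, 3L)
  expect_false(vc$valid)
})

test_that("precedent search ranks, validates, and is threshold-monotone", {
  b <- small_benchmark()
  ida <- b$pairs$id_a[1]; idb <- b$pairs$id_b[1]
  r6 <- find_precedents(b$models[[ida]], b$models[[idb]], b$library,
                        threshold = 0.6, pair_id = "p1")
  expect_equal(r6$status, "precedent")
  tr <- b$truth[b$truth$pair_id == b$pairs$pair_id[1], ]
  hit_fam <- b$library[[match(r6$hit$template_id,
                              vapply(b$library, `[[`, character(1),
                                     "id"))]]$family
  expect_equal(hit_fam, tr$family)
  # any hit at threshold t is also returned at t' <= t
  r4 <- find_precedents(b$models[[ida]], b$models[[idb]], b$library,
                        threshold = 0.4, pair_id = "p1")
  expect_equal(r4$hit$template_id, r6$hit$template_id)
  expect_equal(r4$hit$tmmin, r6$hit$tmmin)
  # impossible threshold
  r_hi <- find_precedents(b$models[[ida]], b$models[[idb]], b$library,
                          threshold = 1.01)
  expect_equal(r_hi$status, "no_precedent")
  # empty model list is a distinct outcome
  r_nm <- find_precedents(list(), b$models[[idb]], b$library)
  expect_equal(r_nm$status, "no_models")
  expect_error(find_precedents(b$models[[ida]], b$models[[idb]], list()),
               "empty")
})

test_that("precedent search is deterministic", {
  b <- small_benchmark()
  ida <- b$pairs$id_a[2]; idb <- b$pairs$id_b[2]
  r1 <- find_precedents(b$models[[ida]], b$models[[idb]], b$library, 0.5)
  r2 <- find_precedents(b$models[[ida]], b$models[[idb]], b$library, 0.5)
  expect_equal(r1$hit$template_id, r2$hit$template_id)
  expect_identical(r1$hit$tmmin, r2$hit$tmmin)
})

test_that("dimer records reject sparse interfaces", {
  a <- ca_chain("A", strand_ca(25))
  bfar <- ca_chain("B", strand_ca(25, y = 40))
  expect_error(dimer_record("bad", a, bfar), "contacts")
})
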