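# Small programmatic fixtures.

# chain with arbitrary atoms from a data.frame-like spec
mk_chain <- function(id, resno, resname, name, x, y, z) {
  elem <- substr(name, 1, 1)
  new_chain(id, data.frame(resno = resno, resname = resname, name = name,
                           elem = elem, x = x, y = y, z = z,
                           stringsAsFactors = FALSE))
}

# CA-only chain from a coordinate matrix
ca_chain <- function(id, ca, resnames = NULL) {
  n <- nrow(ca)
  if (is.null(resnames)) resnames <- rep("ALA", n)
  mk_chain(id, seq_len(n), resnames, rep("CA", n), ca[, 1], ca[, 2], ca[, 3])
}

# chain of single-CB residues placed at given coordinates
cb_chain <- function(id, xyz, resnames) {
  n <- nrow(xyz)
  mk_chain(id, seq_len(n), resnames, rep("CB", n),
           xyz[, 1], xyz[, 2], xyz[, 3])
}

# straight CA strand along x at given y/z offset, 3.8 A spacing
strand_ca <- function(n, y = 0, z = 0) {
  cbind(3.8 * (seq_len(n) - 1), rep(y, n), rep(z, n))
}

rotation_about_z <- function(theta) {
  rbind(c(cos(theta), -sin(theta), 0),
        c(sin(theta), cos(theta), 0),
        c(0, 0, 1))
}

# shared small benchmark for precedent/interface tests (built lazily once)
.small_bench_env <- new.env(parent = emptyenv())
small_benchmark <- function() {
  if (is.null(.small_bench_env$b)) {
    cfg <- generator_config(seed = 11, n_dimers = 4)
    .small_bench_env$b <- make_benchmark(4, 6, 6, cfg)
  }
  .small_bench_env$b
}
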