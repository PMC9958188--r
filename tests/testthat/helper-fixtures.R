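# Shared fixtures, built in code and cached per test run.

rna_tab <- atom_type_table("rna")
prot_tab <- atom_type_table("protein")

# a small typed toy complex with a nonempty interface
toy_complex <- local({
  cx <- generate_toy_complex(seed = 1, n_nt = 6, n_aa = 8)
  assign_types(cx)
})

# reduced-size settings used by network/training tests (L = 8, 8^3 grids)
reduced_net_config <- function(...) {
  args <- utils::modifyList(
    list(conv_channels = c(8, 16, 32, 32, 32),
         seq_strides = c(2, 2, 2, 1, 1), L = 8L, grid_dim = 8L),
    list(...))
  do.call(network_config, args)
}

reduced_tensor <- function(complex = toy_complex, cutoff = 6) {
  featurize_structure(complex, cutoff = cutoff, L = 8L, grid_dim = 8L)
}

# random complex_tensor stand-in for pure network tests
random_tensor <- function(seed, L = 8L, g = 8L, n_real = 3L) {
  set.seed(seed)
  data <- array(0, c(3, L, g, g, g))
  data[, seq_len(n_real), , , ] <- stats::rnorm(3 * n_real * g^3)
  list(data = data, mask = c(rep(1L, n_real), rep(0L, L - n_real)))
}

# rigid motion helpers for equivariance tests
random_rotation <- function(seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(9), 3)))
}

apply_rigid <- function(complex, R, t) {
  if (det(R) < 0) R[, 1] <- -R[, 1]
  xyz <- as.matrix(complex$atoms[, c("x", "y", "z")])
  complex$atoms[, c("x", "y", "z")] <-
    xyz %*% t(R) + matrix(t, nrow(xyz), 3, byrow = TRUE)
  complex
}

# minimal hand-built complex: one nucleotide atom + one residue atom at a
# controlled separation, for boundary tests
two_atom_complex <- function(separation) {
  atoms <- data.frame(
    chain_id = c("R", "P"), seq_index = c(1L, 1L),
    res_code = c("A", "ALA"), kind = c("nucleotide", "amino_acid"),
    atom_name = c("C1'", "CB"), element = c("C", "C"),
    x = c(0, separation), y = 0, z = 0, is_hydrogen = FALSE,
    stringsAsFactors = FALSE)
  rpscore:::new_complex_structure(atoms, "two_atom")
}
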