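# Shared in-code fixtures.  Everything is generated programmatically; no
# binary data ships with the package.

# small random conformation ensemble (K x Np x 3)
random_ensemble <- function(K, Np, seed = 1, sd = 1) {
  set.seed(seed)
  molecule_ensemble(array(rnorm(K * Np * 3, sd = sd), dim = c(K, Np, 3)))
}

# a rigid random rotation + translation applied to an N x 3 structure
apply_random_rigid <- function(coords, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  sweep(coords %*% R, 2, runif(3, -10, 10), `+`)
}

# asymmetric 3-D point cloud with no special symmetry
asymmetric_structure <- function(n = 8, seed = 3) {
  set.seed(seed)
  matrix(rnorm(n * 3), n, 3) + outer(seq_len(n), c(0.5, -0.2, 0.3))
}

# quick small synthetic system (shared settings, modest size)
quick_system <- function(seed = 11, n_copies = 4L, n_frames = 500L, ...) {
  generate_system(synthetic_spec(seed = seed, n_copies = n_copies,
                                 n_frames = n_frames, ...))
}

# write a minimal PDB file; atoms is a data.frame(name, resn, resi) + coords
write_tiny_pdb <- function(path, name, resn, resi, coords) {
  ln <- sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
                seq_along(name), name, resn, resi,
                coords[, 1], coords[, 2], coords[, 3])
  writeLines(c(ln, "END"), path)
  path
}
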