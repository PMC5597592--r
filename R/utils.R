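# Internal helpers shared across modules.

# Boltzmann constant, kJ/(mol K)
.kB_kJmol <- 0.008314462618

#' Flatten an N x 3 coordinate matrix to a length-3N vector
#'
#' Coordinates are flattened particle-major: (x1, y1, z1, x2, y2, z2, ...).
#' This ordering is the package-wide convention for covariance matrices and
#' eigenvectors.
#'
#' @param coords numeric N x 3 matrix (Angstrom).
#' @return numeric vector of length 3N.
#' @export
flatten_coords <- function(coords) {
  stopifnot(is.matrix(coords), ncol(coords) == 3)
  as.vector(t(coords))
}

#' Reshape a length-3N vector back to an N x 3 coordinate matrix
#'
#' Inverse of [flatten_coords()].
#'
#' @param v numeric vector of length 3N.
#' @return numeric N x 3 matrix.
#' @export
unflatten_coords <- function(v) {
  stopifnot(length(v) %% 3 == 0)
  matrix(v, ncol = 3, byrow = TRUE)
}

# K x Np x 3 conformation array -> K x 3Np matrix (rows flattened particle-major)
ensemble_matrix <- function(conf) {
  stopifnot(length(dim(conf)) == 3, dim(conf)[3] == 3)
  K <- dim(conf)[1]; Np <- dim(conf)[2]
  t(matrix(aperm(conf, c(3, 2, 1)), nrow = 3L * Np))
}

# K x 3Np matrix -> K x Np x 3 array
matrix_ensemble <- function(M) {
  stopifnot(ncol(M) %% 3 == 0)
  K <- nrow(M); Np <- ncol(M) %/% 3L
  aperm(array(t(M), dim = c(3, Np, K)), c(3, 2, 1))
}

# defensive checks ----------------------------------------------------------

assert_finite <- function(x, what = "coordinates") {
  if (!all(is.finite(x))) {
    stop(sprintf("non-finite values in %s", what), call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
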