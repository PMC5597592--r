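# Positional-covariance PCA of pooled single-molecule ensembles and the
# basis / covariance comparison statistics built on it.
#
# Conventions: conformations are flattened particle-major (x1,y1,z1,x2,...);
# the covariance divisor is K (population), not K-1 — with the pooled
# conformation counts this package targets (1e5-1e6) the difference is
# negligible and trace identities are exact.

#' Positional covariance of an aligned ensemble
#'
#' @param aligned an `aligned_ensemble` (or any `molecule_ensemble`; alignment
#'   is the caller's responsibility).
#' @return list with `mean_structure` (Np x 3) and `covariance`
#'   (3Np x 3Np, Angstrom^2, divisor K).
#' @export
compute_covariance <- function(aligned) {
  conf <- aligned$conformations
  K <- dim(conf)[1]
  if (K < 2) stop("insufficient data: need at least 2 conformations", call. = FALSE)
  X <- ensemble_matrix(conf)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  covm <- crossprod(Xc) / K
  list(mean_structure = unflatten_coords(mu), covariance = covm)
}

#' Eigendecompose a positional covariance matrix
#'
#' Eigenvalues are sorted descending and clamped to zero when marginally
#' negative (beyond `-1e-8 * lambda_1` is an error).  Each eigenvector's sign
#' is fixed by making its largest-magnitude component positive, which makes
#' dot-product matrices and projection densities reproducible.  Within a
#' degenerate eigenvalue block the ordering after this tiebreak is arbitrary.
#'
#' @param covariance symmetric 3Np x 3Np matrix (Angstrom^2).
#' @param mean_structure Np x 3 matrix.
#' @param tol asymmetry tolerance (relative).
#' @return object of class `pca_model` with fields `mean_structure`,
#'   `eigenvectors` (3Np x 3Np, orthonormal columns), `eigenvalues`
#'   (descending, Angstrom^2), `covariance`, `particle_count`.
#' @export
eigendecompose <- function(covariance, mean_structure, tol = 1e-8) {
  covariance <- as.matrix(covariance)
  scale <- max(1, max(abs(covariance)))
  if (max(abs(covariance - t(covariance))) > tol * scale) {
    stop("covariance matrix is not symmetric", call. = FALSE)
  }
  Np <- nrow(covariance) / 3
  if (!is.null(mean_structure)) stopifnot(nrow(mean_structure) == Np)
  eg <- eigen((covariance + t(covariance)) / 2, symmetric = TRUE)
  lam <- eg$values
  if (length(lam) > 0 && lam[1] > 0 && any(lam < -1e-8 * lam[1])) {
    stop("covariance has significantly negative eigenvalues", call. = FALSE)
  }
  lam[lam < 0] <- 0
  E <- eg$vectors
  # deterministic sign: largest-|component| positive
  for (k in seq_len(ncol(E))) {
    j <- which.max(abs(E[, k]))
    if (E[j, k] < 0) E[, k] <- -E[, k]
  }
  structure(
    list(
      mean_structure = mean_structure,
      eigenvectors = E,
      eigenvalues = lam,
      covariance = covariance,
      particle_count = as.integer(Np)
    ),
    class = "pca_model"
  )
}

#' PCA of an aligned ensemble
#'
#' Convenience wrapper: [compute_covariance()] followed by
#' [eigendecompose()].
#'
#' @param aligned an `aligned_ensemble`.
#' @return a `pca_model`.
#' @export
pca_model <- function(aligned) {
  cv <- compute_covariance(aligned)
  eigendecompose(cv$covariance, cv$mean_structure)
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d particles, %d modes; leading eigenvalues (A^2): %s\n",
              x$particle_count, length(x$eigenvalues),
              paste(signif(utils::head(x$eigenvalues, 5), 4), collapse = ", ")))
  invisible(x)
}

#' Eigenvalues normalized by the particle count
#'
#' Dividing by the number of particles makes spectra comparable between
#' models with different resolutions (atom vs bead counts).
#'
#' @param model a `pca_model`.
#' @return numeric vector, Angstrom^2 per particle.
#' @export
normalized_eigenvalues <- function(model) {
  if (model$particle_count <= 0) stop("particle count must be positive", call. = FALSE)
  model$eigenvalues / model$particle_count
}

#' Cumulative variance fractions
#'
#' @param model a `pca_model`.
#' @return monotone nondecreasing vector of cumulative fractions, last = 1.
#' @export
cumulative_variance <- function(model) {
  s <- sum(model$eigenvalues)
  if (s <= 0) stop("undefined fraction: all-zero eigenvalue spectrum", call. = FALSE)
  cumsum(model$eigenvalues) / s
}

#' Project conformations onto a PCA basis
#'
#' p_k = e_k^T (x - mean) per mode, in Angstrom.  Conformations must already
#' be aligned to the model's reference frame.
#'
#' @param ensemble a `molecule_ensemble` / `aligned_ensemble`.
#' @param model a `pca_model`.
#' @param modes number of leading modes (default 10 or all, whichever is
#'   smaller).
#' @return object of class `projection_series`: `values` is a modes x
#'   n_copies x n_frames array, plus `mode_ids` and `frame_interval`.
#' @export
project <- function(ensemble, model, modes = NULL) {
  conf <- ensemble$conformations
  Np <- dim(conf)[2]
  if (Np != model$particle_count) {
    stop(sprintf("shape error: ensemble has %d particles, model %d", Np, model$particle_count), call. = FALSE)
  }
  modes <- modes %||% min(10L, ncol(model$eigenvectors))
  X <- ensemble_matrix(conf)
  Xc <- sweep(X, 2, flatten_coords(model$mean_structure))
  P <- Xc %*% model$eigenvectors[, seq_len(modes), drop = FALSE]  # K x modes
  NL <- ensemble$n_copies %||% 1L
  T_ <- nrow(P) %/% NL
  vals <- array(0, dim = c(modes, NL, T_))
  for (c_ in seq_len(NL)) {
    vals[, c_, ] <- t(P[(c_ - 1L) * T_ + seq_len(T_), , drop = FALSE])
  }
  structure(
    list(values = vals, mode_ids = seq_len(modes),
         frame_interval = ensemble$frame_interval %||% NULL),
    class = "projection_series"
  )
}

#' Build a projection series from raw per-copy series
#'
#' @param values modes x copies x frames array (Angstrom).
#' @param frame_interval optional time per frame.
#' @return a `projection_series`.
#' @export
projection_series <- function(values, frame_interval = NULL) {
  stopifnot(length(dim(values)) == 3)
  assert_finite(values, "projection values")
  structure(
    list(values = values, mode_ids = seq_len(dim(values)[1]),
         frame_interval = frame_interval),
    class = "projection_series"
  )
}

#' @export
print.projection_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("projection_series: %d modes x %d copies x %d frames\n", d[1], d[2], d[3]))
  invisible(x)
}

#' Pearson correlation of two covariance matrices
#'
#' Correlation over all matrix elements; the standard scalar summary of how
#' similar two simulations' fluctuation patterns are.
#'
#' @param M_i,M_j equal-shape matrices.
#' @return r in `[-1, 1]`.
#' @export
covariance_pcc <- function(M_i, M_j) {
  if (!all(dim(M_i) == dim(M_j))) stop("shape error: covariance matrices differ in shape", call. = FALSE)
  a <- as.vector(M_i); b <- as.vector(M_j)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("undefined correlation: zero-variance element set", call. = FALSE)
  }
  stats::cor(a, b)
}

#' Dot-product matrix between two eigenvector bases
#'
#' Entry (a, b) is |e_a^i . e_b^j| for the leading k modes.  When `mapping`
#' is supplied, model_i's eigenvectors are first mapped to the bead space and
#' renormalized to unit length; mapped bases are generally no longer
#' orthogonal, so off-diagonal structure is expected there.
#'
#' @param model_i,model_j `pca_model`s (or eigenvector matrices).
#' @param k number of leading modes.
#' @param mapping optional [mapping_scheme()] applied to `model_i`.
#' @return k x k matrix of absolute dot products in `[0, 1]`, with mode-id
#'   dimnames.
#' @export
dot_product_matrix <- function(model_i, model_j, k, mapping = NULL) {
  Ei <- if (inherits(model_i, "pca_model")) model_i$eigenvectors else as.matrix(model_i)
  Ej <- if (inherits(model_j, "pca_model")) model_j$eigenvectors else as.matrix(model_j)
  Ei <- Ei[, seq_len(k), drop = FALSE]
  Ej <- Ej[, seq_len(k), drop = FALSE]
  if (!is.null(mapping)) {
    Ei <- apply(Ei, 2, map_vector, scheme = mapping)
    nrm <- sqrt(colSums(Ei^2))
    if (any(nrm == 0)) stop("mapped eigenvector vanished (kernel mode); cannot renormalize", call. = FALSE)
    Ei <- sweep(Ei, 2, nrm, `/`)
  }
  if (nrow(Ei) != nrow(Ej)) {
    stop(sprintf("shape error: bases live in dimensions %d and %d after mapping", nrow(Ei), nrow(Ej)), call. = FALSE)
  }
  D <- abs(crossprod(Ei, Ej))
  D[D > 1] <- 1  # clip fp overshoot
  dimnames(D) <- list(paste0("PC", seq_len(k)), paste0("PC", seq_len(k)))
  D
}

#' Joint PCA over several aligned ensembles
#'
#' Pools the conformations of all ensembles (equal per-ensemble conformation
#' counts required; unequal counts are an error rather than a silent
#' reweighting) and runs PCA on the pooled set.
#'
#' @param ensembles list of `aligned_ensemble`s with identical particle
#'   counts.
#' @return a `pca_model` fitted to the pooled ensemble.
#' @export
joint_pca <- function(ensembles) {
  stopifnot(length(ensembles) >= 1)
  Ks <- vapply(ensembles, function(e) dim(e$conformations)[1], integer(1))
  if (length(unique(Ks)) != 1) {
    stop(sprintf("joint PCA requires equal conformation counts per simulation; got %s",
                 paste(Ks, collapse = ", ")), call. = FALSE)
  }
  Nps <- vapply(ensembles, function(e) dim(e$conformations)[2], integer(1))
  if (length(unique(Nps)) != 1) stop("joint PCA requires equal particle counts", call. = FALSE)
  conf <- do.call(abind3, lapply(ensembles, function(e) e$conformations))
  pooled <- molecule_ensemble(conf, n_copies = 1L,
                              frame_interval = ensembles[[1]]$frame_interval)
  pca_model(pooled)
}

# bind K x Np x 3 arrays along the first dimension
abind3 <- function(...) {
  parts <- list(...)
  Np <- dim(parts[[1]])[2]
  M <- do.call(rbind, lapply(parts, ensemble_matrix))
  matrix_ensemble(M)
}

#' Export projections as CSV (mode, copy, frame, value)
#'
#' @param series a `projection_series`.
#' @param path output path.
#' @export
write_projections_csv <- function(series, path) {
  d <- dim(series$values)
  df <- data.frame(
    mode = rep(seq_len(d[1]), times = d[2] * d[3]),
    copy = rep(rep(seq_len(d[2]) - 1L, each = d[1]), times = d[3]),
    frame = rep(seq_len(d[3]) - 1L, each = d[1] * d[2]),
    value = as.vector(series$values)
  )
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
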