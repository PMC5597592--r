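# Coarse-grain mapping algebra: the m x n weight matrix omega taking atomic
# coordinates and displacements to bead coordinates and displacements, its
# kernel, and the motion-conservation ratio alpha.

#' Construct a coarse-grain mapping scheme
#'
#' Rows of the weight matrix are convex weight vectors over atoms: entries are
#' non-negative and each row is rescaled to sum to one (with a warning when
#' rescaling was needed).  Row normalization is what guarantees the
#' conservation ratio bound alpha <= 1 (Jensen's inequality).
#'
#' @param weights m beads x n atoms numeric matrix, entries >= 0.
#' @param bead_names length-m character vector.
#' @param atom_names length-n character vector.
#' @return object of class `mapping_scheme`.
#' @export
mapping_scheme <- function(weights, bead_names = NULL, atom_names = NULL,
                           warn_rescale = TRUE) {
  weights <- as.matrix(weights)
  m <- nrow(weights); n <- ncol(weights)
  if (m > n) stop("more beads than atoms is not a coarse-graining", call. = FALSE)
  if (any(weights < 0)) stop("mapping weights must be non-negative", call. = FALSE)
  rs <- rowSums(weights)
  if (any(rs == 0)) stop(sprintf("definition error: bead %d has no atoms", which(rs == 0)[1]), call. = FALSE)
  if (any(abs(rs - 1) > 1e-12)) {
    if (warn_rescale && any(abs(rs - 1) > 1e-9)) {
      warning("mapping rows rescaled to sum to 1")
    }
    weights <- weights / rs
  }
  structure(
    list(
      weights = weights,
      bead_names = bead_names %||% paste0("B", seq_len(m)),
      atom_names = atom_names %||% paste0("a", seq_len(n))
    ),
    class = "mapping_scheme"
  )
}

#' @export
print.mapping_scheme <- function(x, ...) {
  cat(sprintf("mapping_scheme: %d beads over %d atoms\n", nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

#' Read a mapping file
#'
#' Text dialect: comments start with `;`; an `[atoms]` block lists atom names
#' in order (any number of whitespace-separated names per line); every
#' subsequent line of the form `<bead>: <atom>[*weight] ...` defines one bead.
#' Unweighted atoms get weight 1 before row normalization.
#'
#' @param path file path.
#' @return a [mapping_scheme()].
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub(";.*$", "", lines))
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0 || tolower(lines[1]) != "[atoms]") {
    stop("mapping file must start with an [atoms] block", call. = FALSE)
  }
  lines <- lines[-1]
  is_bead <- grepl(":", lines, fixed = TRUE)
  first_bead <- which(is_bead)[1]
  if (is.na(first_bead)) stop("mapping file defines no beads", call. = FALSE)
  atom_names <- unlist(strsplit(lines[seq_len(first_bead - 1)], "\\s+"))
  atom_names <- atom_names[nzchar(atom_names)]
  if (length(atom_names) == 0) stop("empty [atoms] block", call. = FALSE)
  if (anyDuplicated(atom_names)) stop("duplicate atom names in [atoms] block", call. = FALSE)
  bead_lines <- lines[first_bead:length(lines)]
  if (!all(grepl(":", bead_lines, fixed = TRUE))) {
    stop("atom-name lines after the first bead definition are not allowed", call. = FALSE)
  }
  m <- length(bead_lines); n <- length(atom_names)
  W <- matrix(0, m, n)
  bead_names <- character(m)
  for (i in seq_len(m)) {
    parts <- strsplit(bead_lines[i], ":", fixed = TRUE)[[1]]
    bead_names[i] <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = ":")), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) == 0) stop(sprintf("definition error: bead '%s' lists no atoms", bead_names[i]), call. = FALSE)
    for (tok in toks) {
      aw <- strsplit(tok, "*", fixed = TRUE)[[1]]
      a <- aw[1]
      w <- if (length(aw) > 1) as.numeric(aw[2]) else 1
      j <- match(a, atom_names)
      if (is.na(j)) stop(sprintf("reference error: bead '%s' references undeclared atom '%s'", bead_names[i], a), call. = FALSE)
      if (is.na(w) || w < 0) stop(sprintf("invalid weight in bead '%s': '%s'", bead_names[i], tok), call. = FALSE)
      W[i, j] <- W[i, j] + w
    }
  }
  # dialect weights are relative by definition; normalization is expected
  mapping_scheme(W, bead_names, atom_names, warn_rescale = FALSE)
}

#' Uniform n:1 hypothetical mapping
#'
#' Consecutive blocks of `ratio` atoms form one equal-weight bead; when
#' `n_atoms` is not a multiple of `ratio`, the final bead absorbs the
#' remainder.
#'
#' @param n_atoms number of atoms.
#' @param ratio atoms per bead, `1 <= ratio <= n_atoms`.
#' @return a [mapping_scheme()].
#' @export
uniform_mapping <- function(n_atoms, ratio) {
  if (ratio < 1) stop("ratio must be >= 1", call. = FALSE)
  if (ratio > n_atoms) stop("ratio cannot exceed the atom count", call. = FALSE)
  m <- n_atoms %/% ratio
  sizes <- rep(ratio, m)
  sizes[m] <- sizes[m] + n_atoms %% ratio
  W <- matrix(0, m, n_atoms)
  start <- 1L
  for (i in seq_len(m)) {
    W[i, start:(start + sizes[i] - 1L)] <- 1 / sizes[i]
    start <- start + sizes[i]
  }
  mapping_scheme(W, paste0("U", seq_len(m)))
}

#' Coarse-grain coordinates
#'
#' Applies C = omega A per frame: bead coordinates are the weighted averages
#' of their atoms' coordinates.
#'
#' @param coords n x 3 matrix or T x n x 3 array (Angstrom).
#' @param scheme a [mapping_scheme()].
#' @return m x 3 matrix or T x m x 3 array.
#' @export
map_coordinates <- function(coords, scheme) {
  W <- scheme$weights
  if (is.matrix(coords)) {
    if (nrow(coords) != ncol(W)) {
      stop(sprintf("shape error: %d atoms vs mapping over %d", nrow(coords), ncol(W)), call. = FALSE)
    }
    return(W %*% coords)
  }
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3)
  if (dim(coords)[2] != ncol(W)) {
    stop(sprintf("shape error: %d atoms vs mapping over %d", dim(coords)[2], ncol(W)), call. = FALSE)
  }
  T_ <- dim(coords)[1]; m <- nrow(W)
  # flatten frames, map all at once: (T x 3n) %*% t(kron) is equivalent to
  # per-axis multiplication; do it axis-wise to avoid the Kronecker product
  out <- array(0, dim = c(T_, m, 3))
  for (a in 1:3) out[, , a] <- coords[, , a] %*% t(W)
  out
}

#' Coarse-grain a displacement vector
#'
#' Maps a flattened 3n atomic displacement (particle-major, see
#' [flatten_coords()]) to the 3m bead displacement, componentwise per axis.
#'
#' @param e_aa numeric vector of length 3n.
#' @param scheme a [mapping_scheme()].
#' @return numeric vector of length 3m.
#' @export
map_vector <- function(e_aa, scheme) {
  W <- scheme$weights
  n <- ncol(W)
  if (length(e_aa) != 3L * n) {
    stop(sprintf("shape error: vector length %d, expected %d", length(e_aa), 3L * n), call. = FALSE)
  }
  flatten_coords(W %*% unflatten_coords(e_aa))
}

#' Motion conservation ratio upon coarse graining
#'
#' alpha = RMSD_cg / RMSD_aa for a collective displacement: the fraction of
#' the (weighted) atomic displacement RMSD that survives mapping to beads.
#' The numerator averages squared bead displacements; the denominator is the
#' mapping-weighted mean of squared atomic displacements, so alpha is bounded
#' by 1 for convex row weights.
#'
#' @param e_aa flattened 3n atomic displacement vector (nonzero).
#' @param scheme a [mapping_scheme()].
#' @return alpha in `[0, 1]`.
#' @export
conservation_ratio <- function(e_aa, scheme) {
  W <- scheme$weights
  n <- ncol(W); m <- nrow(W)
  if (length(e_aa) != 3L * n) {
    stop(sprintf("shape error: vector length %d, expected %d", length(e_aa), 3L * n), call. = FALSE)
  }
  if (all(e_aa == 0)) stop("conservation ratio undefined for the zero vector", call. = FALSE)
  e_cg <- W %*% unflatten_coords(e_aa)           # m x 3 bead displacements
  atom_sq <- rowSums(unflatten_coords(e_aa)^2)   # |e_j|^2 per atom
  num <- sqrt(sum(e_cg^2) / m)
  den <- sqrt(sum(W %*% atom_sq) / m)
  a <- num / den
  min(max(a, 0), 1)
}

#' Conservation profile of a PCA basis under a mapping
#'
#' @param model a [pca_model()] (or any 3n x k eigenvector matrix).
#' @param scheme a [mapping_scheme()].
#' @param modes number of leading modes to evaluate (default: all columns).
#' @param label profile label.
#' @return data.frame of class `conservation_profile` with columns `mode`
#'   (1-based) and `alpha`.
#' @export
conservation_profile <- function(model, scheme, modes = NULL, label = "") {
  E <- if (inherits(model, "pca_model")) model$eigenvectors else as.matrix(model)
  modes <- modes %||% ncol(E)
  alpha <- vapply(seq_len(modes), function(k) conservation_ratio(E[, k], scheme), numeric(1))
  structure(
    data.frame(mode = seq_len(modes), alpha = alpha),
    class = c("conservation_profile", "data.frame"),
    mapping_label = label
  )
}

#' Test whether a displacement lies in the mapping kernel
#'
#' The kernel (null space) of the mapping holds the atomic motions eliminated
#' by coarse graining: intra-bead relative motions that map to zero bead
#' displacement.
#'
#' @param e flattened 3n displacement vector.
#' @param scheme a [mapping_scheme()].
#' @param tol relative tolerance (default 1e-10).
#' @return `TRUE` iff `|map_vector(e)| <= tol * |e|`.
#' @export
in_kernel <- function(e, scheme, tol = 1e-10) {
  sqrt(sum(map_vector(e, scheme)^2)) <= tol * sqrt(sum(e^2))
}

#' Coarse-grain a covariance matrix
#'
#' Returns (omega (x) I3) M (omega (x) I3)^T, the covariance a mapped
#' trajectory would have.  This is the consistency bridge between the
#' map-then-PCA and PCA-then-map comparison routes.
#'
#' @param cov symmetric 3n x 3n matrix (Angstrom^2).
#' @param scheme a [mapping_scheme()].
#' @param tol asymmetry tolerance.
#' @return symmetric 3m x 3m matrix.
#' @export
map_covariance <- function(cov, scheme, tol = 1e-8) {
  W <- scheme$weights
  n <- ncol(W)
  if (nrow(cov) != 3L * n || ncol(cov) != 3L * n) {
    stop(sprintf("shape error: covariance is %dx%d, expected %dx%d",
                 nrow(cov), ncol(cov), 3L * n, 3L * n), call. = FALSE)
  }
  if (max(abs(cov - t(cov))) > tol * max(1, max(abs(cov)))) {
    stop("covariance matrix is not symmetric", call. = FALSE)
  }
  Wk <- kronecker(W, diag(3))
  out <- Wk %*% cov %*% t(Wk)
  (out + t(out)) / 2
}

#' Orthonormal basis of the mapping kernel
#'
#' Computed from the SVD of omega (x) I3; used as an oracle for
#' [in_kernel()] and for alpha = 0 checks.
#'
#' @param scheme a [mapping_scheme()].
#' @return 3n x (3n - 3m) matrix of orthonormal kernel basis vectors.
#' @export
mapping_kernel_basis <- function(scheme) {
  Wk <- kronecker(scheme$weights, diag(3))
  sv <- svd(Wk, nu = 0, nv = ncol(Wk))
  r <- sum(sv$d > 1e-12 * sv$d[1])
  sv$v[, seq(r + 1, ncol(Wk)), drop = FALSE]
}

#' Export a conservation profile as CSV
#'
#' @param profile a [conservation_profile()].
#' @param path output path.
#' @export
write_conservation_csv <- function(profile, path) {
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
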