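# Synthetic multi-copy pseudo-lipid trajectories with planted collective
# modes, Ornstein-Uhlenbeck temporal correlation and known ground truth.
# Every pipeline stage can be validated against these without external data.
#
# The generator emulates pooled single-lipid conformational ensembles:
# a fixed particle topology, a few dominant orthonormal modes with prescribed
# variances, OU dynamics per mode, optional per-frame rigid motion per copy,
# and several statistically independent molecule copies per frame.  It does
# NOT emulate inter-molecular correlations, solvent, or any force field.

#' Deterministic two-tailed pseudo-lipid geometry
#'
#' A head stack plus `tails` zig-zag chains, mirror-symmetric about the
#' x = 0 plane (for two tails).  Particle names distinguish head (`N*`) and
#' tail/chain (`C<j><chain>`) so selections and mapping files can address
#' them; all particles are heavy.
#'
#' @param n_head head particles (>= 1).
#' @param n_tail particles per tail (>= 2).
#' @param tails number of tails (default 2).
#' @return list with `coordinates` (N x 3, Angstrom) and `particles`.
#' @export
make_pseudo_lipid <- function(n_head = 3, n_tail = 4, tails = 2) {
  stopifnot(n_head >= 1, n_tail >= 2, tails >= 1)
  bond <- 1.5  # Angstrom-ish spacing
  coords <- matrix(0, 0, 3)
  name <- character(0); chain_off <- if (tails == 1) 0 else seq(-2, 2, length.out = tails)
  for (i in seq_len(n_head)) {
    coords <- rbind(coords, c(0, 0.4 * (i %% 2), bond * (n_tail + i)))
    name <- c(name, paste0("N", i))
  }
  chain_letters <- LETTERS[seq_len(tails)]
  for (c_ in seq_len(tails)) {
    for (j in seq_len(n_tail)) {
      coords <- rbind(coords, c(chain_off[c_], 0.6 * (j %% 2), bond * (n_tail - j)))
      name <- c(name, paste0("C", j, chain_letters[c_]))
    }
  }
  n <- nrow(coords)
  list(
    coordinates = unname(coords),
    particles = particle_table(name, rep("PLIP", n), rep(1L, n), element = rep("C", n))
  )
}

#' Specification of a synthetic pseudo-lipid system
#'
#' Defaults describe the standard validation world: an 11-particle
#' pseudo-lipid with five planted orthonormal modes of variance
#' (9, 4, 2, 1, 0.5) Angstrom^2 over an isotropic 0.05 Angstrom^2 noise
#' floor, OU relaxation times (50, 40, 30, 20, 10) frames, 16 independent
#' copies and 20000 frames.
#'
#' @param base list from [make_pseudo_lipid()] (default 3 head + 2 x 4 tail).
#' @param planted_eigenvalues descending mode variances, Angstrom^2.
#' @param tau_ou per-mode OU relaxation times, frames.
#' @param noise_floor isotropic variance (Angstrom^2) applied to the
#'   directions orthogonal to the planted modes.
#' @param n_copies molecule copies per frame.
#' @param n_frames frames.
#' @param rigid_motion apply a random rigid motion per copy per frame.
#' @param seed integer master seed; per-copy substreams are derived from it
#'   deterministically.
#' @param planted_modes optional 3N x k orthonormal matrix; drawn
#'   deterministically from the seed when `NULL`.
#' @param mode1_offsets optional vector of per-copy mean offsets for mode 1
#'   (a Gaussian-mixture stationary density to exercise non-Gaussian
#'   density/potential code); recycled over copies.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(base = make_pseudo_lipid(),
                           planted_eigenvalues = c(9, 4, 2, 1, 0.5),
                           tau_ou = c(50, 40, 30, 20, 10),
                           noise_floor = 0.05,
                           n_copies = 16L,
                           n_frames = 20000L,
                           rigid_motion = FALSE,
                           seed = 42L,
                           planted_modes = NULL,
                           mode1_offsets = NULL) {
  k <- length(planted_eigenvalues)
  stopifnot(length(tau_ou) == k, all(tau_ou > 0), all(diff(planted_eigenvalues) <= 0))
  if (any(planted_eigenvalues <= noise_floor)) {
    stop("planted eigenvalues must exceed the noise floor", call. = FALSE)
  }
  n3 <- 3L * nrow(base$coordinates)
  if (is.null(planted_modes)) {
    set.seed(seed %% 2147483647L)
    M <- matrix(stats::rnorm(n3 * k), n3, k)
    # internal collective modes are orthogonal to rigid-body motion; without
    # this the alignment stage would shear the planted subspace
    Rb <- rigid_body_basis(base$coordinates)
    M <- M - Rb %*% crossprod(Rb, M)
    M <- qr.Q(qr(M))
  } else {
    M <- as.matrix(planted_modes)
    G <- crossprod(M)
    if (max(abs(G - diag(k))) > 1e-10) stop("planted modes must be orthonormal", call. = FALSE)
  }
  structure(
    list(base = base, planted_modes = M,
         planted_eigenvalues = planted_eigenvalues, tau_ou = tau_ou,
         noise_floor = noise_floor, n_copies = as.integer(n_copies),
         n_frames = as.integer(n_frames), rigid_motion = rigid_motion,
         seed = as.integer(seed), mode1_offsets = mode1_offsets),
    class = "synthetic_spec"
  )
}

#' Orthonormal basis of rigid-body motions about a structure
#'
#' Three uniform translations plus three infinitesimal rotation generators
#' about the centroid, flattened particle-major and orthonormalized.
#'
#' @param coords N x 3 matrix (Angstrom).
#' @return 3N x 6 matrix with orthonormal columns.
#' @export
rigid_body_basis <- function(coords) {
  N <- nrow(coords)
  xc <- sweep(coords, 2, colMeans(coords))
  cols <- list()
  for (a in 1:3) {
    e <- matrix(0, N, 3); e[, a] <- 1
    cols[[a]] <- flatten_coords(e)
  }
  axes <- diag(3)
  for (a in 1:3) {
    r <- t(apply(xc, 1, function(x) crossprod_vec(axes[a, ], x)))
    cols[[3 + a]] <- flatten_coords(r)
  }
  qr.Q(qr(do.call(cbind, cols)))
}

crossprod_vec <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# deterministic per-copy substream seed, kept inside 32-bit range
copy_seed <- function(seed, copy) {
  as.integer((as.numeric(seed) * 7919 + copy * 104729) %% 2147483647)
}

#' Stationary Ornstein-Uhlenbeck mode amplitude series
#'
#' Exact discretization: a_{t+1} = phi a_t + sqrt(lambda (1 - phi^2)) eps
#' with phi = exp(-1 / tau), initialized from the stationary distribution
#' N(0, lambda), so mean 0, variance lambda_k and autocorrelation
#' exp(-tau_lag / tau_k) hold at every lag.
#'
#' @param spec a [synthetic_spec()].
#' @param copy 1-based copy index selecting the deterministic substream.
#' @return k x T matrix of mode amplitudes (Angstrom).
#' @export
sample_ou_modes <- function(spec, copy = 1L) {
  k <- length(spec$planted_eigenvalues)
  T_ <- spec$n_frames
  set.seed(copy_seed(spec$seed, copy))
  A <- matrix(0, k, T_)
  for (m in seq_len(k)) {
    lam <- spec$planted_eigenvalues[m]
    phi <- exp(-1 / spec$tau_ou[m])
    a0 <- stats::rnorm(1, 0, sqrt(lam))
    eps <- stats::rnorm(T_ - 1, 0, sqrt(lam * (1 - phi^2)))
    A[m, ] <- c(a0, stats::filter(eps, phi, method = "recursive", init = a0))
  }
  if (!is.null(spec$mode1_offsets)) {
    off <- rep(spec$mode1_offsets, length.out = spec$n_copies)[copy]
    A[1, ] <- A[1, ] + off
  }
  A
}

random_rotation <- function() {
  # uniform rotation from a normalized quaternion
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

#' Generate a synthetic multi-copy trajectory with known ground truth
#'
#' Each copy's conformation at frame t is
#' base + sum_k a_k(t) mode_k + orthogonal isotropic noise, with the mode
#' amplitudes a_k following independent stationary OU processes per copy.
#' The noise is projected off the planted modes so the planted variances are
#' exact.  With `rigid_motion = TRUE` every copy additionally receives an
#' independent random rotation and translation per frame (exercising the
#' superposition stage).
#'
#' @param spec a [synthetic_spec()].
#' @return list with `trajectory` (an [md_trajectory()] carrying all copies),
#'   `ensemble` (the pooled `molecule_ensemble` in generation order, before
#'   any rigid motion), and `ground_truth` (planted modes, eigenvalues,
#'   relaxation times, base structure).
#' @export
generate_system <- function(spec) {
  base_flat <- flatten_coords(spec$base$coordinates)
  n3 <- length(base_flat)
  Np <- n3 %/% 3L
  M <- spec$planted_modes
  NL <- spec$n_copies; T_ <- spec$n_frames
  conf <- array(0, dim = c(NL * T_, Np, 3))
  traj_coords <- array(0, dim = c(T_, NL * Np, 3))
  for (c_ in seq_len(NL)) {
    A <- sample_ou_modes(spec, c_)           # k x T (also advances to the copy stream)
    X <- t(A) %*% t(M)                       # T x 3Np planted displacements
    if (spec$noise_floor > 0) {
      E <- matrix(stats::rnorm(T_ * n3, 0, sqrt(spec$noise_floor)), T_, n3)
      E <- E - (E %*% M) %*% t(M)            # keep noise orthogonal to planted modes
      X <- X + E
    }
    X <- sweep(X, 2, base_flat, `+`)
    copy_conf <- matrix_ensemble(X)
    conf[(c_ - 1L) * T_ + seq_len(T_), , ] <- copy_conf
    if (spec$rigid_motion) {
      for (t in seq_len(T_)) {
        R <- random_rotation()
        shift <- stats::runif(3, -20, 20)
        copy_conf[t, , ] <- sweep(copy_conf[t, , ] %*% R, 2, shift, `+`)
      }
    }
    traj_coords[, (c_ - 1L) * Np + seq_len(Np), ] <- copy_conf
  }
  base_pt <- spec$base$particles
  pt <- do.call(rbind, lapply(seq_len(NL), function(c_) {
    p <- base_pt
    p$residue_id <- c_
    p
  }))
  pt$particle_id <- seq_len(nrow(pt)) - 1L
  rownames(pt) <- NULL
  list(
    trajectory = md_trajectory(traj_coords, pt, frame_interval = 1),
    ensemble = molecule_ensemble(conf, n_copies = NL, frame_interval = 1,
                                 particles = base_pt),
    ground_truth = list(
      modes = M,
      eigenvalues = spec$planted_eigenvalues,
      tau_ou = spec$tau_ou,
      noise_floor = spec$noise_floor,
      base = spec$base$coordinates
    )
  )
}

#' Write a synthetic system to disk as standard formats
#'
#' Emits a GRO structure, a plain-text trajectory and a plain-text
#' ground-truth sidecar, so synthetic data flows through the same readers as
#' real data.
#'
#' @param system output of [generate_system()].
#' @param dir output directory (created if missing).
#' @param stem file name stem.
#' @return invisibly, the paths written.
#' @export
write_synthetic_system <- function(system, dir, stem = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gro <- file.path(dir, paste0(stem, ".gro"))
  trj <- file.path(dir, paste0(stem, ".trj"))
  gtf <- file.path(dir, paste0(stem, "_ground_truth.txt"))
  write_structure_gro(system$trajectory$coordinates[1, , ],
                      system$trajectory$particles, gro)
  write_trajectory_text(system$trajectory, trj)
  gt <- system$ground_truth
  con <- file(gtf, "w"); on.exit(close(con))
  writeLines(c(
    paste("eigenvalues", paste(format(gt$eigenvalues, digits = 17), collapse = " ")),
    paste("tau_ou", paste(format(gt$tau_ou, digits = 17), collapse = " ")),
    paste("noise_floor", format(gt$noise_floor, digits = 17)),
    "modes"
  ), con)
  utils::write.table(gt$modes, con, row.names = FALSE, col.names = FALSE)
  invisible(c(gro = gro, trajectory = trj, ground_truth = gtf))
}
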