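# Structure / trajectory / mapping file IO and per-molecule ensemble
# extraction.
#
# Internal length unit is Angstrom everywhere; GRO nanometre values are
# converted on read.  Indices in the data model are 0-based (particle_id);
# 1-based indexing appears only at R's subscript boundary.

#' Build a particle metadata table
#'
#' @param name character vector of atom/bead names (non-empty).
#' @param residue_name character vector of residue names.
#' @param residue_id integer vector of residue ids.
#' @param element optional explicit element symbols; inferred from names when
#'   `NULL` (leading alphabetic character after stripping digits; `H` means
#'   hydrogen).
#' @return data.frame with columns `particle_id` (0-based, contiguous),
#'   `name`, `residue_name`, `residue_id`, `element`, `is_heavy`.
#' @export
particle_table <- function(name, residue_name, residue_id, element = NULL) {
  n <- length(name)
  stopifnot(n >= 1, length(residue_name) == n, length(residue_id) == n)
  if (any(!nzchar(name))) stop("every particle needs a non-empty name", call. = FALSE)
  if (is.null(element)) {
    element <- infer_element(name)
  }
  unknown <- !nzchar(element)
  if (any(unknown)) {
    warning(sprintf("%d particle(s) with unknown element; treating as heavy", sum(unknown)))
  }
  data.frame(
    particle_id = seq_len(n) - 1L,
    name = as.character(name),
    residue_name = as.character(residue_name),
    residue_id = as.integer(residue_id),
    element = as.character(element),
    is_heavy = element != "H",
    stringsAsFactors = FALSE
  )
}

# Element from atom-name convention used by lipid force fields (H11X, C216):
# strip digits, take the first alphabetic character.
infer_element <- function(name) {
  stripped <- gsub("[0-9'\"]", "", name)
  el <- toupper(substr(stripped, 1, 1))
  el[is.na(el)] <- ""
  el
}

#' Read a structure file (PDB or GRO)
#'
#' Coordinates are returned in Angstrom (GRO nm values multiplied by 10).
#' Particle order is file order.
#'
#' @param path file path.
#' @param format `"pdb"` or `"gro"`; guessed from the extension when missing.
#' @return list with elements `particles` (see [particle_table()]) and
#'   `coordinates` (N x 3 matrix, Angstrom).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "gro")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gro$", path, ignore.case = TRUE)) "gro" else "pdb"
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  switch(format,
    pdb = parse_pdb_atoms(lines, path),
    gro = parse_gro(lines, path)
  )
}

parse_pdb_atoms <- function(lines, path = "<pdb>") {
  rec <- substr(lines, 1, 6)
  sel <- which(rec %in% c("ATOM  ", "HETATM") | substr(rec, 1, 4) %in% c("ATOM", "HETA"))
  if (length(sel) == 0) stop(sprintf("no ATOM/HETATM records in %s", path), call. = FALSE)
  ln <- lines[sel]
  name <- trimws(substr(ln, 13, 16))
  resn <- trimws(substr(ln, 18, 21))
  resi <- suppressWarnings(as.integer(trimws(substr(ln, 23, 26))))
  x <- suppressWarnings(as.numeric(substr(ln, 31, 38)))
  y <- suppressWarnings(as.numeric(substr(ln, 39, 46)))
  z <- suppressWarnings(as.numeric(substr(ln, 47, 54)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resi))
  if (length(bad) > 0) {
    stop(sprintf("malformed PDB record at line %d of %s", sel[bad[1]], path), call. = FALSE)
  }
  list(
    particles = particle_table(name, resn, resi),
    coordinates = cbind(x = x, y = y, z = z)
  )
}

parse_gro <- function(lines, path = "<gro>") {
  if (length(lines) < 3) stop(sprintf("truncated GRO file %s", path), call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[2])))
  if (is.na(n) || n < 1) stop(sprintf("malformed atom count at line 2 of %s", path), call. = FALSE)
  if (length(lines) < 2 + n) stop(sprintf("GRO file %s truncated: expected %d atom lines", path, n), call. = FALSE)
  ln <- lines[3:(2 + n)]
  resi <- suppressWarnings(as.integer(substr(ln, 1, 5)))
  resn <- trimws(substr(ln, 6, 10))
  name <- trimws(substr(ln, 11, 15))
  x <- suppressWarnings(as.numeric(substr(ln, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(ln, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(ln, 37, 44)))
  bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resi))
  if (length(bad) > 0) {
    stop(sprintf("malformed GRO record at line %d of %s", 2 + bad[1], path), call. = FALSE)
  }
  list(
    particles = particle_table(name, resn, resi),
    coordinates = cbind(x = x, y = y, z = z) * 10  # nm -> Angstrom
  )
}

#' Construct a trajectory object
#'
#' @param coordinates T x N x 3 array, Angstrom.
#' @param particles particle table of length N.
#' @param frame_interval optional time between frames (arbitrary time units,
#'   typically ps).
#' @param box optional per-frame 3-vector of box lengths (T x 3 matrix,
#'   Angstrom); must be strictly positive.
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(coordinates, particles, frame_interval = NULL, box = NULL) {
  stopifnot(length(dim(coordinates)) == 3, dim(coordinates)[3] == 3)
  if (dim(coordinates)[1] < 1) stop("trajectory needs at least one frame", call. = FALSE)
  if (dim(coordinates)[2] != nrow(particles)) {
    stop(sprintf("shape error: %d particles in coordinates vs %d in particle table",
                 dim(coordinates)[2], nrow(particles)), call. = FALSE)
  }
  assert_finite(coordinates)
  if (!is.null(box)) {
    box <- matrix(box, ncol = 3)
    if (nrow(box) == 1) box <- box[rep(1, dim(coordinates)[1]), , drop = FALSE]
    stopifnot(nrow(box) == dim(coordinates)[1])
    if (any(box <= 0)) stop("box lengths must be strictly positive", call. = FALSE)
  }
  structure(
    list(coordinates = coordinates, particles = particles,
         frame_interval = frame_interval, box = box),
    class = "md_trajectory"
  )
}

#' @export
print.md_trajectory <- function(x, ...) {
  d <- dim(x$coordinates)
  cat(sprintf("md_trajectory: %d frames x %d particles%s%s\n", d[1], d[2],
              if (!is.null(x$frame_interval)) sprintf(", dt = %g", x$frame_interval) else "",
              if (!is.null(x$box)) ", periodic box" else ""))
  invisible(x)
}

#' Read a multi-frame trajectory
#'
#' Supported formats: `"text"` (documented plain-text frames: header line
#' `"T N"`, then T blocks of N lines `"x y z"` in Angstrom) and
#' `"multi_pdb"` (MODEL/ENDMDL blocks).  Binary XTC/DCD readers are not
#' bundled; requesting them raises an informative error.
#'
#' @param path file path.
#' @param particles particle table whose length must equal the per-frame
#'   particle count.
#' @param format one of `"auto"`, `"text"`, `"multi_pdb"`, `"xtc"`, `"dcd"`.
#' @param frame_interval optional time between frames.
#' @return an [md_trajectory()].
#' @export
read_trajectory <- function(path, particles,
                            format = c("auto", "text", "multi_pdb", "xtc", "dcd"),
                            frame_interval = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(sub(".*\\.", "", path))
    format <- switch(ext, pdb = "multi_pdb", xtc = "xtc", dcd = "dcd", "text")
  }
  if (format %in% c("xtc", "dcd")) {
    stop(sprintf("binary %s trajectories are not supported by this build; convert to multi-model PDB or the plain-text frame format", toupper(format)), call. = FALSE)
  }
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "text") read_trajectory_text(path, particles, frame_interval)
  else read_trajectory_multipdb(path, particles, frame_interval)
}

read_trajectory_text <- function(path, particles, frame_interval = NULL) {
  first <- scan(path, what = numeric(), nlines = 1, quiet = TRUE)
  if (length(first) != 2) stop(sprintf("malformed header in %s: expected 'T N'", path), call. = FALSE)
  T_ <- as.integer(first[1]); N <- as.integer(first[2])
  if (N != nrow(particles)) {
    stop(sprintf("shape error: trajectory has %d particles per frame, particle table has %d",
                 N, nrow(particles)), call. = FALSE)
  }
  vals <- scan(path, what = numeric(), skip = 1, quiet = TRUE)
  need <- T_ * N * 3L
  if (length(vals) < need) {
    got_frames <- length(vals) %/% (N * 3L)
    stop(sprintf("truncated trajectory %s at frame %d (expected %d frames)", path, got_frames + 1L, T_), call. = FALSE)
  }
  # values are row-major per frame: frame-by-frame, particle-by-particle, xyz
  coords <- aperm(array(vals[seq_len(need)], dim = c(3, N, T_)), c(3, 2, 1))
  md_trajectory(coords, particles, frame_interval = frame_interval)
}

read_trajectory_multipdb <- function(path, particles, frame_interval = NULL) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) == 0) {
    # single implicit model
    frames <- list(parse_pdb_atoms(lines, path)$coordinates)
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) < length(model_starts)) {
      stop(sprintf("truncated trajectory %s at frame %d (missing ENDMDL)", path, length(model_starts)), call. = FALSE)
    }
    frames <- lapply(seq_along(model_starts), function(i) {
      blk <- lines[model_starts[i]:model_ends[i]]
      parse_pdb_atoms(blk, path)$coordinates
    })
  }
  N <- nrow(particles)
  for (i in seq_along(frames)) {
    if (nrow(frames[[i]]) != N) {
      stop(sprintf("shape error: frame %d has %d particles, particle table has %d",
                   i, nrow(frames[[i]]), N), call. = FALSE)
    }
  }
  coords <- array(0, dim = c(length(frames), N, 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  md_trajectory(coords, particles, frame_interval = frame_interval)
}

#' Write a trajectory in the plain-text frame format
#'
#' Header `"T N"`, then T blocks of N lines `"x y z"` (Angstrom, full double
#' precision).
#'
#' @param traj an [md_trajectory()].
#' @param path output path.
#' @export
write_trajectory_text <- function(traj, path) {
  d <- dim(traj$coordinates)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", d[1], d[2]), con)
  M <- matrix(aperm(traj$coordinates, c(3, 2, 1)), nrow = 3)  # 3 x (N*T)
  writeLines(sprintf("%.17g %.17g %.17g", M[1, ], M[2, ], M[3, ]), con)
  invisible(path)
}

#' Write coordinates as a single-model PDB
#'
#' @param coordinates N x 3 matrix, Angstrom.
#' @param particles particle table of length N.
#' @param path output path.
#' @export
write_structure_pdb <- function(coordinates, particles, path) {
  stopifnot(nrow(coordinates) == nrow(particles))
  ln <- sprintf("ATOM  %5d %-4s %-4s%5d    %8.3f%8.3f%8.3f  1.00  0.00",
                particles$particle_id + 1L,
                substr(particles$name, 1, 4),
                substr(particles$residue_name, 1, 4),
                particles$residue_id %% 100000L,
                coordinates[, 1], coordinates[, 2], coordinates[, 3])
  writeLines(c(ln, "END"), path)
  invisible(path)
}

#' Write a structure as GRO (Angstrom input, nm output)
#'
#' @param coordinates N x 3 matrix, Angstrom.
#' @param particles particle table.
#' @param path output path.
#' @param box 3-vector of box lengths in Angstrom (default large empty box).
#' @export
write_structure_gro <- function(coordinates, particles, path, box = c(100, 100, 100)) {
  stopifnot(nrow(coordinates) == nrow(particles))
  ln <- sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                particles$residue_id %% 100000L,
                substr(particles$residue_name, 1, 5),
                substr(particles$name, 1, 5),
                (particles$particle_id + 1L) %% 100000L,
                coordinates[, 1] / 10, coordinates[, 2] / 10, coordinates[, 3] / 10)
  writeLines(c("generated structure", sprintf("%5d", nrow(particles)), ln,
               sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10, box[3] / 10)),
             path)
  invisible(path)
}

#' Extract the pooled per-molecule conformational ensemble
#'
#' All residues whose name matches `residue_name` are treated as copies of the
#' same molecule; their per-frame conformations are pooled in copy-major,
#' frame-minor order (all frames of copy 1, then copy 2, ...), which makes
#' downstream PCA bit-reproducible.
#'
#' @param traj an [md_trajectory()].
#' @param residue_name residue name selecting the molecule copies.
#' @param heavy_only drop hydrogens when `TRUE`.
#' @return object of class `molecule_ensemble` with fields `conformations`
#'   (K x Np x 3 array, K = n_copies x T), `source_labels` (data.frame of
#'   0-based `copy`, `frame`), `n_copies`, `particles` (per-molecule table).
#' @export
extract_molecule_ensemble <- function(traj, residue_name, heavy_only = TRUE) {
  pt <- traj$particles
  sel <- pt$residue_name == residue_name
  if (!any(sel)) {
    stop(sprintf("empty selection: no residues named '%s'", residue_name), call. = FALSE)
  }
  ids <- unique(pt$residue_id[sel])
  per_copy <- lapply(ids, function(rid) which(sel & pt$residue_id == rid))
  name_seqs <- lapply(per_copy, function(ix) pt$name[ix])
  for (i in seq_along(name_seqs)[-1]) {
    if (!identical(name_seqs[[i]], name_seqs[[1]])) {
      d <- which(name_seqs[[i]] != name_seqs[[1]] |
                   is.na(name_seqs[[i]]) | length(name_seqs[[i]]) != length(name_seqs[[1]]))
      stop(sprintf("topology error: copy %d (residue_id %d) differs from copy 1 at particle %d ('%s' vs '%s')",
                   i, ids[i], d[1], name_seqs[[i]][d[1]], name_seqs[[1]][d[1]]), call. = FALSE)
    }
  }
  keep <- if (heavy_only) pt$is_heavy[per_copy[[1]]] else rep(TRUE, length(per_copy[[1]]))
  per_copy <- lapply(per_copy, function(ix) ix[keep])
  Np <- length(per_copy[[1]])
  if (Np == 0) stop("empty selection after hydrogen filtering", call. = FALSE)
  T_ <- dim(traj$coordinates)[1]
  NL <- length(per_copy)
  conf <- array(0, dim = c(NL * T_, Np, 3))
  for (c_ in seq_len(NL)) {
    rows <- (c_ - 1L) * T_ + seq_len(T_)
    conf[rows, , ] <- traj$coordinates[, per_copy[[c_]], , drop = FALSE]
  }
  mol_particles <- pt[per_copy[[1]], , drop = FALSE]
  mol_particles$particle_id <- seq_len(Np) - 1L
  rownames(mol_particles) <- NULL
  structure(
    list(
      conformations = conf,
      source_labels = data.frame(
        copy = rep(seq_len(NL) - 1L, each = T_),
        frame = rep(seq_len(T_) - 1L, times = NL)
      ),
      n_copies = NL,
      n_frames = T_,
      frame_interval = traj$frame_interval,
      particles = mol_particles
    ),
    class = "molecule_ensemble"
  )
}

#' Construct a molecule ensemble directly from a conformation array
#'
#' @param conformations K x Np x 3 array (Angstrom).
#' @param n_copies number of molecule copies pooled (K must be a multiple).
#' @param frame_interval optional time between frames.
#' @param particles optional per-molecule particle table.
#' @return a `molecule_ensemble`.
#' @export
molecule_ensemble <- function(conformations, n_copies = 1L, frame_interval = NULL,
                              particles = NULL) {
  stopifnot(length(dim(conformations)) == 3, dim(conformations)[3] == 3)
  K <- dim(conformations)[1]
  stopifnot(K %% n_copies == 0)
  T_ <- K %/% n_copies
  structure(
    list(
      conformations = conformations,
      source_labels = data.frame(
        copy = rep(seq_len(n_copies) - 1L, each = T_),
        frame = rep(seq_len(T_) - 1L, times = n_copies)
      ),
      n_copies = as.integer(n_copies),
      n_frames = T_,
      frame_interval = frame_interval,
      particles = particles
    ),
    class = "molecule_ensemble"
  )
}

#' @export
print.molecule_ensemble <- function(x, ...) {
  d <- dim(x$conformations)
  cat(sprintf("molecule_ensemble: %d conformations (%d copies x %d frames), %d particles\n",
              d[1], x$n_copies, x$n_frames, d[2]))
  invisible(x)
}

#' Make molecules whole across periodic boundaries
#'
#' Applies minimum-image shifts of each particle relative to the first
#' particle of its residue, using the per-frame box.  This is a heuristic for
#' molecules smaller than half the box; it does not do general PBC wrapping.
#'
#' @param traj an [md_trajectory()] with a box.
#' @return an unwrapped [md_trajectory()].
#' @export
unwrap_molecules <- function(traj) {
  if (is.null(traj$box)) stop("unwrap requires a periodic box", call. = FALSE)
  coords <- traj$coordinates
  T_ <- dim(coords)[1]
  split_idx <- split(seq_len(nrow(traj$particles)), traj$particles$residue_id)
  for (t in seq_len(T_)) {
    L <- traj$box[t, ]
    for (ix in split_idx) {
      ref <- coords[t, ix[1], ]
      for (a in 1:3) {
        d <- coords[t, ix, a] - ref[a]
        coords[t, ix, a] <- coords[t, ix, a] - round(d / L[a]) * L[a]
      }
    }
  }
  md_trajectory(coords, traj$particles, traj$frame_interval, traj$box)
}
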