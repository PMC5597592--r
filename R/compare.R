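# Ensemble and dynamics comparison statistics: projection densities and
# Boltzmann-inverted effective potentials, radial distribution functions,
# RMSD as a function of time lag with power-law fits, projection
# autocorrelation times, and eigenvalue-weighted speedup ratios.

#' Histogram density of PC projections
#'
#' Pools all copies and frames of one mode and histograms them with fixed-
#' width bins; the result is a probability density (unit integral).
#'
#' @param series a `projection_series` (or numeric vector of samples).
#' @param mode 1-based mode index (ignored when `series` is a vector).
#' @param bin_width bin width in Angstrom (default 0.1).
#' @return object of class `density_profile` with `bin_centers`, `density`,
#'   `bin_width`; `energy` stays `NULL` until [effective_potential()].
#' @export
projection_density <- function(series, mode = 1L, bin_width = 0.1) {
  x <- if (inherits(series, "projection_series")) as.vector(series$values[mode, , ]) else as.numeric(series)
  if (length(x) < 100) stop("need at least 100 samples for a density estimate", call. = FALSE)
  assert_finite(x, "projection samples")
  lo <- min(x); hi <- max(x)
  if (hi - lo < bin_width) {  # all samples (nearly) identical
    breaks <- c(lo - bin_width / 2, lo + bin_width / 2)
  } else {
    # bin edges aligned on multiples of bin_width so symmetric input gives a
    # symmetric histogram
    breaks <- seq(floor(lo / bin_width) * bin_width - bin_width / 2,
                  ceiling(hi / bin_width) * bin_width + bin_width / 2,
                  by = bin_width)
  }
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  structure(
    list(bin_centers = h$mids, density = h$density,
         bin_width = bin_width, n_samples = length(x),
         energy = NULL, temperature = NULL, energy_units = NULL),
    class = "density_profile"
  )
}

#' Effective (Boltzmann-inverted) potential from a probability density
#'
#' E(x) = -kB T log P(x).  Empty bins are masked (`NA`), never +/-Inf.
#'
#' @param density a `density_profile`.
#' @param temperature temperature in K.
#' @param units `"kBT"` (default; E = -log P, dimensionless) or `"kJ/mol"`.
#' @return the profile with `energy`, `temperature` and `energy_units`
#'   filled.
#' @export
effective_potential <- function(density, temperature = 300, units = c("kBT", "kJ/mol")) {
  units <- match.arg(units)
  if (temperature <= 0) stop("temperature must be positive", call. = FALSE)
  p <- density$density
  tot <- sum(p * density$bin_width)
  if (abs(tot - 1) > 1e-6) stop("density is not normalized to unit integral", call. = FALSE)
  e <- rep(NA_real_, length(p))
  pos <- p > 0
  e[pos] <- -log(p[pos])
  if (units == "kJ/mol") e <- e * .kB_kJmol * temperature
  density$energy <- e
  density$temperature <- temperature
  density$energy_units <- units
  density
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density_profile: %d bins of width %g A, %d samples%s\n",
              length(x$bin_centers), x$bin_width, x$n_samples %||% NA,
              if (!is.null(x$energy)) sprintf(", energy in %s at %g K", x$energy_units, x$temperature) else ""))
  invisible(x)
}

# per-copy conformations of an ensemble as a list of T x Np x 3 arrays
split_copies <- function(ensemble) {
  NL <- ensemble$n_copies
  T_ <- ensemble$n_frames
  lapply(seq_len(NL), function(c_) {
    ensemble$conformations[(c_ - 1L) * T_ + seq_len(T_), , , drop = FALSE]
  })
}

#' RMSD as a function of time lag
#'
#' For each lag tau, the RMSD between frames t and t + tau is averaged over
#' t within each molecule copy, then averaged over copies.  Each frame pair
#' is superposed before the RMSD by default, so rigid-body diffusion does not
#' contribute.
#'
#' @param aligned an `aligned_ensemble` (copies share the frame count), or a
#'   list of per-copy T x Np x 3 arrays.
#' @param lags integer vector of frame lags, all < T.
#' @param selection 1-based particle indices entering the RMSD (default all).
#' @param superpose pairwise-superpose each frame pair first (default TRUE).
#' @param t_stride subsample origins t by this stride to bound cost
#'   (default 1: every origin).
#' @return object of class `lag_curve` with `lags`, `rmsd`; `nrmsd`,
#'   `rmsd_eq` and the fit slots stay empty until [fit_nrmsd()].
#' @export
rmsd_lag <- function(aligned, lags, selection = NULL, superpose = TRUE, t_stride = 1L) {
  copies <- if (is.list(aligned) && !inherits(aligned, "molecule_ensemble")) aligned else split_copies(aligned)
  T_ <- dim(copies[[1]])[1]
  if (any(vapply(copies, function(x) dim(x)[1], integer(1)) != T_)) {
    stop("all copies must share the frame count", call. = FALSE)
  }
  lags <- as.integer(lags)
  if (any(lags >= T_)) stop(sprintf("lag %d >= frame count %d", max(lags), T_), call. = FALSE)
  if (any(lags < 1)) stop("lags must be >= 1", call. = FALSE)
  Np <- dim(copies[[1]])[2]
  selection <- selection %||% seq_len(Np)
  per_copy <- matrix(0, length(copies), length(lags))
  for (ci in seq_along(copies)) {
    conf <- copies[[ci]]
    for (li in seq_along(lags)) {
      tau <- lags[li]
      ts <- seq(1L, T_ - tau, by = t_stride)
      vals <- batch_pair_rmsd(conf[ts + tau, , , drop = FALSE],
                              conf[ts, , , drop = FALSE],
                              as.integer(selection), superpose)
      per_copy[ci, li] <- mean(vals)
    }
  }
  structure(
    list(lags = lags, rmsd = colMeans(per_copy), per_copy = per_copy,
         nrmsd = NULL, rmsd_eq = NULL, fit_c1 = NULL, fit_c2 = NULL),
    class = "lag_curve"
  )
}

#' Power-law fit of the normalized RMSD curve
#'
#' NRMSD(tau) = rmsd(tau) / rmsd_eq is fitted with c1 * tau^c2 by ordinary
#' least squares on log(nrmsd) vs log(tau), restricted to the quasi-linear
#' region NRMSD < 0.7.
#'
#' @param curve a `lag_curve`.
#' @param rmsd_eq equilibrium (plateau) RMSD in Angstrom.
#' @param nrmsd_max fit-region upper bound (default 0.7).
#' @return the curve with `nrmsd`, `rmsd_eq`, `fit_c1`, `fit_c2` filled.
#' @export
fit_nrmsd <- function(curve, rmsd_eq, nrmsd_max = 0.7) {
  stopifnot(rmsd_eq > 0)
  nrmsd <- curve$rmsd / rmsd_eq
  ok <- which(nrmsd > 0 & nrmsd < nrmsd_max & curve$lags > 0)
  if (length(ok) < 3) stop(sprintf("fit error: only %d points with NRMSD < %g", length(ok), nrmsd_max), call. = FALSE)
  fit <- stats::lm(log(nrmsd[ok]) ~ log(curve$lags[ok]))
  curve$nrmsd <- nrmsd
  curve$rmsd_eq <- rmsd_eq
  curve$fit_c1 <- exp(unname(stats::coef(fit)[1]))
  curve$fit_c2 <- unname(stats::coef(fit)[2])
  curve$fit_region <- ok
  curve
}

#' @export
print.lag_curve <- function(x, ...) {
  cat(sprintf("lag_curve: %d lags, rmsd %.3g..%.3g A%s\n", length(x$lags),
              min(x$rmsd), max(x$rmsd),
              if (!is.null(x$fit_c2)) sprintf("; fit c1 = %.4g, c2 = %.4g", x$fit_c1, x$fit_c2) else ""))
  invisible(x)
}

#' Autocorrelation of PC projections
#'
#' Mean-removed, variance-normalized autocovariance per molecule copy,
#' averaged over copies (per-copy normalization prevents high-variance copies
#' from dominating).  R(0) = 1 by construction.
#'
#' @param series a `projection_series`.
#' @param mode 1-based mode index.
#' @param lag_max maximum lag in frames (default min(T - 1, 10 * sqrt(T))).
#' @return object of class `autocorr_result` with `lags` (0..lag_max) and
#'   `R`; `tau_char` stays empty until [characteristic_time()].
#' @export
autocorrelation <- function(series, mode = 1L, lag_max = NULL) {
  vals <- series$values[mode, , , drop = FALSE]
  NL <- dim(vals)[2]; T_ <- dim(vals)[3]
  if (T_ < 10) stop("need at least 10 frames for autocorrelation", call. = FALSE)
  lag_max <- as.integer(lag_max %||% min(T_ - 1, ceiling(10 * sqrt(T_))))
  acc <- matrix(0, NL, lag_max + 1L)
  for (c_ in seq_len(NL)) {
    x <- vals[1, c_, ]
    if (stats::var(x) == 0) stop("undefined autocorrelation: zero-variance series", call. = FALSE)
    r <- as.vector(stats::acf(x, lag.max = lag_max, plot = FALSE,
                              demean = TRUE, type = "correlation")$acf)
    # acf() divides every lag's sum by T; rescale to the mean over the T - tau
    # valid origins so the time average matches the definition exactly
    acc[c_, ] <- r * T_ / (T_ - (0:lag_max))
  }
  structure(
    list(lags = 0:lag_max, R = colMeans(acc),
         frame_interval = series$frame_interval %||% 1,
         tau_char = NULL, crossing_method = NULL),
    class = "autocorr_result"
  )
}

#' Characteristic e^-2 decay time of an autocorrelation
#'
#' The lag at which R first falls to e^-2 of its starting value (taken as
#' 1.0), located by linear interpolation between the bracketing lags; when no
#' crossing occurs within the computed lags, the line through the last two
#' points is extrapolated.  A non-decaying R (extrapolation diverging) is
#' flagged unresolved (`tau_char = NA`) rather than silently numbered.
#'
#' @param ac an `autocorr_result`.
#' @return the result with `tau_char` (in the series' time units) and
#'   `crossing_method` (`"interpolated"` or `"extrapolated"`) filled.
#' @export
characteristic_time <- function(ac) {
  if (length(ac$lags) < 2) stop("need R on at least 2 lags", call. = FALSE)
  thr <- exp(-2)
  R <- ac$R
  lags <- ac$lags
  below <- which(R < thr)
  if (length(below) > 0) {
    j <- below[1]
    if (j == 1) {
      tau <- 0  # already below at lag 0: degenerate, but well-defined
    } else {
      # interpolate between (lags[j-1], R[j-1]) and (lags[j], R[j]);
      # the starting value is taken as 1.0 per convention, which only matters
      # when j - 1 == 1 (R[1] is 1 by construction anyway)
      r0 <- if (j - 1 == 1) 1.0 else R[j - 1]
      tau <- lags[j - 1] + (lags[j] - lags[j - 1]) * (r0 - thr) / (r0 - R[j])
    }
    method <- "interpolated"
  } else {
    n <- length(lags)
    slope <- (R[n] - R[n - 1]) / (lags[n] - lags[n - 1])
    if (slope >= 0) {
      ac$tau_char <- NA_real_
      ac$crossing_method <- "unresolved"
      warning("autocorrelation does not decay; characteristic time unresolved")
      return(ac)
    }
    tau <- lags[n] + (thr - R[n]) / slope
    method <- "extrapolated"
  }
  ac$tau_char <- tau * (ac$frame_interval %||% 1)
  ac$crossing_method <- method
  ac
}

#' @export
print.autocorr_result <- function(x, ...) {
  cat(sprintf("autocorr_result: %d lags%s\n", length(x$lags),
              if (!is.null(x$tau_char)) sprintf(", tau_char = %.4g (%s)", x$tau_char, x$crossing_method) else ""))
  invisible(x)
}

#' Eigenvalue-weighted geometric-mean speedup ratio
#'
#' R(i, j) = exp(sum_k w_k log(tau_k^i / tau_k^j)) with weights
#' w_k = E_k / sum(E_k): the geometric mean of per-mode characteristic-time
#' ratios, weighted by the covariance eigenvalues of the common basis.
#'
#' @param times_i,times_j per-mode characteristic times (equal length,
#'   positive; `NA` marks unresolved modes).
#' @param eigenvalues per-mode covariance eigenvalues E_k (same length).
#' @param unresolved `"strict"` (default: any `NA` tau is an error) or
#'   `"exclude"` (drop the mode with a warning and renormalize the weights).
#' @return object of class `speedup_report` with `ratio` (R_ij),
#'   `per_mode_ratios`, `weights`, `modes_used`.
#' @export
speedup_ratio <- function(times_i, times_j, eigenvalues,
                          unresolved = c("strict", "exclude")) {
  unresolved <- match.arg(unresolved)
  stopifnot(length(times_i) == length(times_j), length(eigenvalues) == length(times_i))
  bad <- is.na(times_i) | is.na(times_j)
  if (any(bad)) {
    if (unresolved == "strict") {
      stop(sprintf("unresolved characteristic time for mode(s) %s", paste(which(bad), collapse = ", ")), call. = FALSE)
    }
    warning(sprintf("excluding %d unresolved mode(s); weights renormalized", sum(bad)))
  }
  keep <- which(!bad)
  if (length(keep) == 0) stop("no resolved modes", call. = FALSE)
  if (any(times_i[keep] <= 0) || any(times_j[keep] <= 0)) {
    stop("characteristic times must be positive", call. = FALSE)
  }
  if (any(eigenvalues < 0)) stop("eigenvalue weights must be non-negative", call. = FALSE)
  w <- eigenvalues[keep] / sum(eigenvalues[keep])
  ratios <- times_i[keep] / times_j[keep]
  structure(
    list(ratio = exp(sum(w * log(ratios))),
         per_mode_ratios = ratios, weights = w, modes_used = keep),
    class = "speedup_report"
  )
}

#' @export
print.speedup_report <- function(x, ...) {
  cat(sprintf("speedup_report: R = %.4g over %d modes\n", x$ratio, length(x$modes_used)))
  invisible(x)
}

#' Radial distribution function
#'
#' Intermolecular mode: minimum-image pair distances between selections A and
#' B, histogram normalized by ideal-gas shell counts at the mean pair density
#' so g(r) -> 1 for homogeneous systems; requires a periodic box and
#' `r_max <= min(box)/2`.  Intramolecular mode: distances between A and B
#' particles of the same residue, normalized to a unit-integral probability
#' density over r.
#'
#' @param traj an [md_trajectory()].
#' @param selA,selB 1-based particle index vectors (disjoint or identical).
#' @param mode `"intermolecular"` or `"intramolecular"`.
#' @param bin_width bin width in Angstrom (default 0.2).
#' @param r_max histogram range in Angstrom.
#' @return object of class `rdf_result` with `bin_centers`, `g`, `mode`.
#' @export
radial_distribution <- function(traj, selA, selB,
                                mode = c("intermolecular", "intramolecular"),
                                bin_width = 0.2, r_max = 10) {
  mode <- match.arg(mode)
  coords <- traj$coordinates
  T_ <- dim(coords)[1]
  breaks <- seq(0, r_max, by = bin_width)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, breaks[length(breaks)] + bin_width)
  counts <- numeric(length(breaks) - 1L)
  if (mode == "intermolecular") {
    if (is.null(traj$box)) stop("intermolecular RDF requires a periodic box", call. = FALSE)
    if (any(r_max > apply(traj$box, 1, min) / 2)) {
      stop("r_max exceeds half the smallest box length", call. = FALSE)
    }
    same <- identical(sort(selA), sort(selB))
    n_pairs_per_frame <- 0
    for (t in seq_len(T_)) {
      L <- traj$box[t, ]
      A <- matrix(coords[t, selA, ], ncol = 3)
      B <- matrix(coords[t, selB, ], ncol = 3)
      V <- prod(L)
      rho_B <- (length(selB) - if (same) 1 else 0) / V
      for (i in seq_len(nrow(A))) {
        d <- sweep(B, 2, A[i, ])
        for (a in 1:3) d[, a] <- d[, a] - round(d[, a] / L[a]) * L[a]
        r <- sqrt(rowSums(d^2))
        if (same) r <- r[-i]
        r <- r[r < r_max]
        if (length(r) > 0) {
          counts <- counts + tabulate(findInterval(r, breaks, left.open = TRUE), nbins = length(counts))
        }
      }
      n_pairs_per_frame <- n_pairs_per_frame + nrow(A) * rho_B
    }
    mids <- breaks[-1] - bin_width / 2
    shell_vol <- 4 / 3 * pi * (breaks[-1]^3 - breaks[-length(breaks)]^3)
    # expected ideal-gas counts accumulated over frames and reference particles
    expected <- n_pairs_per_frame * shell_vol
    g <- ifelse(expected > 0, counts / expected, 0)
  } else {
    pt <- traj$particles
    if (is.null(pt)) stop("intramolecular RDF requires particle metadata", call. = FALSE)
    ridA <- pt$residue_id[selA]; ridB <- pt$residue_id[selB]
    all_r <- numeric(0)
    for (t in seq_len(T_)) {
      A <- matrix(coords[t, selA, ], ncol = 3)
      B <- matrix(coords[t, selB, ], ncol = 3)
      for (i in seq_along(selA)) {
        j <- which(ridB == ridA[i] & selB != selA[i])
        if (length(j) == 0) next
        d <- sweep(matrix(B[j, ], ncol = 3), 2, A[i, ])
        all_r <- c(all_r, sqrt(rowSums(d^2)))
      }
    }
    if (length(all_r) == 0) stop("empty selection: no same-molecule pairs", call. = FALSE)
    all_r <- all_r[all_r < r_max]
    counts <- tabulate(findInterval(all_r, breaks, left.open = TRUE), nbins = length(breaks) - 1L)
    mids <- breaks[-1] - bin_width / 2
    g <- counts / (sum(counts) * bin_width)  # unit-integral density over r
  }
  structure(
    list(bin_centers = breaks[-1] - bin_width / 2, g = g, mode = mode,
         bin_width = bin_width, r_max = r_max,
         pair_description = c(sprintf("%d A particles", length(selA)),
                              sprintf("%d B particles", length(selB)))),
    class = "rdf_result"
  )
}

#' @export
print.rdf_result <- function(x, ...) {
  cat(sprintf("rdf_result (%s): %d bins to %g A\n", x$mode, length(x$bin_centers), x$r_max))
  invisible(x)
}
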