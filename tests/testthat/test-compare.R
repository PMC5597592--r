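test_that("projection densities are normalized, aligned and symmetric", {
  d <- projection_density(rep(2.34, 500), bin_width = 0.1)
  expect_equal(sum(d$density * d$bin_width), 1, tolerance = 1e-9)
  expect_equal(length(which(d$density > 0)), 1L)
  expect_lt(abs(d$bin_centers[which.max(d$density)] - 2.34), 0.1)

  set.seed(4)
  x <- rnorm(5000)
  ds <- projection_density(c(x, -x), bin_width = 0.2)
  neg <- rev(ds$density[ds$bin_centers < 0])
  pos <- ds$density[ds$bin_centers > 0]
  nmin <- min(length(neg), length(pos))
  expect_equal(neg[1:nmin], pos[1:nmin], tolerance = 1e-12)
  expect_error(projection_density(rnorm(50)), "100 samples")
})

test_that("large-sample density approaches the bin-averaged Gaussian", {
  set.seed(1)
  x <- rnorm(1e5)
  # bin width 0.5 keeps per-bin counting noise (sigma ~ 0.003) safely inside
  # the 0.01 tolerance; comparison is against the exact bin-integrated pdf
  d <- projection_density(x, bin_width = 0.5)
  lo <- d$bin_centers - d$bin_width / 2
  hi <- d$bin_centers + d$bin_width / 2
  want <- (pnorm(hi) - pnorm(lo)) / d$bin_width
  expect_lt(max(abs(d$density - want)), 0.01)
})

test_that("effective potentials are Boltzmann inversions", {
  u <- projection_density(runif(10000, -1, 1), bin_width = 0.25)
  eu <- effective_potential(u, temperature = 300)
  inner <- abs(eu$bin_centers) < 0.7   # ignore edge bins
  expect_lt(diff(range(eu$energy[inner])), 0.2)

  # bins with density ratio e : 1 differ by exactly 1 kBT
  prof <- structure(list(bin_centers = c(0.5, 1.5), bin_width = 1,
                         density = c(exp(1), 1) / (exp(1) + 1)),
                    class = "density_profile")
  ep <- effective_potential(prof, 300)
  expect_equal(ep$energy[2] - ep$energy[1], 1, tolerance = 1e-12)
  epk <- effective_potential(prof, 300, units = "kJ/mol")
  expect_equal(epk$energy[2] - epk$energy[1], 0.008314462618 * 300, tolerance = 1e-9)
  expect_error(effective_potential(prof, -5), "positive")

  # Gaussian density: quadratic potential with curvature kBT / sigma^2
  set.seed(9)
  g <- projection_density(rnorm(2e5, sd = 2), bin_width = 0.2)
  eg <- effective_potential(g, 300)
  sel <- abs(eg$bin_centers) < 3 & !is.na(eg$energy)
  fit <- lm(eg$energy[sel] ~ poly(eg$bin_centers[sel], 2, raw = TRUE))
  curv <- 2 * coef(fit)[3]
  expect_equal(unname(curv), 1 / 4, tolerance = 0.02)  # relative, 2%
  # masked bins are NA, never infinite
  expect_false(any(is.infinite(eg$energy), na.rm = TRUE))
})

test_that("rmsd_lag averages frame-pair rmsd over origins and copies", {
  base <- asymmetric_structure(5)
  frozen <- molecule_ensemble(array(rep(base, each = 8), dim = c(8, 5, 3)))
  lc <- rmsd_lag(frozen, lags = c(1, 3))
  expect_equal(lc$rmsd, c(0, 0), tolerance = 1e-10)
  expect_error(rmsd_lag(frozen, lags = 8), "lag")

  # hand evaluation: single copy, T = 3, 2 particles, tau = 1, no fitting
  conf <- array(0, dim = c(3, 2, 3))
  conf[1, , ] <- rbind(c(0, 0, 0), c(1, 0, 0))
  conf[2, , ] <- rbind(c(0, 1, 0), c(1, 0, 0))
  conf[3, , ] <- rbind(c(0, 1, 0), c(1, 2, 0))
  # pair (1,2): sqrt((1 + 0)/2); pair (2,3): sqrt((0 + 4)/2)
  hand <- mean(c(sqrt(0.5), sqrt(2)))
  lc2 <- rmsd_lag(list(conf), lags = 1, superpose = FALSE)
  expect_equal(lc2$rmsd, hand, tolerance = 1e-12)

  # i.i.d. isotropic frames, superposition off: flat curve at sigma * sqrt(6)
  # (12 particles keep the sqrt-of-chi-square Jensen bias ~ 1/(12 Np) << 2%)
  set.seed(31)
  sigma <- 0.7
  iid <- molecule_ensemble(array(rnorm(1e4 * 12 * 3, sd = sigma), dim = c(1e4, 12, 3)))
  lci <- rmsd_lag(iid, lags = c(1, 10, 100), superpose = FALSE)
  expect_equal(lci$rmsd, rep(sigma * sqrt(6), 3), tolerance = 0.02 * sigma * sqrt(6))
})

test_that("nrmsd power-law fits respect the fit region", {
  lags <- 1:20
  curve <- structure(list(lags = lags, rmsd = 0.5 * lags^0.2), class = "lag_curve")
  fit <- fit_nrmsd(curve, rmsd_eq = 1)
  expect_equal(fit$fit_c2, 0.2, tolerance = 1e-6)
  expect_equal(fit$fit_c1, 0.5, tolerance = 1e-6)

  const <- structure(list(lags = lags, rmsd = rep(0.5, 20)), class = "lag_curve")
  expect_equal(fit_nrmsd(const, 1)$fit_c2, 0, tolerance = 1e-9)

  # appending points above the 0.7 cutoff leaves the fit unchanged
  more <- structure(list(lags = c(lags, 100, 200), rmsd = c(0.5 * lags^0.2, 0.9, 0.95)),
                    class = "lag_curve")
  fit2 <- fit_nrmsd(more, 1)
  expect_equal(fit2$fit_c2, fit$fit_c2, tolerance = 1e-12)
  expect_equal(fit2$fit_c1, fit$fit_c1, tolerance = 1e-12)
  few <- structure(list(lags = 1:2, rmsd = c(0.3, 0.4)), class = "lag_curve")
  expect_error(fit_nrmsd(few, 1), "fit error")
})

test_that("autocorrelation normalizes per copy with R(0) = 1", {
  alt <- projection_series(array(rep(c(1, -1), 50), dim = c(1, 1, 100)))
  ac <- autocorrelation(alt, lag_max = 4)
  expect_equal(ac$R[1], 1)
  expect_equal(ac$R[2], -1, tolerance = 1e-12)   # lag 1

  set.seed(13)
  any_series <- projection_series(array(rnorm(2 * 500), dim = c(1, 2, 500)))
  expect_equal(autocorrelation(any_series)$R[1], 1)
  flat <- projection_series(array(1, dim = c(1, 1, 50)))
  expect_error(autocorrelation(flat), "zero-variance")

  # OU series: R within 0.02 of exp(-tau/20) out to lag 60; copy-averaged
  # over 8 copies so ACF noise (~sqrt(2 tau / T) per copy) sits well inside
  spec <- synthetic_spec(planted_eigenvalues = 1, tau_ou = 20,
                         noise_floor = 0, n_copies = 8L, n_frames = 1e5L,
                         seed = 99L, base = make_pseudo_lipid())
  vals <- array(0, dim = c(1, 8, 1e5))
  for (c_ in 1:8) vals[, c_, ] <- sample_ou_modes(spec, c_)
  ac2 <- autocorrelation(projection_series(vals), lag_max = 60)
  expect_lt(max(abs(ac2$R - exp(-(0:60) / 20))), 0.02)
})

test_that("characteristic times interpolate or extrapolate the e^-2 crossing", {
  lags <- 0:100
  ac <- structure(list(lags = lags, R = exp(-lags / 5), frame_interval = 1),
                  class = "autocorr_result")
  ct <- characteristic_time(ac)
  expect_equal(ct$tau_char, 10, tolerance = 0.01)
  expect_equal(ct$crossing_method, "interpolated")

  # only lags 0 and 4 known: line through (0,1),(4,0.5) hits e^-2 at 6.917
  two <- structure(list(lags = c(0, 4), R = c(1, 0.5), frame_interval = 1),
                   class = "autocorr_result")
  ct2 <- characteristic_time(two)
  expect_equal(ct2$tau_char, 4 * (1 - exp(-2)) / 0.5, tolerance = 1e-9)
  expect_equal(ct2$crossing_method, "extrapolated")

  ones <- structure(list(lags = 0:10, R = rep(1, 11), frame_interval = 1),
                    class = "autocorr_result")
  expect_warning(ct3 <- characteristic_time(ones), "unresolved")
  expect_true(is.na(ct3$tau_char))
})

test_that("speedup ratios are eigenvalue-weighted geometric means", {
  r <- speedup_ratio(c(10, 50, 5), c(2, 10, 1), eigenvalues = c(3, 2, 1))
  expect_equal(r$ratio, 5, tolerance = 1e-12)
  expect_equal(speedup_ratio(7, 2, 1)$ratio, 3.5)
  r2 <- speedup_ratio(c(2, 8), c(1, 1), eigenvalues = c(3, 1))
  expect_equal(r2$ratio, exp(0.75 * log(2) + 0.25 * log(8)), tolerance = 1e-12)
  expect_equal(r2$ratio, 2.8284, tolerance = 1e-4)
  # antisymmetry
  fwd <- speedup_ratio(c(3, 9), c(2, 1), c(5, 1))$ratio
  bwd <- speedup_ratio(c(2, 1), c(3, 9), c(5, 1))$ratio
  expect_equal(fwd * bwd, 1, tolerance = 1e-12)
  expect_equal(sum(r2$weights), 1, tolerance = 1e-12)

  expect_error(speedup_ratio(c(1, NA), c(1, 1), c(1, 1)), "unresolved")
  expect_warning(r3 <- speedup_ratio(c(4, NA), c(1, 1), c(1, 1), unresolved = "exclude"),
                 "renormalized")
  expect_equal(r3$ratio, 4)
})

test_that("radial distributions place mass where the geometry says", {
  # fixed intramolecular pair at 7.0 A: single delta bin
  pt <- particle_table(c("C1", "C2"), rep("X", 2), c(1L, 1L))
  coords <- array(0, dim = c(1, 2, 3))
  coords[1, 2, ] <- c(7, 0, 0)
  tr <- md_trajectory(coords, pt)
  r <- radial_distribution(tr, 1, 2, mode = "intramolecular", bin_width = 0.2, r_max = 10)
  expect_equal(sum(r$g * r$bin_width), 1, tolerance = 1e-12)
  expect_equal(r$bin_centers[which(r$g > 0)], 6.9)  # bin (6.8, 7.0]
  # nothing below the minimum pair distance
  expect_true(all(r$g[r$bin_centers < 6.8] == 0))

  # intermolecular requires a box and a sane r_max
  pt2 <- particle_table(paste0("C", 1:4), rep("X", 4), 1:4)
  co2 <- array(runif(4 * 3, 0, 20), dim = c(1, 4, 3))
  tr2 <- md_trajectory(co2, pt2, box = c(20, 20, 20))
  expect_error(radial_distribution(tr2, 1:2, 3:4, mode = "intermolecular", r_max = 15),
               "half the smallest box")
  expect_error(radial_distribution(md_trajectory(co2, pt2), 1:2, 3:4,
                                   mode = "intermolecular"), "box")
})
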