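test_that("mapping schemes validate and normalize rows", {
  expect_error(mapping_scheme(matrix(c(1, 0, 0, 0), 2, 2) * c(1, 0)), "no atoms")
  expect_error(mapping_scheme(matrix(-1, 1, 2)), "non-negative")
  expect_error(mapping_scheme(diag(3)[, 1:2]), "more beads")
  sch <- suppressWarnings(mapping_scheme(matrix(c(2, 2, 0, 0, 1, 3), 2, 3, byrow = TRUE)))
  expect_equal(rowSums(sch$weights), c(1, 1), tolerance = 1e-15)
})

test_that("uniform mappings follow the block + remainder rule", {
  expect_equal(uniform_mapping(18, 1)$weights, diag(18), ignore_attr = TRUE)
  u6 <- uniform_mapping(18, 6)
  expect_equal(dim(u6$weights), c(3L, 18L))
  expect_true(all(u6$weights[2, 7:12] == 1 / 6))
  u4 <- uniform_mapping(10, 4)
  expect_equal(dim(u4$weights), c(2L, 10L))       # 4 + 6: last bead absorbs
  expect_true(all(u4$weights[2, 5:10] == 1 / 6))
  expect_error(uniform_mapping(10, 0), ">= 1")
  expect_error(uniform_mapping(4, 5), "exceed")
})

test_that("map_coordinates averages atoms into beads linearly", {
  idn <- mapping_scheme(diag(4))
  co <- asymmetric_structure(4)
  expect_equal(map_coordinates(co, idn), co, ignore_attr = TRUE)

  two <- mapping_scheme(matrix(c(1, 1), 1, 2) / 2)
  expect_equal(unname(map_coordinates(rbind(c(0, 0, 0), c(2, 0, 0)), two)[1, ]),
               c(1, 0, 0))
  w <- mapping_scheme(matrix(c(1 / 3, 2 / 3), 1, 2))
  expect_equal(unname(map_coordinates(rbind(c(0, 0, 0), c(3, 0, 0)), w)[1, ]),
               c(2, 0, 0))
  # frame-wise application over an array
  arr <- array(rnorm(5 * 4 * 3), dim = c(5, 4, 3))
  got <- map_coordinates(arr, uniform_mapping(4, 2))
  for (t in 1:5) {
    expect_equal(got[t, , ], unname(map_coordinates(arr[t, , ], uniform_mapping(4, 2))),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(map_coordinates(co, two), "shape")
})

test_that("map_vector mirrors the coordinate mapping on displacements", {
  sch <- uniform_mapping(4, 2)
  d <- c(1, -2, 3)
  e <- rep(d, 4)                       # every atom displaces identically
  expect_equal(map_vector(e, sch), rep(d, 2))
  anti <- c(d, -d, 0, 0, 0, 0, 0, 0)   # intra-bead antisymmetric
  expect_equal(map_vector(anti, sch), rep(0, 6))
  expect_equal(map_vector(e, mapping_scheme(diag(4))), e)
  expect_error(map_vector(e[1:9], sch), "shape")
  # consistency: mapping a conformation difference = difference of mappings
  a <- asymmetric_structure(4, seed = 1); b <- asymmetric_structure(4, seed = 2)
  expect_equal(map_vector(flatten_coords(a) - flatten_coords(b), sch),
               flatten_coords(map_coordinates(a, sch)) - flatten_coords(map_coordinates(b, sch)),
               tolerance = 1e-12)
})

test_that("conservation ratio matches its defining formula", {
  idn <- mapping_scheme(diag(3))
  set.seed(2)
  e <- rnorm(9)
  expect_equal(conservation_ratio(e, idn), 1, tolerance = 1e-12)

  two <- mapping_scheme(matrix(c(1, 1), 1, 2) / 2)
  d <- c(0.3, -1, 2)
  expect_equal(conservation_ratio(c(d, -d), two), 0, tolerance = 1e-12)
  # one 2-atom bead, displacement (1,0,0) on the first atom only:
  # alpha = 0.5 / sqrt(0.5) = 0.70710678 (term-by-term oracle)
  e2 <- c(1, 0, 0, 0, 0, 0)
  expect_equal(oracle_conservation(e2, two$weights), 0.70710678, tolerance = 1e-8)
  expect_equal(conservation_ratio(e2, two), 0.70710678, tolerance = 1e-8)
  expect_error(conservation_ratio(rep(0, 6), two), "zero vector")

  # random cross-check against the independent oracle
  set.seed(33)
  for (i in 1:20) {
    sch <- uniform_mapping(sample(4:9, 1), sample(2:3, 1))
    e <- rnorm(3 * ncol(sch$weights))
    expect_equal(conservation_ratio(e, sch), oracle_conservation(e, sch$weights),
                 tolerance = 1e-10)
  }
})

test_that("alpha bounds and kernel characterization hold", {
  set.seed(91)
  # alpha in [0, 1] over many random (vector, scheme) pairs
  for (i in 1:200) {
    n <- sample(4:12, 1)
    sch <- uniform_mapping(n, sample(2:4, 1))
    a <- conservation_ratio(rnorm(3 * n), sch)
    expect_gte(a, 0); expect_lte(a, 1)
  }
  # alpha = 1 for vectors constant within every bead
  sch <- uniform_mapping(9, 3)
  for (i in 1:100) {
    per_bead <- matrix(rnorm(9), 3, 3)
    e <- flatten_coords(per_bead[rep(1:3, each = 3), ])
    expect_equal(conservation_ratio(e, sch), 1, tolerance = 1e-10)
  }
  # alpha = 0 exactly on kernel vectors, and only there
  kb <- mapping_kernel_basis(sch)
  for (j in seq_len(ncol(kb))) {
    expect_true(in_kernel(kb[, j], sch))
    expect_lt(conservation_ratio(kb[, j], sch), 1e-9)
  }
  for (i in 1:50) {
    e <- rnorm(27)
    expect_equal(in_kernel(e, sch), conservation_ratio(e, sch) < 1e-10)
  }
})

test_that("in_kernel agrees with a QR null-space oracle", {
  sch <- uniform_mapping(8, 2)
  Wk <- kronecker(sch$weights, diag(3))
  nullb <- oracle_null_space(Wk)
  expect_equal(ncol(nullb), 3 * 8 - 3 * 4)
  for (j in seq_len(ncol(nullb))) expect_true(in_kernel(nullb[, j], sch))
  expect_false(in_kernel(rep(c(1, 0, 0), 8), sch))  # uniform translation maps through
})

test_that("map_covariance is the two-route consistency bridge", {
  sch <- uniform_mapping(6, 2)
  idn <- mapping_scheme(diag(6))
  set.seed(14)
  ens <- random_ensemble(50, 6, seed = 14)
  cv <- compute_covariance(ens)
  expect_equal(map_covariance(cv$covariance, idn), cv$covariance,
               tolerance = 1e-12, ignore_attr = TRUE)

  mapped <- ens
  mapped$conformations <- map_coordinates(ens$conformations, sch)
  cv_cg <- compute_covariance(mapped)
  expect_equal(map_covariance(cv$covariance, sch), cv_cg$covariance,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_lte(qr(map_covariance(cv$covariance, sch))$rank,
             min(qr(cv$covariance)$rank, 3 * 3 * 2))
  asym <- cv$covariance; asym[1, 2] <- asym[1, 2] + 1
  expect_error(map_covariance(asym, sch), "symmetric")
})

test_that("uniform-ladder information loss is monotone", {
  # an 18-particle chain ensemble with smooth planted modes
  base <- make_pseudo_lipid(n_head = 2, n_tail = 8, tails = 2)
  expect_equal(nrow(base$coordinates), 18L)
  sys <- generate_system(synthetic_spec(
    base = base, seed = 5, n_copies = 4L, n_frames = 1000L))
  ens <- extract_molecule_ensemble(sys$trajectory, "PLIP", heavy_only = FALSE)
  model <- pca_model(build_reference(ens))
  mean_alpha <- vapply(c(2, 6, 18), function(r) {
    mean(conservation_profile(model, uniform_mapping(18, r), modes = 5)$alpha)
  }, numeric(1))
  expect_true(all(diff(mean_alpha) <= 1e-10))
})
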