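test_that("compute_covariance matches a naive double-loop oracle", {
  base <- asymmetric_structure(4)
  conf <- array(rep(base, each = 6), dim = c(6, 4, 3))
  cv <- compute_covariance(molecule_ensemble(conf))
  expect_equal(max(abs(cv$covariance)), 0)
  expect_equal(cv$mean_structure, base, ignore_attr = TRUE)

  one <- array(0, dim = c(2, 1, 3))
  one[1, 1, 1] <- -1; one[2, 1, 1] <- 1
  cv1 <- compute_covariance(molecule_ensemble(one))
  expect_equal(cv1$covariance, diag(c(1, 0, 0)), ignore_attr = TRUE)

  ens <- random_ensemble(50, 4, seed = 77)
  cv2 <- compute_covariance(ens)
  X <- t(apply(ens$conformations, 1, function(m) as.vector(t(m))))
  expect_equal(cv2$covariance, oracle_covariance(X), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(compute_covariance(molecule_ensemble(ens$conformations[1, , , drop = FALSE])),
               "insufficient")
})

test_that("eigendecompose orders, clamps, signs and validates", {
  m <- eigendecompose(diag(c(4, 1, 0)), matrix(0, 1, 3))
  expect_equal(m$eigenvalues, c(4, 1, 0))
  expect_equal(abs(m$eigenvectors), diag(3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(apply(m$eigenvectors, 2, max) > 0))  # sign convention

  set.seed(6)
  A <- crossprod(matrix(rnorm(36), 6, 6))
  model <- eigendecompose(A, matrix(0, 2, 3))
  expect_equal(crossprod(model$eigenvectors), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  want <- oracle_eigen_sym(A)
  expect_equal(model$eigenvalues, want$values, tolerance = 1e-8)
  for (k in 1:6) {
    expect_equal(abs(sum(model$eigenvectors[, k] * want$vectors[, k])), 1,
                 tolerance = 1e-8)
  }
  expect_equal(sum(model$eigenvalues), sum(diag(A)), tolerance = 1e-8)

  expect_error(eigendecompose(matrix(c(1, 2, 0, 1), 2, 2), NULL), "symmetric")
  expect_error(eigendecompose(diag(c(1, -0.5, 0)), matrix(0, 1, 3)), "negative")
})

test_that("normalized eigenvalues and cumulative variance behave", {
  m <- eigendecompose(diag(c(8, 4, 0, 0, 0, 0)), matrix(0, 2, 3))
  m$eigenvalues <- c(8, 4); m$eigenvectors <- m$eigenvectors[, 1:2]
  m$particle_count <- 4L
  expect_equal(normalized_eigenvalues(m), c(2, 1))
  expect_equal(normalized_eigenvalues(m), c(2, 1))  # idempotent metadata

  m2 <- eigendecompose(diag(c(5, 3, 2)), matrix(0, 1, 3))
  expect_equal(cumulative_variance(m2), c(0.5, 0.8, 1.0))
  m3 <- eigendecompose(diag(c(7, 0, 0)), matrix(0, 1, 3))
  expect_equal(cumulative_variance(m3), c(1, 1, 1))
  # planted spectrum + noise floor: smallest k reaching 90% by direct cumsum
  lam <- sort(c(9, 4, 2, 1, 0.5, rep(0.05, 10)), decreasing = TRUE)
  m4 <- list(eigenvalues = lam)
  class(m4) <- "pca_model"
  got_k <- which(cumulative_variance(m4) >= 0.9)[1]
  expect_equal(got_k, which(cumsum(lam) / sum(lam) >= 0.9)[1])
  m5 <- m4; m5$eigenvalues <- rep(0, 3)
  expect_error(cumulative_variance(m5), "all-zero")
})

test_that("projections recover amplitudes and eigenvalue variances", {
  sys <- quick_system(seed = 17, n_copies = 2L, n_frames = 300L)
  al <- build_reference(extract_molecule_ensemble(sys$trajectory, "PLIP", heavy_only = FALSE))
  model <- pca_model(al)

  mean_ens <- molecule_ensemble(array(model$mean_structure, dim = c(1, 11, 3)))
  p0 <- project(mean_ens, model, modes = 5)
  expect_lt(max(abs(p0$values)), 1e-10)

  shifted <- model$mean_structure + 2.5 * matrix(model$eigenvectors[, 3], ncol = 3, byrow = TRUE)
  p1 <- project(molecule_ensemble(array(shifted, dim = c(1, 11, 3))), model, modes = 5)
  expect_equal(as.vector(p1$values), c(0, 0, 2.5, 0, 0), tolerance = 1e-8)

  # population variance of the generating ensemble's projections = eigenvalue
  pr <- project(al, model, modes = 6)
  K <- al$n_copies * al$n_frames
  for (k in 1:6) {
    x <- as.vector(pr$values[k, , ])
    expect_equal(mean((x - mean(x))^2), model$eigenvalues[k], tolerance = 1e-10)
  }
  # across-mode sample correlations vanish within 3/sqrt(K)
  for (k in 2:4) {
    expect_lt(abs(cor(as.vector(pr$values[1, , ]), as.vector(pr$values[k, , ]))),
              3 / sqrt(K))
  }
  expect_error(project(random_ensemble(5, 4), model), "shape")
})

test_that("trace equals total positional variance after alignment", {
  sys <- quick_system(seed = 23, n_copies = 2L, n_frames = 200L)
  al <- build_reference(extract_molecule_ensemble(sys$trajectory, "PLIP", heavy_only = FALSE))
  model <- pca_model(al)
  X <- t(apply(al$conformations, 1, function(m) as.vector(t(m))))
  total_var <- sum(apply(X, 2, function(col) mean((col - mean(col))^2)))
  expect_equal(sum(model$eigenvalues), total_var, tolerance = 1e-8 * total_var)
})

test_that("covariance PCC follows the flattened Pearson formula", {
  set.seed(3)
  A <- crossprod(matrix(rnorm(36), 6, 6))
  B <- crossprod(matrix(rnorm(36), 6, 6))
  expect_equal(covariance_pcc(A, A), 1.0)
  expect_equal(covariance_pcc(A, -A), -1.0)
  want <- sum((A - mean(A)) * (B - mean(B))) /
    sqrt(sum((A - mean(A))^2) * sum((B - mean(B))^2))
  expect_equal(covariance_pcc(A, B), want, tolerance = 1e-12)
  expect_equal(covariance_pcc(A, B), covariance_pcc(B, A))
  expect_equal(covariance_pcc(A, 2.5 * A + 3), 1.0, tolerance = 1e-12)
  expect_error(covariance_pcc(A, B[1:3, 1:3]), "shape")
  expect_error(covariance_pcc(matrix(1, 2, 2), A[1:2, 1:2]), "zero-variance")
})

test_that("dot-product matrices expose basis overlap structure", {
  set.seed(12)
  E <- qr.Q(qr(matrix(rnorm(144), 12, 12)))
  expect_equal(dot_product_matrix(E, E, 4), diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  perm <- E[, c(2, 1, 4, 3)]
  D <- dot_product_matrix(E[, 1:4], perm, 4)
  expect_equal(unname(D), diag(4)[c(2, 1, 4, 3), ], tolerance = 1e-10)
  expect_true(all(D >= 0 & D <= 1))
  # mapped AA basis against PCA of the mapped trajectory: leading diagonal
  # dominates, and entries match elementwise recomputation
  sch <- uniform_mapping(6, 2)
  ens <- random_ensemble(400, 6, seed = 40)
  aa <- pca_model(ens)
  mapped <- ens
  mapped$conformations <- map_coordinates(ens$conformations, sch)
  cg <- pca_model(mapped)
  D2 <- dot_product_matrix(aa, cg, 3, mapping = sch)
  Ei <- apply(aa$eigenvectors[, 1:3], 2, map_vector, scheme = sch)
  Ei <- sweep(Ei, 2, sqrt(colSums(Ei^2)), `/`)
  for (a in 1:3) for (b in 1:3) {
    expect_equal(D2[a, b], abs(sum(Ei[, a] * cg$eigenvectors[, b])), tolerance = 1e-10)
  }
  # mapped bases need not stay orthogonal; only bounds are asserted
  expect_true(all(D2 >= 0 & D2 <= 1))
  expect_error(dot_product_matrix(aa, cg, 3), "shape")
})

test_that("joint PCA pools equally sized ensembles only", {
  e1 <- random_ensemble(30, 4, seed = 1)
  e2 <- random_ensemble(30, 4, seed = 2)
  jm <- joint_pca(list(e1, e2))
  conf <- array(0, dim = c(60, 4, 3))
  conf[1:30, , ] <- e1$conformations
  conf[31:60, , ] <- e2$conformations
  both <- molecule_ensemble(conf)
  # pooled covariance equals covariance of the concatenated ensemble
  direct <- pca_model(both)
  expect_equal(jm$eigenvalues, direct$eigenvalues, tolerance = 1e-10)
  expect_error(joint_pca(list(e1, random_ensemble(20, 4))), "equal conformation")
})
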