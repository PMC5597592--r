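# Independent oracles used to derive frozen expected values.  These stay
# deliberately naive and share no code path with the package internals.

# covariance by explicit double loop over elements (divisor K)
oracle_covariance <- function(X) {
  K <- nrow(X); D <- ncol(X)
  mu <- colMeans(X)
  C <- matrix(0, D, D)
  for (a in seq_len(D)) {
    for (b in seq_len(D)) {
      s <- 0
      for (k in seq_len(K)) s <- s + (X[k, a] - mu[a]) * (X[k, b] - mu[b])
      C[a, b] <- s / K
    }
  }
  C
}

# symmetric eigensolver by classical Jacobi rotations (independent of LAPACK)
oracle_eigen_sym <- function(A, tol = 1e-12, max_sweeps = 100) {
  n <- nrow(A)
  V <- diag(n)
  for (sweep in seq_len(max_sweeps)) {
    off <- 0
    for (p in seq_len(n - 1)) for (q in seq(p + 1, n)) off <- off + A[p, q]^2
    if (sqrt(2 * off) < tol * max(1, sqrt(sum(diag(A)^2)))) break
    for (p in seq_len(n - 1)) {
      for (q in seq(p + 1, n)) {
        if (abs(A[p, q]) < 1e-300) next
        theta <- (A[q, q] - A[p, p]) / (2 * A[p, q])
        t_ <- sign(theta) / (abs(theta) + sqrt(theta^2 + 1))
        if (theta == 0) t_ <- 1
        c_ <- 1 / sqrt(t_^2 + 1); s_ <- t_ * c_
        J <- diag(n); J[p, p] <- c_; J[q, q] <- c_; J[p, q] <- s_; J[q, p] <- -s_
        A <- t(J) %*% A %*% J
        V <- V %*% J
      }
    }
  }
  ord <- order(diag(A), decreasing = TRUE)
  list(values = diag(A)[ord], vectors = V[, ord, drop = FALSE])
}

# Horn's quaternion absolute-orientation method (independent of Kabsch/SVD);
# returns the transformed mobile and the rmsd over the selection
oracle_quaternion_superpose <- function(mobile, reference, selection = seq_len(nrow(mobile))) {
  P <- mobile[selection, , drop = FALSE]
  Q <- reference[selection, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  S <- t(Pc) %*% Qc
  N <- matrix(0, 4, 4)
  N[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  N[1, 2] <- N[2, 1] <- S[2, 3] - S[3, 2]
  N[1, 3] <- N[3, 1] <- S[3, 1] - S[1, 3]
  N[1, 4] <- N[4, 1] <- S[1, 2] - S[2, 1]
  N[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  N[2, 3] <- N[3, 2] <- S[1, 2] + S[2, 1]
  N[2, 4] <- N[4, 2] <- S[3, 1] + S[1, 3]
  N[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  N[3, 4] <- N[4, 3] <- S[2, 3] + S[3, 2]
  N[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  eg <- oracle_eigen_sym(N)
  q <- eg$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  moved <- sweep(sweep(mobile, 2, cp) %*% t(R), 2, cq, `+`)
  d <- moved[selection, , drop = FALSE] - Q
  list(coordinates = moved, rmsd = sqrt(mean(rowSums(d^2))))
}

# minimal rmsd over in-plane rotations + optimal translation, by grid search
# (valid oracle for planar point sets: the optimal rotation is about z)
oracle_grid_superpose_rmsd <- function(mobile, reference, step = 1e-4) {
  cp <- colMeans(mobile); cq <- colMeans(reference)
  Pc <- sweep(mobile, 2, cp); Qc <- sweep(reference, 2, cq)
  best <- Inf
  for (th in seq(0, 2 * pi, by = step)) {
    R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
    d <- Pc %*% R - Qc
    best <- min(best, sqrt(mean(rowSums(d^2))))
  }
  best
}

# null-space basis from the QR decomposition of t(A) (independent of SVD)
oracle_null_space <- function(A) {
  qrA <- qr(t(A))
  r <- qrA$rank
  Qfull <- qr.Q(qrA, complete = TRUE)
  Qfull[, seq(r + 1, nrow(t(A))), drop = FALSE]
}

# direct term-by-term evaluation of the conservation ratio
oracle_conservation <- function(e_aa, W) {
  m <- nrow(W); n <- ncol(W)
  E <- matrix(e_aa, ncol = 3, byrow = TRUE)  # n x 3 per-atom displacements
  num <- 0
  for (i in seq_len(m)) {
    bead <- c(0, 0, 0)
    for (j in seq_len(n)) bead <- bead + W[i, j] * E[j, ]
    num <- num + sum(bead^2)
  }
  den <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) den <- den + W[i, j] * sum(E[j, ]^2)
  sqrt(num / m) / sqrt(den / m)
}
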