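# Symmetric banded matrix utilities (the pbtrf/pbtrs analogue used for the
# Lucas-Kanade Hessian). Storage is LAPACK-style lower band: a (kd+1) x m
# matrix `ab` with ab[1+i, j] = A[j+i, j] for 0 <= i <= kd.

band_from_dense <- function(A, kd) {
  m <- nrow(A)
  ab <- matrix(0, kd + 1, m)
  for (i in 0:kd) {
    j <- seq_len(m - i)
    ab[i + 1, j] <- A[cbind(j + i, j)]
  }
  ab
}

band_to_dense <- function(ab) {
  kd <- nrow(ab) - 1L
  m <- ncol(ab)
  A <- matrix(0, m, m)
  for (i in 0:kd) {
    j <- seq_len(m - i)
    A[cbind(j + i, j)] <- ab[i + 1, j]
    A[cbind(j, j + i)] <- ab[i + 1, j]
  }
  A
}

# Banded Cholesky factorization A = L L' for symmetric positive-definite A
# in lower band storage; returns L in the same storage. O(m * kd^2).
# Fails with an error if a non-positive pivot is met.
band_chol <- function(ab) {
  kd <- nrow(ab) - 1L
  m <- ncol(ab)
  L <- ab
  for (j in seq_len(m)) {
    v <- L[1, j]
    if (!is.finite(v) || v <= 0) {
      stop(sprintf("banded Cholesky failed: non-positive pivot at column %d", j))
    }
    L[1, j] <- sqrt(v)
    if (j < m) {
      q <- min(kd, m - j)
      if (q >= 1) {
        L[2:(q + 1), j] <- L[2:(q + 1), j] / L[1, j]
        for (i in seq_len(q)) {
          # update column j+i, rows j+i .. j+q
          L[1:(q - i + 1), j + i] <- L[1:(q - i + 1), j + i] -
            L[i + 1, j] * L[(i + 1):(q + 1), j]
        }
      }
    }
  }
  L
}

# Solve L L' x = b given the banded factor L.
band_chol_solve <- function(L, b) {
  kd <- nrow(L) - 1L
  m <- ncol(L)
  y <- as.numeric(b)
  for (j in seq_len(m)) {          # forward solve L y = b
    y[j] <- y[j] / L[1, j]
    q <- min(kd, m - j)
    if (q >= 1) {
      y[(j + 1):(j + q)] <- y[(j + 1):(j + q)] - y[j] * L[2:(q + 1), j]
    }
  }
  for (j in rev(seq_len(m))) {     # back solve L' x = y
    q <- min(kd, m - j)
    if (q >= 1) {
      y[j] <- y[j] - sum(L[2:(q + 1), j] * y[(j + 1):(j + q)])
    }
    y[j] <- y[j] / L[1, j]
  }
  y
}

# Forward solve only: L w = b (used for the trust-region Newton update,
# where ||w||^2 = s' (B + lambda I)^{-1} s with s the step).
band_forward_solve <- function(L, b) {
  kd <- nrow(L) - 1L
  m <- ncol(L)
  y <- as.numeric(b)
  for (j in seq_len(m)) {
    y[j] <- y[j] / L[1, j]
    q <- min(kd, m - j)
    if (q >= 1) {
      y[(j + 1):(j + q)] <- y[(j + 1):(j + q)] - y[j] * L[2:(q + 1), j]
    }
  }
  y
}

# Add lambda to the diagonal of a band-stored symmetric matrix.
band_shift <- function(ab, lambda) {
  ab[1, ] <- ab[1, ] + lambda
  ab
}

# Number of diagonals at or above the main diagonal of a symmetric matrix
# that contain any entry exceeding `tol` in magnitude.
count_nonzero_upper_diagonals <- function(A, tol = 0) {
  m <- nrow(A)
  sum(vapply(0:(m - 1), function(k) {
    j <- seq_len(m - k)
    any(abs(A[cbind(j, j + k)]) > tol)
  }, logical(1)))
}
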