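# Small numerical helpers shared across modules.

# package-level memo for expensive reference spectra (keyed by problem
# name + parameter values); lives for the R session
.vf_cache <- new.env(parent = emptyenv())

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
inv_softplus <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}
sigmoid <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

#' @noRd
vf_stop <- function(...) stop(sprintf(...), call. = FALSE)

# ---- batched small-matrix linear algebra --------------------------------
# Batches are stored as K x n x n arrays (K points, n coordinates, n <= ~12).

# batched matrix product: (K,n,n) x (K,n,n) -> (K,n,n)
bmm <- function(A, B) {
  n <- dim(A)[2]
  K <- dim(A)[1]
  C <- array(0, c(K, n, n))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    acc <- numeric(K)
    for (l in seq_len(n)) acc <- acc + A[, i, l] * B[, l, j]
    C[, i, j] <- acc
  }
  C
}

# batched matrix-vector: (K,n,n) x (K,n) -> (K,n)
bmv <- function(A, v) {
  n <- dim(A)[2]
  K <- dim(A)[1]
  out <- matrix(0, K, n)
  for (i in seq_len(n)) {
    acc <- numeric(K)
    for (l in seq_len(n)) acc <- acc + A[, i, l] * v[, l]
    out[, i] <- acc
  }
  out
}

# batched determinant for n <= 3 (closed form), larger n falls back to a loop
bdet <- function(A) {
  n <- dim(A)[2]
  if (n == 1L) return(A[, 1, 1])
  if (n == 2L) return(A[, 1, 1] * A[, 2, 2] - A[, 1, 2] * A[, 2, 1])
  if (n == 3L) {
    return(A[, 1, 1] * (A[, 2, 2] * A[, 3, 3] - A[, 2, 3] * A[, 3, 2]) -
           A[, 1, 2] * (A[, 2, 1] * A[, 3, 3] - A[, 2, 3] * A[, 3, 1]) +
           A[, 1, 3] * (A[, 2, 1] * A[, 3, 2] - A[, 2, 2] * A[, 3, 1]))
  }
  apply(A, 1, function(m) det(matrix(m, n, n)))
}

# batched inverse; closed form for n <= 3
binv <- function(A) {
  n <- dim(A)[2]
  K <- dim(A)[1]
  if (n == 1L) {
    out <- array(0, c(K, 1, 1)); out[, 1, 1] <- 1 / A[, 1, 1]; return(out)
  }
  d <- bdet(A)
  out <- array(0, c(K, n, n))
  if (n == 2L) {
    out[, 1, 1] <-  A[, 2, 2] / d
    out[, 2, 2] <-  A[, 1, 1] / d
    out[, 1, 2] <- -A[, 1, 2] / d
    out[, 2, 1] <- -A[, 2, 1] / d
    return(out)
  }
  if (n == 3L) {
    cof <- function(i1, i2, j1, j2) A[, i1, j1] * A[, i2, j2] - A[, i1, j2] * A[, i2, j1]
    out[, 1, 1] <-  cof(2, 3, 2, 3) / d
    out[, 1, 2] <- -cof(1, 3, 2, 3) / d
    out[, 1, 3] <-  cof(1, 2, 2, 3) / d
    out[, 2, 1] <- -cof(2, 3, 1, 3) / d
    out[, 2, 2] <-  cof(1, 3, 1, 3) / d
    out[, 2, 3] <- -cof(1, 2, 1, 3) / d
    out[, 3, 1] <-  cof(2, 3, 1, 2) / d
    out[, 3, 2] <- -cof(1, 3, 1, 2) / d
    out[, 3, 3] <-  cof(1, 2, 1, 2) / d
    return(out)
  }
  for (k in seq_len(K)) out[k, , ] <- solve(A[k, , ])
  out
}

# batched transpose
bt <- function(A) aperm(A, c(1, 3, 2))

# central finite-difference gradient of a scalar field f(r) (vectorized over
# rows of r), 4th-order five-point stencil; h per coordinate.
fd_grad <- function(f, r, h = 1e-4) {
  r <- as.matrix(r)
  n <- ncol(r)
  g <- matrix(0, nrow(r), n)
  for (j in seq_len(n)) {
    hp <- h * (1 + abs(r[, j]))
    rp1 <- r; rp1[, j] <- r[, j] + hp
    rm1 <- r; rm1[, j] <- r[, j] - hp
    rp2 <- r; rp2[, j] <- r[, j] + 2 * hp
    rm2 <- r; rm2[, j] <- r[, j] - 2 * hp
    g[, j] <- (-f(rp2) + 8 * f(rp1) - 8 * f(rm1) + f(rm2)) / (12 * hp)
  }
  g
}
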