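# Primitive orthonormal 1D bases, polyad-truncated direct products,
# Gaussian quadrature grids, and augmented-basis evaluation.

# ---- Gauss rules (Golub-Welsch, exact symmetric tridiagonal eigen) -------

#' Gauss quadrature nodes and weights
#'
#' Golub-Welsch construction from the Jacobi matrix of the orthogonal
#' polynomial family. `hermite` returns the rule for the weight exp(-x^2) on
#' the real line; `legendre` the rule for unit weight on \[-1, 1\].
#'
#' @param family `"hermite"` or `"legendre"`.
#' @param degree number of nodes (rule is exact for polynomials up to degree
#'   `2*degree - 1`).
#' @return list with `nodes` and `weights`, nodes ascending.
#' @keywords internal
gauss_rule <- function(family = c("hermite", "legendre"), degree) {
  family <- match.arg(family)
  stopifnot(degree >= 1)
  if (degree == 1L) {
    if (family == "hermite")
      return(list(nodes = 0, weights = sqrt(pi), weights_flat = sqrt(pi)))
    return(list(nodes = 0, weights = 2))
  }
  k <- seq_len(degree - 1)
  off <- if (family == "hermite") sqrt(k / 2) else k / sqrt(4 * k^2 - 1)
  J <- matrix(0, degree, degree)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  x <- sort(eigen(J, symmetric = TRUE, only.values = TRUE)$values)
  # weights from the stable derivative/function formulas (the Golub-Welsch
  # eigenvector components underflow at high degree)
  if (family == "hermite") {
    hk <- hermite_fun_table(degree - 1L, x)$val[, degree]
    wf <- 1 / (degree * hk^2)            # w_k * exp(x_k^2), all O(1)
    list(nodes = x, weights = wf * exp(-x^2), weights_flat = wf)
  } else {
    dP <- legendre_poly_table(degree, x)$d[, degree + 1L]
    list(nodes = x, weights = 2 / ((1 - x^2) * dP^2))
  }
}

# ---- 1D primitive families ----------------------------------------------

# Hermite functions h_n(y) = (2^n n! sqrt(pi))^(-1/2) H_n(y) exp(-y^2/2),
# orthonormal on R. Returns values (and derivatives) for n = 0..nmax at y.
hermite_fun_table <- function(nmax, y, deriv = FALSE) {
  y <- as.numeric(y)
  H <- matrix(0, length(y), nmax + 1L)
  H[, 1] <- pi^(-0.25) * exp(-y^2 / 2)
  if (nmax >= 1L) H[, 2] <- sqrt(2) * y * H[, 1]
  if (nmax >= 2L) for (n in 2:nmax) {
    H[, n + 1] <- y * sqrt(2 / n) * H[, n] - sqrt((n - 1) / n) * H[, n - 1]
  }
  if (!deriv) return(list(val = H))
  dH <- matrix(0, length(y), nmax + 1L)
  dH[, 1] <- -y * H[, 1]
  if (nmax >= 1L) for (n in 1:nmax) {
    dH[, n + 1] <- sqrt(2 * n) * H[, n] - y * H[, n + 1]
  }
  list(val = H, d = dH)
}

# Legendre polynomials P_l(u) and derivatives for l = 0..lmax.
legendre_poly_table <- function(lmax, u) {
  u <- as.numeric(u)
  P <- matrix(0, length(u), lmax + 1L)
  P[, 1] <- 1
  if (lmax >= 1L) P[, 2] <- u
  if (lmax >= 2L) for (l in 2:lmax) {
    P[, l + 1] <- ((2 * l - 1) * u * P[, l] - (l - 1) * P[, l - 1]) / l
  }
  dP <- matrix(0, length(u), lmax + 1L)
  if (lmax >= 1L) for (l in 1:lmax) {
    dP[, l + 1] <- l * (P[, l] - u * P[, l + 1]) / (1 - u^2)
  }
  list(val = P, d = dP)
}

# sin^1/2-weighted normalized Legendre functions on (0, pi):
# phi_l(a) = sqrt((2l+1)/2) P_l(cos a) sqrt(sin a), orthonormal wrt da.
legendre_sinehalf_table <- function(lmax, alpha, deriv = FALSE) {
  u <- cos(alpha)
  s <- sin(alpha)
  lp <- legendre_poly_table(lmax, u)
  norm <- sqrt((2 * seq(0, lmax) + 1) / 2)
  V <- sweep(lp$val * sqrt(s), 2, norm, `*`)
  if (!deriv) return(list(val = V))
  # d/da [P_l(cos a) sqrt(sin a)] = -sin a P_l'(u) sqrt(s) + P_l cos a/(2 sqrt(s))
  D <- sweep(-s * sqrt(s) * lp$d + lp$val * u / (2 * sqrt(s)), 2, norm, `*`)
  list(val = V, d = D)
}

# ---- BasisSpec -----------------------------------------------------------

#' Specify a direct-product primitive basis
#'
#' One entry per coordinate. Hermite coordinates use harmonic-oscillator
#' eigenfunctions `phi_n(q) = sigma^(-1/2) h_n((q - center)/width)` (the
#' Gaussian weight is part of the function); angular coordinates use
#' normalized Legendre polynomials in cos(q) multiplied by sin(q)^(1/2),
#' which builds in the correct behavior at linear geometries.
#'
#' @param family character vector, one of `"hermite"`, `"legendre_sinehalf"`
#'   per coordinate.
#' @param center,width numeric vectors (used by Hermite coordinates; ignored,
#'   and defaulted, for angular ones).
#' @param nmax integer vector, maximum 1D quantum number per coordinate.
#' @return an object of class `vf_basis_spec`.
#' @export
basis_spec <- function(family, center = NULL, width = NULL, nmax) {
  family <- match.arg(family, c("hermite", "legendre_sinehalf"), several.ok = TRUE)
  n <- length(family)
  if (is.null(center)) center <- rep(0, n)
  if (is.null(width)) width <- rep(1, n)
  stopifnot(length(center) == n, length(width) == n, length(nmax) == n,
            all(width > 0), all(nmax >= 0))
  structure(list(family = family, center = center, width = width,
                 nmax = as.integer(nmax), ncoord = n),
            class = "vf_basis_spec")
}

#' @export
print.vf_basis_spec <- function(x, ...) {
  cat("<vf_basis_spec> ", x$ncoord, " coordinate(s)\n", sep = "")
  for (i in seq_len(x$ncoord)) {
    cat(sprintf("  [%d] %s  nmax=%d", i, x$family[i], x$nmax[i]))
    if (x$family[i] == "hermite")
      cat(sprintf("  center=%g width=%g", x$center[i], x$width[i]))
    cat("\n")
  }
  invisible(x)
}

# 1D table of basis values (and derivatives) at points q for coordinate i.
basis_1d_table <- function(bs, i, q, deriv = FALSE) {
  if (bs$family[i] == "hermite") {
    y <- (q - bs$center[i]) / bs$width[i]
    tb <- hermite_fun_table(bs$nmax[i], y, deriv = deriv)
    tb$val <- tb$val / sqrt(bs$width[i])
    if (deriv) tb$d <- tb$d / bs$width[i]^1.5
    tb
  } else {
    legendre_sinehalf_table(bs$nmax[i], q, deriv = deriv)
  }
}

# ---- TruncationRule ------------------------------------------------------

#' Polyad truncation rule for a direct-product basis
#'
#' Retains multi-indices `n = (n_1, ..., n_d)` with
#' `sum(weights * n) <= pmax`.
#'
#' @param weights integer polyad weights, all `>= 1`.
#' @param pmax integer polyad cap, `>= 0`.
#' @export
truncation_rule <- function(weights, pmax) {
  stopifnot(all(weights >= 1), pmax >= 0,
            all(weights == as.integer(weights)), pmax == as.integer(pmax))
  structure(list(weights = as.integer(weights), pmax = as.integer(pmax)),
            class = "vf_truncation_rule")
}

#' Enumerate retained multi-indices in graded lexicographic order
#'
#' Indices are graded by the polyad value `sum(w * n)` and ordered
#' lexicographically within each grade, so eigenvector coefficients are
#' reproducible across runs.
#'
#' @param rule a [truncation_rule()].
#' @return integer matrix, one row per retained multi-index.
#' @export
enumerate_basis <- function(rule) {
  w <- rule$weights
  d <- length(w)
  caps <- rule$pmax %/% w
  grids <- lapply(caps, function(m) 0:m)
  idx <- as.matrix(expand.grid(rev(grids), KEEP.OUT.ATTRS = FALSE))[, d:1, drop = FALSE]
  poly <- as.vector(idx %*% w)
  keep <- poly <= rule$pmax
  idx <- idx[keep, , drop = FALSE]
  poly <- poly[keep]
  ord <- do.call(order, c(list(poly), lapply(seq_len(d), function(j) idx[, j])))
  idx <- idx[ord, , drop = FALSE]
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  idx
}

#' Count the retained direct-product basis functions
#'
#' @param rule a [truncation_rule()].
#' @return integer count of multi-indices with `sum(weights * n) <= pmax`.
#' @export
count_basis <- function(rule) nrow(enumerate_basis(rule))

# ---- QuadratureGrid ------------------------------------------------------

#' Build a tensor-product Gaussian quadrature grid for a basis
#'
#' Gauss-Hermite rules (mapped by the basis center/width) are used for
#' Hermite coordinates and Gauss-Legendre rules in cos(alpha) for angular
#' coordinates. The returned weights are adjusted so that
#' `sum_k w_k phi_m(q_k) phi_n(q_k) = delta_mn` holds to the rule's
#' exactness (the Gaussian weight of the Hermite functions and the sin
#' factor of the angular measure are divided out).
#'
#' @param bs a [basis_spec()].
#' @param degrees integer vector of 1D quadrature degrees.
#' @return an object of class `vf_quadrature` with per-coordinate `nodes`
#'   and `weights`, the tensor node matrix `Q` (K x d) and weight vector `W`.
#' @export
build_quadrature <- function(bs, degrees) {
  d <- bs$ncoord
  stopifnot(length(degrees) == d)
  for (i in seq_len(d)) {
    if (degrees[i] < bs$nmax[i] + 1L)
      vf_stop("quadrature degree %d too small for coordinate %d (nmax = %d): need at least nmax + 1",
              degrees[i], i, bs$nmax[i])
  }
  nodes <- vector("list", d)
  weights <- vector("list", d)
  for (i in seq_len(d)) {
    if (bs$family[i] == "hermite") {
      gr <- gauss_rule("hermite", degrees[i])
      nodes[[i]] <- bs$center[i] + bs$width[i] * gr$nodes
      weights[[i]] <- bs$width[i] * gr$weights_flat
    } else {
      gr <- gauss_rule("legendre", degrees[i])
      a <- acos(gr$nodes)
      ord <- order(a)
      nodes[[i]] <- a[ord]
      weights[[i]] <- (gr$weights / sin(a))[ord]
    }
  }
  grids <- do.call(expand.grid, c(rev(nodes), KEEP.OUT.ATTRS = FALSE))
  Q <- as.matrix(grids)[, d:1, drop = FALSE]
  dimnames(Q) <- NULL
  wg <- do.call(expand.grid, c(rev(weights), KEEP.OUT.ATTRS = FALSE))
  W <- Reduce(`*`, as.list(as.data.frame(as.matrix(wg))))
  structure(list(nodes = nodes, weights = weights, degrees = as.integer(degrees),
                 Q = Q, W = as.numeric(W), ncoord = d),
            class = "vf_quadrature")
}

#' @export
print.vf_quadrature <- function(x, ...) {
  cat("<vf_quadrature> degrees:", paste(x$degrees, collapse = " x "),
      " (", nrow(x$Q), " tensor nodes)\n", sep = "")
  invisible(x)
}

# ---- basis evaluation ----------------------------------------------------

# Evaluate all retained product functions at points Q (K x d).
# Returns B (K x N); with deriv = TRUE also dB, a list of d matrices (K x N)
# of partial derivatives wrt each coordinate.
basis_matrix <- function(bs, idx, Q, deriv = FALSE) {
  Q <- as.matrix(Q)
  d <- bs$ncoord
  N <- nrow(idx)
  K <- nrow(Q)
  tabs <- lapply(seq_len(d), function(i) basis_1d_table(bs, i, Q[, i], deriv = deriv))
  B <- matrix(1, K, N)
  for (i in seq_len(d)) B <- B * tabs[[i]]$val[, idx[, i] + 1L, drop = FALSE]
  if (!deriv) return(list(B = B))
  dB <- vector("list", d)
  for (j in seq_len(d)) {
    M <- matrix(1, K, N)
    for (i in seq_len(d)) {
      tb <- if (i == j) tabs[[i]]$d else tabs[[i]]$val
      M <- M * tb[, idx[, i] + 1L, drop = FALSE]
    }
    dB[[j]] <- M
  }
  list(B = B, dB = dB)
}

# Per-coordinate half log-derivative of the native measure weight rho_i(q):
# rho = 1 for Hermite coordinates, rho = sin(q) for angular (Legendre)
# coordinates. The kinetic-energy assembly uses the weighted derivative
# d/dq - (d log rho)/2, which absorbs the linear-geometry-singular part of
# the pseudopotential exactly (the boundary terms of the plain symmetric
# form do not vanish for the sin^1/2-weighted basis).
measure_half_logderiv <- function(bs, Q) {
  Q <- as.matrix(Q)
  out <- matrix(0, nrow(Q), bs$ncoord)
  for (i in seq_len(bs$ncoord)) {
    if (bs$family[i] == "legendre_sinehalf")
      out[, i] <- cos(Q[, i]) / (2 * sin(Q[, i]))
  }
  out
}

#' Evaluate primitive product basis functions
#'
#' @param bs a [basis_spec()].
#' @param multi_index integer vector (one multi-index) or matrix (one row per
#'   multi-index).
#' @param q numeric vector (one point) or matrix (one row per point).
#' @return numeric matrix of values, points in rows, multi-indices in columns
#'   (dropped to a vector when a single multi-index is given).
#' @export
eval_primitive <- function(bs, multi_index, q) {
  idx <- if (is.matrix(multi_index)) multi_index else matrix(multi_index, nrow = 1)
  if (any(idx > rep(bs$nmax, each = nrow(idx))))
    vf_stop("multi-index exceeds the basis nmax")
  Q <- if (is.matrix(q)) q else matrix(q, ncol = bs$ncoord)
  out <- basis_matrix(bs, idx, Q)$B
  if (nrow(idx) == 1L) drop(out) else out
}

#' Evaluate augmented (flow-composed) basis functions
#'
#' Computes `gamma_n(r) = phi_n(g(r)) |det J_g(r)|^(1/2)` where `g` is the
#' flow map. Multiplication by the square-root Jacobian determinant keeps the
#' augmented set orthonormal in the original coordinates for any flow
#' parameters.
#'
#' @param bs a [basis_spec()].
#' @param fm a [flow_model()].
#' @param multi_index integer vector or matrix of multi-indices.
#' @param r numeric vector (one point) or matrix of points in the original
#'   coordinates.
#' @return values of the augmented functions (points in rows).
#' @export
eval_augmented <- function(bs, fm, multi_index, r) {
  R <- if (is.matrix(r)) r else matrix(r, ncol = bs$ncoord)
  fw <- flow_jacobian(fm, R)
  idx <- if (is.matrix(multi_index)) multi_index else matrix(multi_index, nrow = 1)
  phi <- basis_matrix(bs, idx, fw$q)$B
  out <- phi * exp(fw$logdet / 2)
  if (nrow(idx) == 1L) drop(out) else out
}
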