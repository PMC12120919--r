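# Internal-coordinate systems: domains, Cartesian embeddings, the exact
# kinetic-energy G-matrix, g~ = det(G^-1), and the Podolsky pseudopotential.

#' Describe the domain of one internal coordinate
#'
#' @param kind `"finite"`, `"semi_infinite"` or `"infinite"`.
#' @param lower,upper numeric bounds (`-Inf`/`Inf` allowed as appropriate).
#' @param periodic logical; only allowed for finite domains.
#' @export
coordinate_domain <- function(kind = c("finite", "semi_infinite", "infinite"),
                              lower = -Inf, upper = Inf, periodic = FALSE) {
  kind <- match.arg(kind)
  if (kind == "finite") stopifnot(is.finite(lower), is.finite(upper))
  if (kind == "semi_infinite") stopifnot(is.finite(lower), upper == Inf)
  if (kind == "infinite") { lower <- -Inf; upper <- Inf }
  if (!(lower < upper)) vf_stop("domain requires lower < upper")
  if (periodic && kind != "finite") vf_stop("periodic only allowed for finite domains")
  structure(list(kind = kind, lower = lower, upper = upper, periodic = periodic),
            class = "vf_domain")
}

#' Define an internal-coordinate system
#'
#' Exactly one of `embedding` + `masses` (Cartesian embedding, from which the
#' exact kinetic-energy G-matrix is constructed numerically) or `g_field`
#' (user-supplied map from a coordinate vector to a symmetric G matrix) must
#' be provided.
#'
#' @param names character vector of coordinate labels.
#' @param domains list of [coordinate_domain()] objects.
#' @param embedding function `(r, masses) -> natoms x 3` matrix of Cartesian
#'   positions, or the name of a registered embedding
#'   (see `vf_embeddings`).
#' @param masses atomic masses (amu or toy units), required with `embedding`.
#' @param g_field function `(r) -> n x n` symmetric matrix.
#' @param g_field_batch optional vectorized variant `(R) -> K x n x n` array
#'   used in performance-critical paths.
#' @param u_field optional explicit pseudopotential function `(R) -> K`
#'   overriding the numerical construction from `g_field` derivatives
#'   (used by model systems whose singular kinetic term is known in closed
#'   form).
#' @return an object of class `vf_coords`.
#' @export
coordinate_system <- function(names, domains, embedding = NULL, masses = NULL,
                              g_field = NULL, g_field_batch = NULL,
                              u_field = NULL) {
  n <- length(names)
  stopifnot(length(domains) == n)
  has_emb <- !is.null(embedding)
  has_g <- !is.null(g_field)
  if (has_emb == has_g)
    vf_stop("provide exactly one of {embedding + masses, g_field}")
  if (has_emb) {
    if (is.character(embedding)) {
      if (!embedding %in% names(vf_embeddings))
        vf_stop("unknown embedding '%s'; registered: %s", embedding,
                paste(names(vf_embeddings), collapse = ", "))
      embedding <- vf_embeddings[[embedding]]
    }
    stopifnot(is.function(embedding), !is.null(masses), all(masses > 0))
  }
  structure(list(names = names, domains = domains, embedding = embedding,
                 masses = masses, g_field = g_field,
                 g_field_batch = g_field_batch, u_field = u_field, ncoord = n),
            class = "vf_coords")
}

#' @export
print.vf_coords <- function(x, ...) {
  cat("<vf_coords>", paste(x$names, collapse = ", "), "\n")
  cat("  kinetic energy from:",
      if (!is.null(x$g_field)) "user G field" else "Cartesian embedding", "\n")
  invisible(x)
}

# ---- registered embeddings ----------------------------------------------

#' Registered Cartesian embeddings
#'
#' Named list of functions `(r, masses) -> natoms x 3` matrices:
#' `diatomic` (bond length), `valence_triatomic` (two bond lengths and the
#' included angle, central atom second), `jacobi_triatomic` (diatom bond
#' length, atom-to-diatom-center-of-mass distance, and the angle between
#' the two vectors).
#'
#' @export
vf_embeddings <- list(
  diatomic = function(r, masses) {
    rbind(c(0, 0, 0), c(r[1], 0, 0))
  },
  valence_triatomic = function(r, masses) {
    r1 <- r[1]; r2 <- r[2]; a <- r[3]
    rbind(r1 * c(sin(a / 2), cos(a / 2), 0),
          c(0, 0, 0),
          r2 * c(-sin(a / 2), cos(a / 2), 0))
  },
  jacobi_triatomic = function(r, masses) {
    # r = (r_diatom, R, alpha); atoms 1-2 form the diatom along z with their
    # center of mass at the origin; atom 3 at distance R, angle alpha from z
    m1 <- masses[1]; m2 <- masses[2]
    rd <- r[1]; R <- r[2]; a <- r[3]
    rbind(c(0, 0, -m2 * rd / (m1 + m2)),
          c(0, 0, m1 * rd / (m1 + m2)),
          c(R * sin(a), 0, R * cos(a)))
  }
)

# ---- G-matrix construction ----------------------------------------------

# Jacobian d x / d r of the embedding by 4th-order central differences.
embedding_jacobian <- function(emb, r, masses, h = 1e-5) {
  n <- length(r)
  x0 <- emb(r, masses)
  J <- matrix(0, length(x0), n)
  for (j in seq_len(n)) {
    hp <- h * (1 + abs(r[j]))
    shift <- function(s) { rr <- r; rr[j] <- r[j] + s * hp; as.numeric(emb(rr, masses)) }
    J[, j] <- (-shift(2) + 8 * shift(1) - 8 * shift(-1) + shift(-2)) / (12 * hp)
  }
  list(x0 = x0, J = J)
}

#' Kinetic-energy G-matrix from a Cartesian embedding
#'
#' Numerically exact construction: the embedding Jacobian columns are
#' augmented with overall-translation and overall-rotation generators, the
#' mass-weighted metric of the full frame is inverted, and the vibrational
#' block of the inverse is returned. This equals the Wilson G-matrix
#' `G = B M^-1 B^T` for any embedding, without per-molecule formulas.
#'
#' @param cs a [coordinate_system()] with an embedding (a user-supplied
#'   `g_field` is passed through unchanged).
#' @param r coordinate vector.
#' @return symmetric positive-definite `n x n` matrix (units
#'   1/(mass x length^2)).
#' @export
gmatrix_from_embedding <- function(cs, r) {
  if (!is.null(cs$g_field)) return(cs$g_field(r))
  n <- cs$ncoord
  ej <- embedding_jacobian(cs$embedding, r, cs$masses)
  x0 <- ej$x0
  natoms <- nrow(x0)
  cols <- ej$J
  # Cartesian layout is coordinate-major: (x_1..x_A, y_1..y_A, z_1..z_A)
  for (ax in 1:3) {
    tcol <- numeric(3 * natoms)
    tcol[((ax - 1) * natoms + 1):(ax * natoms)] <- 1
    cols <- cbind(cols, tcol)
  }
  # rotation generators e_ax x x_a; drop directions annihilated by the
  # geometry (e.g. rotation about a linear molecule's axis)
  ref_scale <- max(abs(x0), 1e-8)
  for (ax in 1:3) {
    e <- c(0, 0, 0); e[ax] <- 1
    rcol <- as.numeric(t(apply(x0, 1, function(xa) pracma_cross(e, xa))))
    if (sqrt(sum(rcol^2)) > 1e-9 * ref_scale) cols <- cbind(cols, rcol)
  }
  Mw <- rep(cs$masses, times = 3)
  g_full <- t(cols) %*% (cols * Mw)
  cn <- tryCatch(rcond(g_full), error = function(e) 0)
  if (!is.finite(cn) || cn < 1e-13) {
    worst <- which.min(diag(g_full)[seq_len(n)])
    vf_stop("singular geometry at r = (%s): the metric of coordinate '%s' degenerates",
            paste(signif(r, 6), collapse = ", "), cs$names[worst])
  }
  Gfull <- solve(g_full)
  G <- Gfull[seq_len(n), seq_len(n), drop = FALSE]
  (G + t(G)) / 2
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Build the kinetic field (G, g~, U) of a coordinate system
#'
#' @param cs a [coordinate_system()].
#' @param constant_G set `TRUE` when G does not depend on the coordinates;
#'   the pseudopotential is then identically zero and is skipped.
#' @return an object of class `vf_kinetic` with members `G(r)` (matrix),
#'   `G_batch(R)` (K x n x n array), `g_tilde(R)` (vector, det(G^-1)), and
#'   `U(R)` (vector pseudopotential).
#' @export
kinetic_field <- function(cs, constant_G = FALSE) {
  n <- cs$ncoord
  G_point <- function(r) {
    G <- gmatrix_from_embedding(cs, r)
    if (any(!is.finite(G))) vf_stop("non-finite G at r = (%s)", paste(signif(r, 6), collapse = ", "))
    G
  }
  G_batch <- if (!is.null(cs$g_field_batch)) {
    cs$g_field_batch
  } else {
    function(R) {
      R <- as.matrix(R)
      out <- array(0, c(nrow(R), n, n))
      for (k in seq_len(nrow(R))) out[k, , ] <- G_point(R[k, ])
      out
    }
  }
  g_tilde <- function(R) {
    R <- if (is.matrix(R)) R else matrix(R, ncol = n)
    1 / bdet(G_batch(R))
  }
  U_fun <- if (!is.null(cs$u_field)) {
    cs$u_field
  } else if (constant_G) {
    function(R) numeric(if (is.matrix(R)) nrow(R) else 1L)
  } else {
    function(R) pseudopotential_numeric(G_batch, g_tilde, R, n)
  }
  structure(list(G = G_point, G_batch = G_batch, g_tilde = g_tilde, U = U_fun,
                 constant_G = constant_G, ncoord = n),
            class = "vf_kinetic")
}

# Podolsky pseudopotential (hbar = 1):
#   U = (1/32) sum_lm [ G_lm g_l g_m / g^2 + 4 d/dr_l ( G_lm g_m / g ) ],
# with g = g~ = det(G^-1) and g_l its partial derivatives. The relative sign
# was fixed against an independent symbolic derivation of the Podolsky
# operator (in 1D the expression equals -G''/8 + G'^2/(32 G)).
pseudopotential_numeric <- function(G_batch, g_tilde, R, n, h = 1e-4) {
  R <- if (is.matrix(R)) R else matrix(R, ncol = n)
  K <- nrow(R)
  gt <- g_tilde(R)
  dgt <- fd_grad(g_tilde, R, h = h)
  G <- G_batch(R)
  term1 <- numeric(K)
  for (l in seq_len(n)) for (m in seq_len(n))
    term1 <- term1 + G[, l, m] * dgt[, l] * dgt[, m]
  term1 <- term1 / gt^2
  # F_l(r) = sum_m G_lm dgt_m / gt ; term2 = 4 sum_l dF_l/dr_l
  F_field <- function(X, l) {
    Gx <- G_batch(X)
    gx <- g_tilde(X)
    dg <- fd_grad(g_tilde, X, h = h)
    acc <- numeric(nrow(X))
    for (m in seq_len(n)) acc <- acc + Gx[, l, m] * dg[, m]
    acc / gx
  }
  term2 <- numeric(K)
  for (l in seq_len(n)) {
    hp <- h * (1 + abs(R[, l]))
    Rp <- R; Rp[, l] <- R[, l] + hp
    Rm <- R; Rm[, l] <- R[, l] - hp
    term2 <- term2 + (F_field(Rp, l) - F_field(Rm, l)) / (2 * hp)
  }
  (term1 + 4 * term2) / 32
}

#' Evaluate the pseudopotential of a kinetic field
#'
#' @param kf a [kinetic_field()].
#' @param r coordinate vector or matrix of points (rows).
#' @return numeric vector of pseudopotential values.
#' @export
pseudopotential <- function(kf, r) {
  R <- if (is.matrix(r)) r else matrix(r, ncol = kf$ncoord)
  u <- kf$U(R)
  if (any(!is.finite(u)))
    vf_stop("non-finite pseudopotential at r = (%s)",
            paste(signif(R[which(!is.finite(u))[1], ], 6), collapse = ", "))
  u
}
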