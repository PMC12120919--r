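# Assembly of potential, kinetic, pseudopotential and overlap matrices in the
# augmented basis, and the dense symmetric eigenproblem.
#
# All integrals are Gaussian quadratures in the native basis coordinates q;
# r-space quantities are pulled back through the flow inverse. The kinetic
# matrix uses the symmetric first-derivative form obtained by integration by
# parts (boundary term omitted; the primitive bases decay or carry the
# sin^1/2 factor at the domain edges):
#
#   T_nm = (hbar^2/2) Int dq sum_kl (d_k phi_n + phi_n B_k) Gbar_kl
#                                  (d_l phi_m + phi_m B_l)
#
# with Gbar = J G(r) J^T (J = dq/dr) and B_k = d(log|det J|^(1/2))/dq_k.

# q-space representation of the measure half log-derivative: w_q = J^-T w_r
# with w_r,i = (d log rho_i / dr_i)/2 (rho = sin for angular coordinates)
measure_weight_q <- function(bs, fr) {
  mr <- measure_half_logderiv(bs, fr$r)
  if (all(mr == 0)) return(mr)
  bmv(bt(binv(fr$J)), mr)
}

resolve_idx <- function(bs, rule) {
  idx <- if (inherits(rule, "vf_truncation_rule")) enumerate_basis(rule) else as.matrix(rule)
  if (ncol(idx) != bs$ncoord) vf_stop("truncation rule dimension does not match basis")
  if (any(idx > rep(bs$nmax, each = nrow(idx))))
    vf_stop("truncation retains indices above the basis nmax; increase nmax")
  idx
}

# Pull quadrature nodes back through the flow and gather all per-node flow
# quantities needed for matrix assembly. fm = NULL denotes the strict
# identity map (q = r), used for reference-coordinate calculations.
augmented_frame <- function(fm, grid, kf = NULL, warm_cache = NULL, ld_order = 4L) {
  Q <- grid$Q
  K <- nrow(Q)
  d <- ncol(Q)
  if (is.null(fm)) {
    r <- Q
    J <- array(0, c(K, d, d))
    for (i in seq_len(d)) J[, i, i] <- 1
    logdet <- numeric(K)
    Bq <- matrix(0, K, d)
    qf <- Q
  } else {
    r <- flow_inverse(fm, Q, warm_cache = warm_cache)
    r <- if (is.matrix(r)) r else matrix(r, ncol = d)
    fj <- flow_jacobian(fm, r)
    qf <- fj$q
    if (max(abs(qf - Q)) > 1e-8)
      vf_stop("flow inverse/forward round trip failed at quadrature nodes (%.3e)",
              max(abs(qf - Q)))
    J <- fj$J
    logdet <- fj$logdet
    grad <- flow_logdet_grad(fm, r, order = ld_order)
    Bq <- bmv(bt(binv(J)), grad / 2)
  }
  out <- list(r = r, q = qf, W = grid$W, J = J, logdet = logdet, Bq = Bq)
  if (!is.null(kf)) {
    Garr <- kf$G_batch(r)
    out$Gbar <- bmm(bmm(J, Garr), bt(J))
  }
  out
}

#' Potential-energy matrix in the augmented basis
#'
#' `V_nm = sum_k w_k phi_n(q_k) V(g^-1(q_k)) phi_m(q_k)`.
#'
#' @param bs a [basis_spec()].
#' @param fm a [flow_model()], or `NULL` for the identity map.
#' @param potential vectorized function: matrix of points (rows) -> values.
#' @param grid a [build_quadrature()] grid.
#' @param rule a [truncation_rule()] or an index matrix.
#' @return symmetric `N x N` matrix.
#' @export
build_potential <- function(bs, fm, potential, grid, rule) {
  idx <- resolve_idx(bs, rule)
  fr <- augmented_frame(fm, grid)
  v <- potential(fr$r)
  if (any(!is.finite(v))) {
    bad <- which(!is.finite(v))
    vf_stop("potential undefined (non-finite) at %d pulled-back node(s); first offender r = (%s)",
            length(bad), paste(signif(fr$r[bad[1], ], 6), collapse = ", "))
  }
  B <- basis_matrix(bs, idx, fr$q)$B
  M <- crossprod(B, B * (fr$W * v))
  (M + t(M)) / 2
}

#' Kinetic-energy matrix in the augmented basis
#'
#' Symmetric first-derivative quadrature form (see file header); reduces to
#' `(hbar^2/2) <dphi_n/dq | G | dphi_m/dq>` under the identity flow.
#'
#' @inheritParams build_potential
#' @param kf a [kinetic_field()].
#' @export
build_kinetic <- function(bs, fm, kf, grid, rule) {
  idx <- resolve_idx(bs, rule)
  fr <- augmented_frame(fm, grid, kf = kf)
  bm <- basis_matrix(bs, idx, fr$q, deriv = TRUE)
  d <- bs$ncoord
  # the measure half log-derivative lives in the original coordinates r and
  # transforms through J^-T exactly like the log-det gradient
  Wq <- measure_weight_q(bs, fr)
  Dl <- vector("list", d)
  for (a in seq_len(d)) Dl[[a]] <- bm$dB[[a]] + bm$B * (fr$Bq[, a] - Wq[, a])
  N <- nrow(idx)
  Tm <- matrix(0, N, N)
  for (a in seq_len(d)) for (b in seq_len(d)) {
    wg <- fr$W * fr$Gbar[, a, b]
    if (all(wg == 0)) next
    Tm <- Tm + crossprod(Dl[[a]], Dl[[b]] * wg)
  }
  Tm <- Tm / 2
  asym <- max(abs(Tm - t(Tm))) / max(abs(Tm), 1e-300)
  if (asym > 1e-8)
    vf_stop("kinetic matrix asymmetry %.3e exceeds tolerance (derivative inconsistency)", asym)
  (Tm + t(Tm)) / 2
}

#' Pseudopotential matrix in the augmented basis
#'
#' Identical contract to [build_potential()] with the potential replaced by
#' the scalar pseudopotential of the kinetic field.
#'
#' @inheritParams build_kinetic
#' @export
build_pseudopotential_matrix <- function(bs, fm, kf, grid, rule) {
  build_potential(bs, fm, function(R) pseudopotential(kf, R), grid, rule)
}

#' Overlap matrix of the augmented basis
#'
#' Computed honestly through the flow round trip (inverse, forward,
#' Jacobian): equals the identity to quadrature exactness for any flow
#' parameters, which is the orthonormality guarantee of the square-root
#' Jacobian weighting.
#'
#' @inheritParams build_potential
#' @export
build_overlap <- function(bs, fm, grid, rule) {
  idx <- resolve_idx(bs, rule)
  fr <- augmented_frame(fm, grid)
  gamma <- basis_matrix(bs, idx, fr$q)$B * exp(fr$logdet / 2)
  wD <- fr$W * exp(-fr$logdet)
  M <- crossprod(gamma, gamma * wD)
  (M + t(M)) / 2
}

#' Assemble all Hamiltonian matrices
#'
#' @inheritParams build_kinetic
#' @param potential vectorized potential function.
#' @return object of class `vf_hmats` with `T`, `V`, `U`, `S`, the index
#'   matrix and quadrature metadata.
#' @export
build_hamiltonian <- function(bs, fm, kf, potential, grid, rule) {
  idx <- resolve_idx(bs, rule)
  Tm <- build_kinetic(bs, fm, kf, grid, idx)
  Vm <- build_potential(bs, fm, potential, grid, idx)
  Um <- build_pseudopotential_matrix(bs, fm, kf, grid, idx)
  Sm <- build_overlap(bs, fm, grid, idx)
  structure(list(T = Tm, V = Vm, U = Um, S = Sm, idx = idx,
                 degrees = grid$degrees),
            class = "vf_hmats")
}

#' @export
print.vf_hmats <- function(x, ...) {
  cat(sprintf("<vf_hmats> N = %d, quadrature degrees %s\n",
              nrow(x$T), paste(x$degrees, collapse = " x ")))
  invisible(x)
}

#' Solve the symmetric eigenproblem
#'
#' Dense symmetric eigensolution of `H = T + V + U`; the lowest `M`
#' eigenpairs are returned in ascending order with a deterministic sign
#' convention (largest-magnitude coefficient positive).
#'
#' @param h a `vf_hmats` object (or a plain symmetric matrix).
#' @param M number of states to return.
#' @return object of class `vf_spectrum` with `energies`, `coefficients`
#'   (columns are states), and the basis index matrix.
#' @export
solve_spectrum <- function(h, M = NULL) {
  H <- if (inherits(h, "vf_hmats")) h$T + h$V + h$U else as.matrix(h)
  if (any(!is.finite(H))) vf_stop("non-finite entries in the Hamiltonian matrix")
  N <- nrow(H)
  if (is.null(M)) M <- N
  if (M > N) vf_stop("requested %d states from an N = %d basis", M, N)
  e <- eigen((H + t(H)) / 2, symmetric = TRUE)
  energies <- rev(e$values)[seq_len(M)]
  C <- e$vectors[, order(e$values)[seq_len(M)], drop = FALSE]
  for (j in seq_len(ncol(C))) {
    i <- which.max(abs(C[, j]))
    if (C[i, j] < 0) C[, j] <- -C[, j]
  }
  structure(list(energies = energies, coefficients = C,
                 idx = if (inherits(h, "vf_hmats")) h$idx else NULL,
                 M = M),
            class = "vf_spectrum")
}

#' @export
print.vf_spectrum <- function(x, ...) {
  cat("<vf_spectrum>", x$M, "state(s); lowest energies:\n")
  print(utils::head(x$energies, 10))
  invisible(x)
}

#' Write a spectrum as a plain-text energy table
#'
#' @param sp a `vf_spectrum`.
#' @param file path of the tab-delimited output.
#' @param assignments optional result of [assign_states()] to append leading
#'   quantum numbers.
#' @export
write_energy_table <- function(sp, file, assignments = NULL) {
  df <- data.frame(state = seq_along(sp$energies) - 1L, energy = sp$energies)
  if (!is.null(assignments)) {
    df$assignment <- vapply(seq_len(nrow(assignments$records)), function(i)
      paste(assignments$records$labels[[i]], collapse = " "), character(1))
    df$p_max <- assignments$records$p_max
  }
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

# diagnostic: estimate of the integrated-by-parts boundary term for the
# kinetic matrix, evaluated on the faces of the quadrature node box
boundary_term_estimate <- function(bs, fm, kf, grid, rule, nprobe = 64L) {
  idx <- resolve_idx(bs, rule)
  d <- bs$ncoord
  est <- 0
  for (i in seq_len(d)) {
    for (side in c(1L, length(grid$nodes[[i]]))) {
      q <- vapply(seq_len(d), function(j) {
        if (j == i) grid$nodes[[i]][side] else stats::median(grid$nodes[[j]])
      }, numeric(1))
      fr <- tryCatch({
        r <- if (is.null(fm)) matrix(q, 1) else matrix(flow_inverse(fm, q), 1)
        bm <- basis_matrix(bs, idx, matrix(q, 1), deriv = TRUE)
        max(abs(bm$B * bm$dB[[i]]))
      }, error = function(e) NA_real_)
      if (is.finite(fr)) est <- max(est, fr)
    }
  }
  est
}
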