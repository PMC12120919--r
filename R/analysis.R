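# Spectrum analysis: projection-based assignment of approximate quantum
# numbers onto contracted 1D eigenfunctions, basis-set convergence-rate
# fits, and potential-energy cuts in flow coordinates.

#' Contracted one-dimensional eigenfunctions along one coordinate
#'
#' Partitions the Hamiltonian into a one-dimensional subsystem for the
#' chosen coordinate: all other coordinates are frozen at a reference point
#' (in flow coordinates q), and the reduced Hamiltonian is built with the
#' same augmented-basis machinery at n = 1 and diagonalized. The returned
#' eigenfunctions are expansion vectors over the coordinate's primitive 1D
#' basis, so projections of full eigenstates reduce to exact linear algebra.
#'
#' @param bs a [basis_spec()].
#' @param fm a [flow_model()] or `NULL` for the identity map (reference
#'   coordinates).
#' @param kf a [kinetic_field()].
#' @param potential vectorized potential function of the original
#'   coordinates.
#' @param coord index of the coordinate to contract.
#' @param q_ref numeric vector (length = number of coordinates): reference
#'   point in flow coordinates at which the other coordinates are frozen.
#' @param degree 1D quadrature degree.
#' @return list with `energies`, `vectors` (columns = 1D eigenfunctions over
#'   the primitive basis), and `coord`.
#' @export
contract_1d <- function(bs, fm, kf, potential, coord, q_ref, degree) {
  d <- bs$ncoord
  stopifnot(length(q_ref) == d, coord >= 1, coord <= d)
  bs1 <- basis_spec(bs$family[coord], bs$center[coord], bs$width[coord],
                    nmax = bs$nmax[coord])
  g1 <- build_quadrature(bs1, degree)
  K <- length(g1$nodes[[1]])
  Q <- matrix(rep(q_ref, each = K), K, d)
  Q[, coord] <- g1$nodes[[1]]
  grid <- structure(list(nodes = stats::setNames(list(g1$nodes[[1]]), NULL),
                         weights = list(g1$weights[[1]]),
                         degrees = degree, Q = Q, W = g1$weights[[1]],
                         ncoord = d),
                    class = "vf_quadrature")
  fr <- augmented_frame(fm, grid, kf = kf)
  tb <- basis_1d_table(bs, coord, Q[, coord], deriv = TRUE)
  Wq <- measure_weight_q(bs, fr)
  Dm <- tb$d + tb$val * (fr$Bq[, coord] - Wq[, coord])
  W <- grid$W
  v <- potential(fr$r) + kf$U(fr$r)
  H <- 0.5 * crossprod(Dm, Dm * (W * fr$Gbar[, coord, coord])) +
    crossprod(tb$val, tb$val * (W * v))
  sp <- solve_spectrum((H + t(H)) / 2)
  list(energies = sp$energies, vectors = sp$coefficients, coord = coord)
}

#' Assign approximate quantum numbers by projection
#'
#' Each eigenstate is projected onto all direct products of contracted 1D
#' eigenfunctions; the product with the largest norm-square projection
#' defines the assignment, which is unique when that norm-square exceeds
#' 0.5 (strictly).
#'
#' @param spectrum a `vf_spectrum` from [solve_spectrum()].
#' @param contractions list of [contract_1d()] results, one per coordinate,
#'   in coordinate order.
#' @return object of class `vf_assignment`: `records` data frame (state,
#'   energy index, `p_max`, `unique`, assigned labels) and `summary` with
#'   the median/mean/min largest projections and `N_assign`.
#' @export
assign_states <- function(spectrum, contractions) {
  idx <- spectrum$idx
  if (is.null(idx)) vf_stop("spectrum carries no basis index matrix")
  d <- ncol(idx)
  stopifnot(length(contractions) == d)
  dims <- apply(idx, 2, max) + 1L
  n1d <- vapply(contractions, function(ct) ncol(ct$vectors), integer(1))
  M <- spectrum$M
  p_max <- numeric(M)
  labels <- matrix(0L, M, d)
  for (m in seq_len(M)) {
    arr <- array(0, dims)
    arr[matrix(idx + 1L, ncol = d)] <- spectrum$coefficients[, m]
    # contract each dimension with the 1D eigenvector matrices
    for (i in seq_len(d)) {
      Ui <- contractions[[i]]$vectors[seq_len(dims[i]), , drop = FALSE]
      mat <- matrix(aperm(arr, c(i, seq_len(d)[-i])), dims[i])
      arr2 <- crossprod(Ui, mat)           # n1d_i x rest
      newdims <- c(n1d[i], dims[-i])
      arr <- aperm(array(arr2, newdims), order(c(i, seq_len(d)[-i])))
      dims[i] <- n1d[i]
    }
    p <- arr^2
    tot <- sum(p)
    if (tot > 1 + 1e-6)
      vf_stop("projection norm %.8f exceeds 1 (grid inconsistency)", tot)
    best <- which.max(p)
    p_max[m] <- p[best]
    labels[m, ] <- arrayInd(best, dim(p)) - 1L
  }
  unique_flag <- p_max > 0.5
  records <- data.frame(state = seq_len(M) - 1L, p_max = p_max,
                        unique = unique_flag)
  records$labels <- lapply(seq_len(M), function(m) labels[m, ])
  structure(list(records = records,
                 summary = data.frame(median = stats::median(p_max),
                                      mean = mean(p_max), min = min(p_max),
                                      N_assign = sum(unique_flag))),
            class = "vf_assignment")
}

#' @export
print.vf_assignment <- function(x, ...) {
  cat("<vf_assignment>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Fit the algebraic basis-set convergence rate
#'
#' Ordinary least squares of `log(L) = -k log(N) + log(A)`.
#'
#' @param losses positive loss (or error) values.
#' @param Ns basis sizes, same length (at least 3).
#' @return object of class `vf_convergence_fit` with `k`, `logA`, standard
#'   errors, and the fitted values.
#' @export
fit_convergence <- function(losses, Ns) {
  if (length(losses) != length(Ns) || length(losses) < 3)
    vf_stop("need at least 3 (loss, N) pairs")
  if (any(losses <= 0)) vf_stop("losses must be positive for a log-log fit")
  fit <- stats::lm(log(losses) ~ log(Ns))
  cf <- stats::coef(fit)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  structure(list(k = -unname(cf[2]), logA = unname(cf[1]),
                 k_se = unname(se[2]), logA_se = unname(se[1]),
                 Ns = Ns, fitted = exp(stats::fitted(fit))),
            class = "vf_convergence_fit")
}

#' @export
print.vf_convergence_fit <- function(x, ...) {
  cat(sprintf("<vf_convergence_fit> k = %.4g +/- %.2g, log A = %.4g +/- %.2g (n = %d)\n",
              x$k, x$k_se, x$logA, x$logA_se, length(x$Ns)))
  invisible(x)
}

#' Two-dimensional cut of the potential in flow coordinates
#'
#' Tabulates `V(g^-1(q))` over a grid in two flow coordinates with the
#' remaining flow coordinates fixed.
#'
#' @param potential vectorized potential function.
#' @param fm a [flow_model()] or `NULL` for the identity map.
#' @param coords integer vector of the two cut coordinates.
#' @param q_fixed full-length vector of flow-coordinate values; the two cut
#'   entries are ignored.
#' @param q1,q2 grid vectors for the two cut coordinates.
#' @return data frame with columns `q1`, `q2`, `V`.
#' @export
pes_cut <- function(potential, fm, coords, q_fixed, q1, q2) {
  d <- length(q_fixed)
  gr <- expand.grid(q1 = q1, q2 = q2)
  Q <- matrix(rep(q_fixed, each = nrow(gr)), nrow(gr), d)
  Q[, coords[1]] <- gr$q1
  Q[, coords[2]] <- gr$q2
  R <- if (is.null(fm)) Q else {
    rr <- flow_inverse(fm, Q)
    if (is.matrix(rr)) rr else matrix(rr, ncol = d)
  }
  data.frame(q1 = gr$q1, q2 = gr$q2, V = potential(R))
}

#' Separability score of a potential cut
#'
#' Sum of absolute mixed second differences of `V` over the cut grid; lower
#' values indicate a more separable (less coupled) surface. Only the
#' direction of changes in this score is meaningful.
#'
#' @param cut a [pes_cut()] data frame over a regular grid.
#' @export
separability_score <- function(cut) {
  q1 <- sort(unique(cut$q1)); q2 <- sort(unique(cut$q2))
  Vm <- matrix(cut$V[order(cut$q2, cut$q1)], length(q1), length(q2))
  mix <- Vm[-1, -1] - Vm[-nrow(Vm), -1] - Vm[-1, -ncol(Vm)] + Vm[-nrow(Vm), -ncol(Vm)]
  sum(abs(mix))
}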