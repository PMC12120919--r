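# Variational optimization of the flow parameters.
#
# Loss functions derived from the variational principle: the trace of the
# Hamiltonian (sum of all energies spanned by the basis; needs only diagonal
# matrix elements because the augmented basis stays orthonormal) or the sum
# of the lowest M eigenvalues (repeated diagonalization, higher accuracy for
# the targeted states). Quadrature degrees can alternate between optimizer
# steps to prevent overfitting to a fixed grid; final energies are always
# recomputed with a larger quadrature.

#' Training configuration
#'
#' @param loss_kind `"trace"` or `"lowest_m"`.
#' @param M number of targeted states for `"lowest_m"`.
#' @param iterations optimizer iterations (default 1000).
#' @param lr Adam step size (default 1e-3).
#' @param quad_degrees list of integer vectors; the optimizer cycles through
#'   them (one per iteration, by parity) to alternate quadrature degrees.
#' @param final_degrees quadrature degrees for the final spectrum evaluation.
#' @param seed integer seed recorded in checkpoints.
#' @export
train_config <- function(loss_kind = c("lowest_m", "trace"), M = 5L,
                         iterations = 1000L, lr = 1e-3,
                         quad_degrees, final_degrees, seed = 1L) {
  loss_kind <- match.arg(loss_kind)
  stopifnot(iterations >= 1, M >= 1)
  if (!is.list(quad_degrees)) quad_degrees <- list(quad_degrees)
  structure(list(loss_kind = loss_kind, M = as.integer(M),
                 iterations = as.integer(iterations), lr = lr,
                 quad_degrees = quad_degrees,
                 final_degrees = final_degrees, seed = as.integer(seed)),
            class = "vf_train_config")
}

#' Variational loss of a Hamiltonian matrix
#'
#' Trace mode sums the diagonal (no diagonalization); `lowest_m` sums the M
#' smallest eigenvalues. A warning is issued when the states at the cut are
#' degenerate within 1e-10, where the gradient of the partial sum is
#' ill-defined.
#'
#' @param H symmetric matrix (or a `vf_hmats` object).
#' @param kind `"trace"` or `"lowest_m"`.
#' @param M subset size for `"lowest_m"`.
#' @export
hamiltonian_loss <- function(H, kind = c("trace", "lowest_m"), M = NULL) {
  kind <- match.arg(kind)
  if (inherits(H, "vf_hmats")) H <- H$T + H$V + H$U
  if (any(!is.finite(H))) vf_stop("non-finite Hamiltonian entries")
  if (kind == "trace") return(sum(diag(H)))
  stopifnot(!is.null(M), M <= nrow(H))
  ev <- sort(eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  if (M < length(ev) && abs(ev[M + 1] - ev[M]) < 1e-10)
    warning("E_M and E_{M+1} are degenerate within 1e-10; the lowest-M loss gradient is ill-defined at this crossing")
  sum(ev[seq_len(M)])
}

# Precompute everything theta-independent for one quadrature grid.
loss_context <- function(bs, rule, grid) {
  idx <- resolve_idx(bs, rule)
  bm <- basis_matrix(bs, idx, grid$Q, deriv = TRUE)
  d <- bs$ncoord
  # plain-derivative products (theta-independent: the quadrature nodes in q
  # are fixed); the theta-dependent log-det and measure terms are combined
  # per evaluation in flow_loss
  P <- rowSums(bm$B^2)
  Ca <- lapply(seq_len(d), function(a) rowSums(bm$B * bm$dB[[a]]))
  Dab <- vector("list", d)
  for (a in seq_len(d)) {
    Dab[[a]] <- vector("list", d)
    for (b in seq_len(d)) Dab[[a]][[b]] <- rowSums(bm$dB[[a]] * bm$dB[[b]])
  }
  list(idx = idx, grid = grid, bs = bs, B = bm$B, dB = bm$dB, P = P, Ca = Ca,
       Dab = Dab, d = d, cache = new.env(parent = emptyenv()))
}

# Evaluate the training loss for one context; returns a large smooth penalty
# when quadrature nodes leave the flow's output box (where the pullback is
# undefined), so the optimizer is steered back to admissible scalings.
flow_loss <- function(ctx, fm, kf, potential, tc, guard = NULL) {
  ab <- flow_scaling(fm)
  Qs <- if (is.null(guard)) ctx$grid$Q else guard
  wn <- sweep(sweep(Qs, 2, ab$b, `-`), 2, ab$a, `/`)
  excess <- pmax(abs(wn) - 0.995, 0)
  if (any(excess > 0)) return(1e8 * (1 + sum(excess)))
  fr <- augmented_frame(fm, ctx$grid, kf = kf, warm_cache = ctx$cache, ld_order = 2L)
  W <- ctx$grid$W
  v <- potential(fr$r)
  if (any(!is.finite(v))) return(1e8)
  u <- kf$U(fr$r)
  E <- fr$Bq - measure_weight_q(ctx$bs, fr)
  if (tc$loss_kind == "trace") {
    d <- ctx$d
    kin <- numeric(length(W))
    for (a in seq_len(d)) for (b in seq_len(d)) {
      kin <- kin + fr$Gbar[, a, b] *
        (ctx$Dab[[a]][[b]] + ctx$Ca[[a]] * E[, b] + ctx$Ca[[b]] * E[, a] +
           ctx$P * E[, a] * E[, b])
    }
    return(sum(W * (kin / 2 + (v + u) * ctx$P)))
  }
  # lowest_m: assemble the full matrices on this grid
  d <- ctx$d
  Dl <- vector("list", d)
  for (a in seq_len(d)) Dl[[a]] <- ctx$dB[[a]] + ctx$B * E[, a]
  N <- ncol(ctx$B)
  H <- crossprod(ctx$B, ctx$B * (W * (v + u)))
  for (a in seq_len(d)) for (b in seq_len(d)) {
    wg <- W * fr$Gbar[, a, b]
    H <- H + 0.5 * crossprod(Dl[[a]], Dl[[b]] * wg)
  }
  ev <- sort(eigen((H + t(H)) / 2, symmetric = TRUE, only.values = TRUE)$values)
  sum(ev[seq_len(min(tc$M, N))])
}

#' One-shot variational loss of a flow
#'
#' Builds the Hamiltonian on the given grid and evaluates the configured
#' loss; the trace mode uses only diagonal elements.
#'
#' @param bs,rule,grid basis, truncation and quadrature.
#' @param fm a [flow_model()] (or `NULL` for the identity map).
#' @param kf a [kinetic_field()].
#' @param potential vectorized potential function.
#' @param tc a [train_config()].
#' @export
vf_loss <- function(bs, rule, grid, fm, kf, potential, tc) {
  ctx <- loss_context(bs, rule, grid)
  if (is.null(fm)) {
    h <- build_hamiltonian(bs, NULL, kf, potential, grid, rule)
    return(hamiltonian_loss(h, tc$loss_kind, tc$M))
  }
  flow_loss(ctx, fm, kf, potential, tc)
}

#' Train the flow parameters by gradient descent
#'
#' Adam optimization of all flow parameters on the configured variational
#' loss; gradients by forward finite differences of the loss (the loss is an
#' explicit quadrature sum, smooth in the parameters). Quadrature degrees
#' alternate across iterations per the configuration; the returned spectrum
#' is recomputed at the (larger) final quadrature. The parameter vector with
#' the best observed loss is returned, so the trained loss never exceeds the
#' initial one.
#'
#' @param bs,rule basis and truncation.
#' @param kf kinetic field.
#' @param potential vectorized potential function.
#' @param fm initial [flow_model()] (typically identity-initialized).
#' @param tc a [train_config()].
#' @param verbose print per-iteration progress every `verbose` iterations
#'   (0 = silent).
#' @return list with the trained `fm`, the `state` (loss history, gradient
#'   norms, degree schedule), and the final `spectrum`.
#' @export
train_flow <- function(bs, rule, kf, potential, fm, tc, verbose = 0L) {
  set.seed(tc$seed)
  ctxs <- lapply(tc$quad_degrees, function(dg) loss_context(bs, rule, build_quadrature(bs, dg)))
  final_grid <- build_quadrature(bs, tc$final_degrees)
  # box guard: per-coordinate extreme nodes over all grids incl. final
  guard <- do.call(rbind, lapply(c(lapply(ctxs, function(x) x$grid), list(final_grid)),
                                 function(g) {
                                   lo <- vapply(g$nodes, min, numeric(1))
                                   hi <- vapply(g$nodes, max, numeric(1))
                                   rbind(lo, hi)
                                 }))
  theta <- flow_get_params(fm)
  P <- length(theta)
  m <- v <- numeric(P)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  history <- numeric(tc$iterations)
  gnorm <- numeric(tc$iterations)
  best <- list(loss = Inf, theta = theta)
  fm_cur <- fm
  for (it in seq_len(tc$iterations)) {
    ctx <- ctxs[[(it - 1L) %% length(ctxs) + 1L]]
    f0 <- flow_loss(ctx, fm_cur, kf, potential, tc, guard = guard)
    if (!is.finite(f0))
      vf_stop("non-finite loss at iteration %d; aborting (last finite loss %.6g)",
              it, if (it > 1) history[it - 1] else NA_real_)
    history[it] <- f0
    if (f0 < best$loss) { best$loss <- f0; best$theta <- theta }
    g <- numeric(P)
    for (p in seq_len(P)) {
      h <- 1e-6 * (1 + abs(theta[p]))
      thp <- theta; thp[p] <- theta[p] + h
      fp <- flow_loss(ctx, flow_set_params(fm_cur, thp), kf, potential, tc, guard = guard)
      g[p] <- (fp - f0) / h
    }
    if (any(!is.finite(g)))
      vf_stop("non-finite gradient at iteration %d; aborting", it)
    gnorm[it] <- sqrt(sum(g^2))
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^it)
    vhat <- v / (1 - beta2^it)
    theta <- theta - tc$lr * mhat / (sqrt(vhat) + eps)
    fm_cur <- flow_set_params(fm_cur, theta)
    if (verbose > 0 && (it %% verbose == 0L))
      message(sprintf("iter %4d  loss %.8g  |g| %.3g  degrees %s",
                      it, f0, gnorm[it], paste(ctx$grid$degrees, collapse = "x")))
  }
  # evaluate both the final iterate and the best-seen iterate on the last
  # context and keep the better
  ctx <- ctxs[[length(ctxs)]]
  f_final <- flow_loss(ctx, fm_cur, kf, potential, tc, guard = guard)
  f_best <- flow_loss(ctx, flow_set_params(fm, best$theta), kf, potential, tc, guard = guard)
  if (f_best < f_final) fm_cur <- flow_set_params(fm_cur, best$theta)
  h <- build_hamiltonian(bs, fm_cur, kf, potential, final_grid, rule)
  spectrum <- solve_spectrum(h)
  state <- structure(list(iteration = tc$iterations,
                          loss_history = c(history, min(f_final, f_best)),
                          grad_norm = gnorm,
                          final_loss = min(f_final, f_best),
                          degrees_cycle = tc$quad_degrees),
                     class = "vf_train_state")
  list(fm = fm_cur, state = state, spectrum = spectrum)
}

#' @export
print.vf_train_state <- function(x, ...) {
  cat(sprintf("<vf_train_state> %d iteration(s); loss %.8g -> %.8g\n",
              x$iteration, x$loss_history[1], x$final_loss))
  invisible(x)
}
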