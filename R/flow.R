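# Invertible, domain-bounded residual flow q = g(r).
#
# Architecture (fixed prescale -> residual blocks -> tanh wrapper ->
# interval-constrained affine scaling with trainable pair (a, b)):
#
#   u_i = artanh(c_i * t_i(r_i)) / s_i   (t_i affine over the node span)
#   z   = u + f_1(u) + ... (residual blocks, each Lipschitz < 1)
#   q_i = scale_i( tanh( inner_i(z_i) ) )
#
# For unbounded (infinite / semi-infinite) coordinates inner_i is the
# identity and scale_i(w) = a_i(alpha_i) w + b_i(beta_i) with the
# subparametrization keeping [b - a, b + a] inside the physical domain; the
# map covers a wide slab around the quadrature nodes, beyond which the
# decaying basis carries no weight. For finite coordinates the output must
# cover the whole interval (angular bases do not decay at the interval
# edges), so the trainable affine pair acts before the wrapper,
# inner_i(z) = a_i z + b_i, and scale_i is the fixed affine bijection of
# (-1, 1) onto the full domain. In both cases, with zero residual blocks
# the composite is exactly affine in the prescale variable, so identity
# initialization is exact.

KAPPA <- tanh(1)

# ---- constructor ---------------------------------------------------------

#' Construct a normalizing-flow model over a coordinate system
#'
#' @param grid a [build_quadrature()] grid; its per-coordinate node span
#'   defines the fixed prescale (the outermost quadrature nodes map to the
#'   edges of the wrapper's reference interval). Build the flow on the
#'   largest quadrature it will ever be evaluated with, so that all node
#'   pullbacks are defined.
#' @param domains list of [coordinate_domain()] objects, one per coordinate.
#' @param n_blocks number of invertible residual blocks (default 10).
#' @param hidden integer vector of hidden-layer widths in each block
#'   (default `c(8, 8)`).
#' @param lipschitz target Lipschitz bound of each block, `< 1`; enforced by
#'   exact spectral normalization of every weight matrix.
#' @param init `"identity"` (zero block outputs, scaling inverting the
#'   prescale) or `"random"`.
#' @param init_sd standard deviation for `"random"` initial weights.
#' @param seed optional integer seed for the random weight draw.
#' @return an object of class `vf_flow`.
#' @export
flow_model <- function(grid, domains, n_blocks = 10L, hidden = c(8L, 8L),
                       lipschitz = 0.9, init = c("identity", "random"),
                       init_sd = 0.1, seed = NULL) {
  init <- match.arg(init)
  d <- grid$ncoord
  stopifnot(length(domains) == d, lipschitz > 0, lipschitz < 1)
  mid <- half <- cmar <- s0 <- lower <- upper <- numeric(d)
  kind <- character(d)
  for (i in seq_len(d)) {
    dom <- domains[[i]]
    stopifnot(inherits(dom, "vf_domain"))
    nd <- grid$nodes[[i]]
    kind[i] <- dom$kind
    lower[i] <- dom$lower
    upper[i] <- dom$upper
    if (min(nd) <= dom$lower || max(nd) >= dom$upper)
      vf_stop("quadrature nodes of coordinate %d fall outside its domain", i)
    if (dom$kind == "finite") {
      # prescale over the whole interval; s0 sends the outermost node to 1
      mid[i] <- (dom$lower + dom$upper) / 2
      half[i] <- (dom$upper - dom$lower) / 2
      cmar[i] <- 1
      tmax <- max(abs((nd - mid[i]) / half[i]))
      s0[i] <- atanh(tmax)
    } else {
      nmid <- (min(nd) + max(nd)) / 2
      nhalf <- (max(nd) - min(nd)) / 2
      if (nhalf <= 0) vf_stop("degenerate quadrature node span for coordinate %d", i)
      mid[i] <- nmid
      half[i] <- nhalf
      s0[i] <- 1
      margin <- min(nmid - dom$lower, dom$upper - nmid)
      if (dom$kind == "infinite") {
        cmar[i] <- KAPPA
      } else {
        cc <- max(KAPPA, 1.02 * nhalf / margin)
        if (cc > 0.999) cc <- 0.999
        if (nhalf / cc >= margin)
          vf_stop("quadrature nodes of coordinate %d leave no room inside its domain [%g, %g]",
                  i, dom$lower, dom$upper)
        cmar[i] <- cc
      }
    }
  }
  if (!is.null(seed)) set.seed(seed)
  hidden <- as.integer(hidden)
  blocks <- vector("list", n_blocks)
  for (s in seq_len(n_blocks)) {
    W1 <- matrix(stats::rnorm(hidden[1] * d, 0, 1 / sqrt(d)), hidden[1], d)
    W2 <- matrix(stats::rnorm(hidden[2] * hidden[1], 0, 1 / sqrt(hidden[1])), hidden[2], hidden[1])
    if (init == "identity") {
      W3 <- matrix(0, d, hidden[2])
    } else {
      W3 <- matrix(stats::rnorm(d * hidden[2], 0, init_sd / sqrt(hidden[2])), d, hidden[2])
    }
    blocks[[s]] <- list(W1 = W1, b1 = numeric(hidden[1]),
                        W2 = W2, b2 = numeric(hidden[2]),
                        W3 = W3, b3 = numeric(d))
  }
  a0 <- half / cmar
  alpha <- beta <- numeric(d)
  for (i in seq_len(d)) {
    if (kind[i] == "infinite") {
      alpha[i] <- inv_softplus(a0[i]); beta[i] <- mid[i]
    } else if (kind[i] == "semi_infinite") {
      alpha[i] <- inv_softplus(a0[i])
      beta[i] <- inv_softplus(mid[i] - lower[i] - a0[i])
    } else {
      # inner affine: a = softplus(alpha) undoes the s0 normalization
      alpha[i] <- inv_softplus(s0[i])
      beta[i] <- 0
    }
  }
  fm <- structure(list(d = d, mid = mid, half = half, cmar = cmar, s0 = s0,
                       kind = kind, lower = lower, upper = upper,
                       blocks = blocks, alpha = alpha, beta = beta,
                       n_blocks = as.integer(n_blocks), hidden = hidden,
                       lipschitz = lipschitz, boundary = "error",
                       inv_tol = 1e-12, inv_maxit = 100L),
                  class = "vf_flow")
  flow_prepare(fm)
}

#' @export
print.vf_flow <- function(x, ...) {
  cat(sprintf("<vf_flow> %d coordinate(s), %d residual block(s), hidden [%s], Lipschitz <= %g\n",
              x$d, x$n_blocks, paste(x$hidden, collapse = ", "), x$lipschitz))
  ab <- flow_scaling(x)
  for (i in seq_len(x$d))
    cat(sprintf("  [%d] %s  output box [%.6g, %.6g]\n", i, x$kind[i],
                ab$b[i] - ab$a[i], ab$b[i] + ab$a[i]))
  invisible(x)
}

# exact spectral norm; matrices are tiny so svd is cheap and exact
spec_norm <- function(W) if (all(W == 0)) 0 else svd(W, nu = 0, nv = 0)$d[1]

# Normalize every weight matrix to spectral norm <= lipschitz^(1/3) so the
# block's Lipschitz constant is bounded by `lipschitz` (tanh is 1-Lipschitz).
# Also caches the node-independent coefficient tensor used by the batched
# block-Jacobian assembly: C[(q-1)*d + p][i, j] = W3[p,i] W2[i,j] W1[j,q],
# stored column-bound as an h2 x (h1 * d^2) matrix.
flow_prepare <- function(fm) {
  s_target <- fm$lipschitz^(1 / 3)
  d <- fm$d
  for (s in seq_along(fm$blocks)) {
    bl <- fm$blocks[[s]]
    for (nm in c("W1", "W2", "W3")) {
      W <- bl[[nm]]
      # Frobenius norm bounds the spectral norm; svd only when it may exceed
      sn <- sqrt(sum(W^2))
      if (sn > s_target) sn <- spec_norm(W)
      bl[[paste0(nm, "n")]] <- if (sn > s_target) W * (s_target / sn) else W
    }
    h1 <- length(bl$b1); h2 <- length(bl$b2)
    Cb <- matrix(0, h2, h1 * d * d)
    for (q in seq_len(d)) for (p in seq_len(d)) {
      Cb[, ((q - 1L) * d + p - 1L) * h1 + seq_len(h1)] <-
        bl$W3n[p, ] * bl$W2n * rep(bl$W1n[, q], each = h2)
    }
    bl$Cb <- Cb
    fm$blocks[[s]] <- bl
  }
  fm
}

# trainable scaling from the interval-specific subparametrization.
# (a, b): outer affine applied after tanh (the output box is [b-a, b+a]);
# (ai, bi): inner affine applied before tanh (finite coordinates only, where
# the outer affine is the fixed bijection onto the full interval).
flow_scaling <- function(fm) {
  a <- b <- numeric(fm$d)
  ai <- rep(1, fm$d)
  bi <- numeric(fm$d)
  for (i in seq_len(fm$d)) {
    if (fm$kind[i] == "infinite") {
      a[i] <- softplus(fm$alpha[i]); b[i] <- fm$beta[i]
    } else if (fm$kind[i] == "semi_infinite") {
      a[i] <- softplus(fm$alpha[i])
      b[i] <- fm$lower[i] + a[i] + softplus(fm$beta[i])
    } else {
      a[i] <- fm$half[i]
      b[i] <- fm$mid[i]
      ai[i] <- softplus(fm$alpha[i])
      bi[i] <- fm$beta[i]
    }
  }
  list(a = a, b = b, ai = ai, bi = bi)
}

# ---- forward pass --------------------------------------------------------

flow_check_domain <- function(fm, R) {
  for (i in seq_len(fm$d)) {
    t <- (R[, i] - fm$mid[i]) / fm$half[i]
    bad <- abs(fm$cmar[i] * t) >= 1 | R[, i] <= fm$lower[i] | R[, i] >= fm$upper[i]
    if (any(bad)) {
      lo <- fm$mid[i] - fm$half[i] / fm$cmar[i]
      hi <- fm$mid[i] + fm$half[i] / fm$cmar[i]
      vf_stop("coordinate %d: %d point(s) outside the flow domain (%.6g, %.6g)",
              i, sum(bad), max(lo, fm$lower[i]), min(hi, fm$upper[i]))
    }
  }
  invisible(TRUE)
}

addrow <- function(M, v) M + rep(v, each = nrow(M))

# evaluate one residual block (K x h matrices); returns value and, if jac,
# the per-point Jacobian array (K, d, d):
# J = W3 diag(1-H2^2) W2 diag(1-H1^2) W1 batched over points via the cached
# coefficient tensor Cb (one matmul + d^2 weighted row sums).
block_eval <- function(bl, Z, jac = FALSE) {
  H1 <- tanh(addrow(Z %*% t(bl$W1n), bl$b1))
  H2 <- tanh(addrow(H1 %*% t(bl$W2n), bl$b2))
  F <- addrow(H2 %*% t(bl$W3n), bl$b3)
  if (!jac) return(list(F = F))
  K <- nrow(Z); d <- ncol(Z)
  d1 <- 1 - H1^2
  d2 <- 1 - H2^2
  h1 <- ncol(H1)
  tmp <- d2 %*% bl$Cb                       # K x (h1 * d^2)
  J <- array(0, c(K, d, d))
  for (q in seq_len(d)) for (p in seq_len(d)) {
    colsel <- ((q - 1L) * d + p - 1L) * h1 + seq_len(h1)
    J[, p, q] <- rowSums(tmp[, colsel, drop = FALSE] * d1)
  }
  list(F = F, J = J)
}

# full forward pass with optional exact Jacobian/log-determinant
flow_forward_full <- function(fm, R, jac = FALSE) {
  R <- as.matrix(R)
  flow_check_domain(fm, R)
  K <- nrow(R); d <- fm$d
  Tm <- addrow(R, -fm$mid) / rep(fm$half, each = K)
  CT <- Tm * rep(fm$cmar, each = K)
  U <- atanh(CT) / rep(fm$s0, each = K)
  du <- (1 / (1 - CT^2)) * rep(fm$cmar / (fm$half * fm$s0), each = K)  # du_i/dr_i > 0
  Z <- U
  if (jac) {
    JR <- array(0, c(K, d, d))
    for (i in seq_len(d)) JR[, i, i] <- 1
    logdetR <- numeric(K)
  }
  for (bl in fm$blocks) {
    be <- block_eval(bl, Z, jac = jac)
    if (jac) {
      Istep <- be$J
      for (i in seq_len(d)) Istep[, i, i] <- Istep[, i, i] + 1
      logdetR <- logdetR + log(bdet(Istep))
      JR <- bmm(Istep, JR)
    }
    Z <- Z + be$F
  }
  ab <- flow_scaling(fm)
  Zeff <- addrow(Z * rep(ab$ai, each = K), ab$bi)
  Wr <- tanh(Zeff)
  Qm <- addrow(Wr * rep(ab$a, each = K), ab$b)
  out <- list(q = Qm, u = U, z = Z, w = Wr, a = ab$a, b = ab$b)
  if (jac) {
    pre <- (1 - Wr^2) * rep(ab$a * ab$ai, each = K)   # dq_i/dz_i
    J <- JR
    for (i in seq_len(d)) for (l in seq_len(d)) J[, i, l] <- pre[, i] * JR[, i, l] * du[, l]
    out$J <- J
    out$logdet <- rowSums(log(pre)) + logdetR + rowSums(log(du))
  }
  out
}

#' Apply the flow map
#'
#' @param fm a [flow_model()].
#' @param r numeric vector (one point) or matrix (points in rows).
#' @return the transformed coordinates `q`, same shape as the input.
#' @export
flow_forward <- function(fm, r) {
  R <- if (is.matrix(r)) r else matrix(r, ncol = fm$d)
  q <- flow_forward_full(fm, R)$q
  if (is.matrix(r)) q else drop(q)
}

#' Jacobian and log-determinant of the flow map
#'
#' The full n x n Jacobian is computed exactly by the chain rule through the
#' architecture (no stochastic estimators); the log-determinant is the sum of
#' the positive per-stage contributions, so it is finite on the open domain.
#'
#' @inheritParams flow_forward
#' @return list with `q` (mapped points), `J` (K x n x n Jacobian array),
#'   `logdet` (length-K vector) and `D = exp(-logdet)`, the inverse Jacobian
#'   determinant magnitude.
#' @export
flow_jacobian <- function(fm, r) {
  R <- if (is.matrix(r)) r else matrix(r, ncol = fm$d)
  fw <- flow_forward_full(fm, R, jac = TRUE)
  list(q = fw$q, J = fw$J, logdet = fw$logdet, D = exp(-fw$logdet))
}

# ---- inverse -------------------------------------------------------------

# invert one residual block: solve z + f(z) = y by a Newton iteration with a
# Banach (Picard) fallback; vectorized over points
block_invert <- function(fm, bl, Y, Z0 = NULL) {
  Z <- if (!is.null(Z0) && all(dim(Z0) == dim(Y))) Z0 else Y
  for (it in seq_len(fm$inv_maxit)) {
    be <- block_eval(bl, Z, jac = TRUE)
    Res <- Z + be$F - Y
    rn <- max(abs(Res))
    if (rn < fm$inv_tol) return(Z)
    A <- be$J
    for (i in seq_len(ncol(Y))) A[, i, i] <- A[, i, i] + 1
    step <- tryCatch(bmv(binv(A), Res), error = function(e) Res)
    Z <- Z - step
  }
  be <- block_eval(bl, Z)
  rn <- max(abs(Z + be$F - Y))
  if (rn >= fm$inv_tol)
    vf_stop("block inversion did not converge within %d iterations (residual %.3e)",
            fm$inv_maxit, rn)
  Z
}

#' Invert the flow map
#'
#' The scaling, wrapper and prescale stages are inverted in closed form;
#' each residual block is inverted by a (Newton-accelerated) fixed-point
#' iteration, which converges because every block is a contraction.
#'
#' @inheritParams flow_forward
#' @param q points in the flow's output box.
#' @param warm_cache optional environment carrying block-space iterates from
#'   a previous call at nearby parameters (warm start for the fixed-point
#'   solves; used by the training loop).
#' @return the preimage points `r`, same shape as the input.
#' @export
flow_inverse <- function(fm, q, warm_cache = NULL) {
  Qm <- if (is.matrix(q)) q else matrix(q, ncol = fm$d)
  ab <- flow_scaling(fm)
  Wr <- sweep(sweep(Qm, 2, ab$b, `-`), 2, ab$a, `/`)
  out_of_box <- abs(Wr) >= 1
  if (any(out_of_box)) {
    if (fm$boundary == "clamp") {
      Wr[out_of_box] <- sign(Wr[out_of_box]) * (1 - 1e-12)
    } else {
      i <- which(out_of_box, arr.ind = TRUE)[1, 2]
      vf_stop("coordinate %d: point outside the flow output box [%.6g, %.6g]",
              i, ab$b[i] - ab$a[i], ab$b[i] + ab$a[i])
    }
  }
  Z <- addrow(atanh(Wr), -ab$bi) / rep(ab$ai, each = nrow(Wr))
  nb <- length(fm$blocks)
  Zs <- vector("list", nb)
  for (s in rev(seq_len(nb))) {
    Z <- block_invert(fm, fm$blocks[[s]], Z,
                      Z0 = if (!is.null(warm_cache)) warm_cache$Zs[[s]] else NULL)
    Zs[[s]] <- Z
  }
  if (!is.null(warm_cache)) warm_cache$Zs <- Zs
  Tm <- tanh(Z * rep(fm$s0, each = nrow(Z))) / rep(fm$cmar, each = nrow(Z))
  R <- addrow(Tm * rep(fm$half, each = nrow(Z)), fm$mid)
  if (is.matrix(q)) R else drop(R)
}

# ---- log-det gradient (used by the kinetic-energy assembly) --------------

# d(logdet)/dr at points R: central differences of the analytic
# log-determinant (the only second-derivative quantity of the flow needed).
# order 4 is used for final matrix assembly, order 2 inside training loops.
# Steps shrink adaptively near the edge of the effective domain so the
# probes stay admissible even when the flow pulls nodes close to it.
flow_logdet_grad <- function(fm, R, h = 1e-4, order = 4L) {
  f <- function(X) flow_forward_full(fm, X, jac = TRUE)$logdet
  R <- as.matrix(R)
  n <- ncol(R)
  reach <- if (order >= 4L) 2.2 else 1.1
  g <- matrix(0, nrow(R), n)
  for (j in seq_len(n)) {
    lo <- max(fm$mid[j] - fm$half[j] / fm$cmar[j], fm$lower[j])
    hi <- min(fm$mid[j] + fm$half[j] / fm$cmar[j], fm$upper[j])
    hp <- pmin(h * (1 + abs(R[, j])),
               (R[, j] - lo) / reach, (hi - R[, j]) / reach)
    rp1 <- R; rp1[, j] <- R[, j] + hp
    rm1 <- R; rm1[, j] <- R[, j] - hp
    if (order >= 4L) {
      rp2 <- R; rp2[, j] <- R[, j] + 2 * hp
      rm2 <- R; rm2[, j] <- R[, j] - 2 * hp
      g[, j] <- (-f(rp2) + 8 * f(rp1) - 8 * f(rm1) + f(rm2)) / (12 * hp)
    } else {
      g[, j] <- (f(rp1) - f(rm1)) / (2 * hp)
    }
  }
  g
}

# ---- parameter vector ----------------------------------------------------

#' @rdname flow_params
#' @export
flow_get_params <- function(fm) {
  th <- numeric(0)
  for (bl in fm$blocks)
    th <- c(th, bl$W1, bl$b1, bl$W2, bl$b2, bl$W3, bl$b3)
  c(th, fm$alpha, fm$beta)
}

#' Get or set the trainable parameters of a flow as a flat vector
#'
#' Ordering: for each residual block `W1, b1, W2, b2, W3, b3`
#' (column-major), then the scaling parameters `alpha` and `beta`.
#' Setting re-applies spectral normalization.
#'
#' @param fm a [flow_model()].
#' @param theta numeric parameter vector from [flow_get_params()].
#' @name flow_params
#' @export
flow_set_params <- function(fm, theta) {
  pos <- 1L
  take <- function(k) {
    v <- theta[pos:(pos + k - 1L)]
    pos <<- pos + k
    v
  }
  for (s in seq_along(fm$blocks)) {
    bl <- fm$blocks[[s]]
    for (nm in c("W1", "b1", "W2", "b2", "W3", "b3")) {
      obj <- bl[[nm]]
      v <- take(length(obj))
      bl[[nm]] <- if (is.matrix(obj)) matrix(v, nrow(obj), ncol(obj)) else v
    }
    fm$blocks[[s]] <- bl
  }
  fm$alpha <- take(fm$d)
  fm$beta <- take(fm$d)
  if (pos != length(theta) + 1L) vf_stop("parameter vector has wrong length")
  flow_prepare(fm)
}

#' Randomly perturb the trainable parameters of a flow
#'
#' Draws Gaussian perturbations of the block weights (and, optionally, small
#' perturbations of the scaling parameters) around the current values;
#' useful for property tests over arbitrary admissible flows.
#'
#' @param fm a [flow_model()].
#' @param sd weight perturbation standard deviation.
#' @param sd_scaling perturbation standard deviation of `alpha`/`beta`.
#' @param seed optional seed.
#' @export
flow_randomize <- function(fm, sd = 0.2, sd_scaling = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (s in seq_along(fm$blocks)) {
    bl <- fm$blocks[[s]]
    for (nm in c("W1", "b1", "W2", "b2", "W3", "b3"))
      bl[[nm]] <- bl[[nm]] + stats::rnorm(length(bl[[nm]]), 0, sd)
    fm$blocks[[s]] <- bl
  }
  fm$alpha <- fm$alpha + stats::rnorm(fm$d, 0, sd_scaling)
  fm$beta <- fm$beta + stats::rnorm(fm$d, 0, sd_scaling)
  flow_prepare(fm)
}
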