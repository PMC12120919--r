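# Shared fixtures and independent oracles used across the test files.

# 1D harmonic fixture: basis, quadrature, identity-initialized small flow
fixture_1d <- function(nmax = 9L, degree = 40L, n_blocks = 2L,
                       hidden = c(4L, 4L), seed = 1L) {
  p <- make_problem("harmonic_1d")
  bs <- p$bs
  bs$nmax <- nmax
  rule <- truncation_rule(1L, nmax)
  grid <- build_quadrature(bs, degree)
  fm <- flow_model(grid, p$domains, n_blocks = n_blocks, hidden = hidden,
                   seed = seed)
  list(p = p, bs = bs, rule = rule, grid = grid, fm = fm)
}

# dense r-space oracle for the Hamiltonian blocks: 4th-order central
# derivatives of the augmented functions on a uniform grid, Simpson weights.
# Independent of the q-space quadrature assembly.
rspace_oracle_1d <- function(bs, fm, kf, potential, rule, npts = 8001L,
                             frac = 0.999) {
  lo <- fm$mid - frac * fm$half / fm$cmar
  hi <- fm$mid + frac * fm$half / fm$cmar
  xs <- matrix(seq(lo, hi, length.out = npts), ncol = 1)
  h <- xs[2] - xs[1]
  idx <- enumerate_basis(rule)
  G <- eval_augmented(bs, fm, idx, xs)
  i <- 3:(npts - 2)
  dG <- (-G[i + 2, ] + 8 * G[i + 1, ] - 8 * G[i - 1, ] + G[i - 2, ]) / (12 * h)
  Gi <- G[i, , drop = FALSE]
  Ri <- xs[i, , drop = FALSE]
  m <- length(i)
  if (m %% 2 == 0) { m <- m - 1L; dG <- dG[1:m, ]; Gi <- Gi[1:m, ]; Ri <- Ri[1:m, , drop = FALSE] }
  sw <- rep(c(2, 4), length.out = m); sw[1] <- 1; sw[m] <- 1
  sw <- sw * h / 3
  gb <- kf$G_batch(Ri)[, 1, 1]
  list(T = 0.5 * crossprod(dG, dG * (gb * sw)),
       V = crossprod(Gi, Gi * (potential(Ri) * sw)),
       S = crossprod(Gi, Gi * sw))
}

# 2D analogue on a tensor grid (x1 varies fastest in all flattened arrays)
rspace_oracle_2d <- function(bs, fm, kf, potential, rule, npts = 441L,
                             frac = 0.995) {
  lo <- fm$mid - frac * fm$half / fm$cmar
  hi <- fm$mid + frac * fm$half / fm$cmar
  xs1 <- seq(lo[1], hi[1], length.out = npts)
  xs2 <- seq(lo[2], hi[2], length.out = npts)
  h1 <- xs1[2] - xs1[1]; h2 <- xs2[2] - xs2[1]
  R <- as.matrix(expand.grid(x1 = xs1, x2 = xs2))
  idx <- enumerate_basis(rule)
  G <- eval_augmented(bs, fm, idx, R)
  N <- ncol(G)
  arrs <- array(G, c(npts, npts, N))
  m <- npts - 4L
  if (m %% 2 == 0) m <- m - 1L
  ii <- 3:(2L + m)                        # interior indices kept
  d1 <- (-arrs[ii + 2, ii, , drop = FALSE] + 8 * arrs[ii + 1, ii, , drop = FALSE] -
           8 * arrs[ii - 1, ii, , drop = FALSE] + arrs[ii - 2, ii, , drop = FALSE]) / (12 * h1)
  d2 <- (-arrs[ii, ii + 2, , drop = FALSE] + 8 * arrs[ii, ii + 1, , drop = FALSE] -
           8 * arrs[ii, ii - 1, , drop = FALSE] + arrs[ii, ii - 2, , drop = FALSE]) / (12 * h2)
  Gs <- arrs[ii, ii, , drop = FALSE]
  simp <- function(k) { s <- rep(c(2, 4), length.out = k); s[1] <- 1; s[k] <- 1; s / 3 }
  wv <- as.vector(outer(simp(m) * h1, simp(m) * h2))
  Rsub <- as.matrix(expand.grid(x1 = xs1[ii], x2 = xs2[ii]))
  gb <- kf$G_batch(Rsub)
  flat <- function(A) matrix(A, m * m, N)
  F1 <- flat(d1); F2 <- flat(d2); F0 <- flat(Gs)
  Tm <- 0.5 * (crossprod(F1, F1 * (gb[, 1, 1] * wv)) +
               crossprod(F2, F2 * (gb[, 2, 2] * wv)) +
               crossprod(F1, F2 * (gb[, 1, 2] * wv)) +
               crossprod(F2, F1 * (gb[, 1, 2] * wv)))
  Vm <- crossprod(F0, F0 * (potential(Rsub) * wv))
  list(T = Tm, V = Vm)
}

# quick random flow around identity with safe scaling perturbations
random_flow <- function(fm, sd = 0.2, sd_scaling = 0.03, seed = NULL) {
  flow_randomize(fm, sd = sd, sd_scaling = sd_scaling, seed = seed)
}
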