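test_that("identity initialization reproduces the input coordinates exactly", {
  fx <- fixture_1d()
  r <- matrix(seq(-3, 3, length.out = 21), ncol = 1)
  expect_lt(max(abs(flow_forward(fx$fm, r) - r)), 1e-13)
  expect_lt(max(abs(flow_jacobian(fx$fm, r)$logdet)), 1e-13)
  # mixed finite/infinite 2D case
  p <- make_problem("bender_2d")
  bsp <- p$bs; bsp$nmax <- c(8L, 12L)
  g <- build_quadrature(bsp, c(16L, 20L))
  fm <- flow_model(g, p$domains, n_blocks = 2L, hidden = c(4L, 4L), seed = 2)
  R <- cbind(seq(-0.8, 0.8, length.out = 9), seq(0.5, pi - 0.5, length.out = 9))
  expect_lt(max(abs(flow_forward(fm, R) - R)), 1e-12)
})

test_that("the output range never leaves the physical domain", {
  p <- make_problem("bender_2d")
  bsp <- p$bs; bsp$nmax <- c(8L, 12L)
  g <- build_quadrature(bsp, c(16L, 20L))
  for (seed in 1:8) {
    fm <- random_flow(flow_model(g, p$domains, n_blocks = 2L, hidden = c(4L, 4L), seed = seed),
                      sd = 0.5, sd_scaling = 0.5, seed = seed + 100)
    # extreme admissible inputs: just inside the effective slab
    lo <- pmax(fm$mid - 0.9999 * fm$half / fm$cmar, fm$lower + 1e-12)
    hi <- pmin(fm$mid + 0.9999 * fm$half / fm$cmar, fm$upper - 1e-12)
    R <- rbind(lo, hi, (lo + hi) / 2)
    q <- flow_forward(fm, R)
    expect_true(all(q[, 2] > 0 & q[, 2] < pi))
    ab <- vibflow:::flow_scaling(fm)
    expect_true(all(ab$b - ab$a >= fm$lower - 1e-12))
    expect_true(all(ab$b + ab$a <= fm$upper + 1e-12))
  }
})

test_that("the forward map equals the explicit stage-by-stage composition", {
  fx <- fixture_1d()
  fm <- random_flow(fx$fm, sd = 0.3, seed = 9)
  r <- matrix(seq(-2.5, 2.5, length.out = 11), ncol = 1)
  # stage 1: prescale u = artanh(c (r - mid)/half)
  u <- atanh(fm$cmar * (r - fm$mid) / fm$half)
  # stage 2: residual blocks
  z <- u
  for (bl in fm$blocks) {
    h1 <- tanh(sweep(z %*% t(bl$W1n), 2, bl$b1, `+`))
    h2 <- tanh(sweep(h1 %*% t(bl$W2n), 2, bl$b2, `+`))
    z <- z + sweep(h2 %*% t(bl$W3n), 2, bl$b3, `+`)
  }
  # stages 3-4: tanh wrapper and scaling
  ab <- vibflow:::flow_scaling(fm)
  q_manual <- ab$a * tanh(z) + ab$b
  expect_lt(max(abs(flow_forward(fm, r) - q_manual)), 1e-12)
})

test_that("forward/inverse round trips are exact over many parameter draws", {
  fx <- fixture_1d()
  p2 <- make_problem("coupled_harmonic_2d")
  bs2 <- p2$bs; bs2$nmax <- c(9L, 9L)
  g2 <- build_quadrature(bs2, c(20L, 20L))
  fm2_base <- flow_model(g2, p2$domains, n_blocks = 2L, hidden = c(4L, 4L), seed = 3)
  worst <- 0
  for (seed in 1:25) {
    fm1 <- random_flow(fx$fm, sd = 0.4, seed = seed)
    r <- matrix(seq(-2.8, 2.8, length.out = 20), ncol = 1)
    worst <- max(worst, max(abs(flow_inverse(fm1, flow_forward(fm1, r)) - r)))
    fm2 <- random_flow(fm2_base, sd = 0.3, seed = seed + 50)
    R <- matrix(runif(40, -1.5, 1.5), ncol = 2)
    Q <- flow_forward(fm2, R)
    worst <- max(worst, max(abs(flow_inverse(fm2, Q) - R)))
    worst <- max(worst, max(abs(flow_forward(fm2, flow_inverse(fm2, Q)) - Q)))
  }
  expect_lt(worst, 1e-8)
})

test_that("1D flows are strictly increasing for admissible parameters", {
  fx <- fixture_1d()
  r <- matrix(seq(-3.2, 3.2, length.out = 101), ncol = 1)
  for (seed in 1:10) {
    fm <- random_flow(fx$fm, sd = 0.6, sd_scaling = 0.3, seed = seed)
    fj <- flow_jacobian(fm, r)
    expect_true(all(fj$J[, 1, 1] > 0))
    expect_true(all(diff(drop(fj$q)) > 0))
  }
})

test_that("Jacobian log-determinants match finite differences and affine closed forms", {
  fx <- fixture_1d()
  fm <- random_flow(fx$fm, sd = 0.3, seed = 17)
  r <- matrix(seq(-2, 2, length.out = 9), ncol = 1)
  fj <- flow_jacobian(fm, r)
  h <- 1e-6
  num <- (flow_forward(fm, r + h) - flow_forward(fm, r - h)) / (2 * h)
  expect_lt(max(abs(fj$J[, 1, 1] - num)), 1e-6)
  expect_equal(fj$D, exp(-fj$logdet), tolerance = 1e-14)
  # pure affine map q = 2 r (+ const): double the scaling amplitude
  fm_aff <- fx$fm
  fm_aff$alpha <- vibflow:::inv_softplus(2 * softplus(fx$fm$alpha))
  fm_aff <- vibflow:::flow_prepare(fm_aff)
  fj_aff <- flow_jacobian(fm_aff, r)
  expect_equal(fj_aff$logdet, rep(log(2), nrow(r)), tolerance = 1e-12)
})

test_that("logdet is smooth in the parameters (finite-difference consistency)", {
  fx <- fixture_1d()
  fm <- random_flow(fx$fm, sd = 0.2, seed = 23)
  th <- flow_get_params(fm)
  r <- matrix(c(-1.2, 0.4, 1.7), ncol = 1)
  set.seed(1)
  dir <- rnorm(length(th)); dir <- dir / sqrt(sum(dir^2))
  gd <- function(h) {
    fp <- flow_set_params(fm, th + h * dir)
    fmm <- flow_set_params(fm, th - h * dir)
    (flow_jacobian(fp, r)$logdet - flow_jacobian(fmm, r)$logdet) / (2 * h)
  }
  g1 <- gd(1e-4); g2 <- gd(5e-5)
  expect_lt(max(abs(g1 - g2)) / max(abs(g2), 1e-8), 1e-5)
})

test_that("points outside the domain or output box raise informative errors", {
  fx <- fixture_1d()
  hi <- fx$fm$mid + 1.01 * fx$fm$half / fx$fm$cmar
  expect_error(flow_forward(fx$fm, matrix(hi, 1, 1)), "outside the flow domain")
  ab <- vibflow:::flow_scaling(fx$fm)
  expect_error(flow_inverse(fx$fm, matrix(ab$b + ab$a * 1.0001, 1, 1)),
               "output box")
  fm_cl <- fx$fm; fm_cl$boundary <- "clamp"
  r <- flow_inverse(fm_cl, matrix(ab$b + ab$a * 1.0001, 1, 1))
  expect_true(is.finite(r))
})

test_that("residual blocks respect the spectral Lipschitz bound", {
  fx <- fixture_1d(n_blocks = 3L)
  fm <- flow_randomize(fx$fm, sd = 5, seed = 31)   # large weights, must be clipped
  for (bl in fm$blocks) {
    lip <- vibflow:::spec_norm(bl$W1n) * vibflow:::spec_norm(bl$W2n) *
      vibflow:::spec_norm(bl$W3n)
    expect_lte(lip, fm$lipschitz + 1e-12)
  }
  # inverse still converges at the Lipschitz limit
  r <- matrix(seq(-2, 2, length.out = 11), ncol = 1)
  expect_lt(max(abs(flow_inverse(fm, flow_forward(fm, r)) - r)), 1e-9)
})

test_that("checkpoints round-trip the flow losslessly", {
  fx <- fixture_1d()
  fm <- random_flow(fx$fm, sd = 0.3, seed = 41)
  path <- tempfile(fileext = ".json")
  vf_save_checkpoint(fm, path, meta = list(seed = 7))
  fm2 <- vf_load_checkpoint(path)
  expect_identical(flow_get_params(fm2), flow_get_params(fm))
  r <- matrix(seq(-2, 2, length.out = 7), ncol = 1)
  expect_identical(flow_forward(fm2, r), flow_forward(fm, r))
  expect_equal(attr(fm2, "meta")$seed, 7)
})
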