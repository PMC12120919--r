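test_that("harmonic matrix elements match the ladder-operator closed forms", {
  fx <- fixture_1d(nmax = 9L)
  h <- build_hamiltonian(fx$bs, NULL, fx$p$kf, fx$p$V, fx$grid, fx$rule)
  n <- 0:9
  expect_equal(diag(h$V), (2 * n + 1) / 4, tolerance = 1e-12)
  off2 <- h$V[cbind(1:8, 3:10)]
  expect_equal(off2, sqrt((n[1:8] + 1) * (n[1:8] + 2)) / 4, tolerance = 1e-12)
  expect_equal(diag(h$T), (2 * n + 1) / 4, tolerance = 1e-12)
  expect_lt(max(abs(h$S - diag(10))), 1e-13)
  expect_lt(max(abs(h$U)), 1e-14)
  # V = 0 gives the zero matrix
  Vz <- build_potential(fx$bs, NULL, function(R) numeric(nrow(as.matrix(R))),
                        fx$grid, fx$rule)
  expect_identical(max(abs(Vz)), 0)
})

test_that("a non-finite potential at a node is reported with the offending point", {
  fx <- fixture_1d()
  bad <- function(R) { v <- fx$p$V(R); v[3] <- NaN; v }
  expect_error(build_potential(fx$bs, NULL, bad, fx$grid, fx$rule),
               "potential undefined")
})

test_that("q-space matrices equal the dense r-space oracle for random flows (1D)", {
  fx <- fixture_1d(nmax = 7L)
  rule <- truncation_rule(1L, 7L)
  for (seed in c(5, 29)) {
    fm <- random_flow(fx$fm, sd = 0.2, seed = seed)
    Tq <- build_kinetic(fx$bs, fm, fx$p$kf, fx$grid, rule)
    Vq <- build_potential(fx$bs, fm, fx$p$V, fx$grid, rule)
    orc <- rspace_oracle_1d(fx$bs, fm, fx$p$kf, fx$p$V, rule)
    expect_lt(max(abs(Tq - orc$T)), 1e-5)
    expect_lt(max(abs(Vq - orc$V)), 1e-6)
  }
})

test_that("q-space matrices equal the dense r-space oracle for a random flow (2D)", {
  p <- make_problem("coupled_harmonic_2d")
  bs <- p$bs; bs$nmax <- c(3L, 3L)
  rule <- truncation_rule(c(1L, 1L), 3L)
  g <- build_quadrature(bs, c(14L, 14L))
  fm <- random_flow(flow_model(g, p$domains, n_blocks = 2L, hidden = c(4L, 4L), seed = 4),
                    sd = 0.15, sd_scaling = 0.02, seed = 13)
  Tq <- build_kinetic(bs, fm, p$kf, g, rule)
  Vq <- build_potential(bs, fm, p$V, g, rule)
  orc <- rspace_oracle_2d(bs, fm, p$kf, p$V, rule)
  expect_lt(max(abs(Tq - orc$T)), 1e-5)
  expect_lt(max(abs(Vq - orc$V)), 1e-5)
})

test_that("pseudopotential matrices share the potential code path and symmetry", {
  # 1D nonconstant G
  cs <- coordinate_system("x", list(coordinate_domain("infinite")),
                          g_field = function(r) matrix(1 / (1 + 0.2 * r^2), 1, 1),
                          g_field_batch = function(R) {
                            R <- as.matrix(R)
                            array(1 / (1 + 0.2 * R[, 1]^2), c(nrow(R), 1, 1))
                          })
  kf <- kinetic_field(cs)
  bs <- basis_spec("hermite", 0, 1, nmax = 5L)
  g <- build_quadrature(bs, 30L)
  rule <- truncation_rule(1L, 5L)
  Um <- build_pseudopotential_matrix(bs, NULL, kf, g, rule)
  Um2 <- build_potential(bs, NULL, function(R) pseudopotential(kf, R), g, rule)
  expect_identical(Um, Um2)
  expect_lt(max(abs(Um - t(Um))), 1e-14)
  # constant G gives a zero matrix
  ph <- make_problem("harmonic_1d")
  fx <- fixture_1d()
  Uz <- build_pseudopotential_matrix(fx$bs, NULL, ph$kf, fx$grid, fx$rule)
  expect_identical(max(abs(Uz)), 0)
})

test_that("solve returns exact limits: harmonic ladder and sorted diagonals", {
  fx <- fixture_1d(nmax = 39L, degree = 60L)
  h <- build_hamiltonian(fx$bs, NULL, fx$p$kf, fx$p$V, fx$grid, fx$rule)
  sp <- solve_spectrum(h, 20)
  expect_lt(max(abs(sp$energies - (1:20 - 0.5))), 1e-9)
  # diagonal matrix input
  sp2 <- solve_spectrum(diag(c(3, 1, 2)), 3)
  expect_equal(sp2$energies, c(1, 2, 3))
  expect_error(solve_spectrum(diag(2), 5), "N = 2")
  expect_error(solve_spectrum(matrix(c(1, NaN, NaN, 1), 2)), "non-finite")
})

test_that("the variational bound holds for every flow draw and truncation", {
  fx <- fixture_1d(nmax = 9L)
  for (seed in 1:8) {
    fm <- random_flow(fx$fm, sd = 0.5, sd_scaling = 0.2, seed = seed)
    for (pm in c(3L, 6L, 9L)) {
      h <- build_hamiltonian(fx$bs, fm, fx$p$kf, fx$p$V, fx$grid,
                             truncation_rule(1L, pm))
      e0 <- solve_spectrum(h, 1)$energies
      expect_gte(e0, 0.5 - 1e-10)
    }
  }
})

test_that("converged spectra are independent of the flow parameters", {
  fx <- fixture_1d(nmax = 39L, degree = 64L)
  fm <- random_flow(fx$fm, sd = 0.15, sd_scaling = 0.02, seed = 7)
  h <- build_hamiltonian(fx$bs, fm, fx$p$kf, fx$p$V, fx$grid, fx$rule)
  sp <- solve_spectrum(h, 8)
  expect_lt(max(abs(sp$energies - (1:8 - 0.5))), 1e-6)
})

test_that("energies decrease monotonically under nested truncations for a fixed flow", {
  p <- make_problem("morse_1d")
  bs <- p$bs; bs$nmax <- 19L
  g <- build_quadrature(bs, 40L)
  fm <- random_flow(flow_model(g, p$domains, n_blocks = 2L, hidden = c(4L, 4L), seed = 3),
                    sd = 0.2, seed = 19)
  prev <- NULL
  for (pm in c(7L, 11L, 15L, 19L)) {
    h <- build_hamiltonian(bs, fm, p$kf, p$V, g, truncation_rule(1L, pm))
    e <- solve_spectrum(h, 5)$energies
    if (!is.null(prev)) expect_true(all(e <= prev + 1e-11))
    prev <- e
  }
})

test_that("a pure scaling flow reproduces the rescaled problem's kinetic matrix", {
  fx <- fixture_1d(nmax = 7L)
  rule <- truncation_rule(1L, 7L)
  # affine flow q = 2 r: kinetic in the augmented basis equals the kinetic of
  # basis functions phi(2r) sqrt(2), i.e. the identity-flow matrix of the
  # problem rescaled by the analytic change of variables
  fm_aff <- fx$fm
  fm_aff$alpha <- vibflow:::inv_softplus(2 * softplus(fx$fm$alpha))
  fm_aff <- vibflow:::flow_prepare(fm_aff)
  Tq <- build_kinetic(fx$bs, fm_aff, fx$p$kf, fx$grid, rule)
  # analytic: <d/dr phi_n(2r) sqrt2 | G | ...>/2 = 4 * identity-flow T
  T0 <- build_kinetic(fx$bs, NULL, fx$p$kf, fx$grid, rule)
  expect_equal(Tq, 4 * T0, tolerance = 1e-9)
})
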