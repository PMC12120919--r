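test_that("diatomic stretch G equals the reduced-mass closed form", {
  cs <- coordinate_system("r", list(coordinate_domain("semi_infinite", 0)),
                          embedding = "diatomic", masses = c(1, 1))
  expect_equal(drop(gmatrix_from_embedding(cs, 1.3)), 2, tolerance = 1e-10)
  cs2 <- coordinate_system("r", list(coordinate_domain("semi_infinite", 0)),
                           embedding = "diatomic", masses = c(2, 2))
  expect_equal(drop(gmatrix_from_embedding(cs2, 0.8)), 1, tolerance = 1e-10)
  set.seed(1)
  for (k in 1:10) {
    m <- runif(2, 0.3, 30)
    csx <- coordinate_system("r", list(coordinate_domain("semi_infinite", 0)),
                             embedding = "diatomic", masses = m)
    G <- drop(gmatrix_from_embedding(csx, runif(1, 0.5, 2)))
    expect_equal(G, 1 / m[1] + 1 / m[2], tolerance = 1e-10)
  }
})

test_that("a user-supplied g_field passes through unchanged", {
  Gm <- matrix(c(2, 0.1, 0.1, 3), 2, 2)
  cs <- coordinate_system(c("a", "b"),
                          list(coordinate_domain("infinite"), coordinate_domain("infinite")),
                          g_field = function(r) Gm)
  expect_identical(gmatrix_from_embedding(cs, c(0.3, -1)), Gm)
})

test_that("the embedding construction reproduces the Wilson valence G-matrix", {
  p <- make_problem("triatomic_toy_3d")
  set.seed(2)
  for (k in 1:6) {
    r <- c(runif(1, 0.7, 1.4), runif(1, 0.7, 1.4), runif(1, 0.9, 2.4))
    Ge <- gmatrix_from_embedding(p$cs, r)
    Gw <- p$kf$G_batch(matrix(r, 1))[1, , ]
    expect_lt(max(abs(Ge - Gw)), 1e-9)
    expect_lt(max(abs(Ge - t(Ge))), 1e-14)
    expect_true(all(eigen(Ge, symmetric = TRUE, only.values = TRUE)$values > 0))
  }
})

test_that("Jacobi coordinates give the textbook diagonal G structure", {
  m <- c(2, 3, 5)
  cs <- coordinate_system(c("rd", "R", "alpha"),
                          list(coordinate_domain("semi_infinite", 0),
                               coordinate_domain("semi_infinite", 0),
                               coordinate_domain("finite", 0, pi)),
                          embedding = "jacobi_triatomic", masses = m)
  rd <- 1.1; R <- 1.7
  G <- gmatrix_from_embedding(cs, c(rd, R, 1.2))
  mu12 <- 1 / (1 / m[1] + 1 / m[2])
  muR <- 1 / (1 / (m[1] + m[2]) + 1 / m[3])
  expect_equal(G[1, 1], 1 / mu12, tolerance = 1e-9)
  expect_equal(G[2, 2], 1 / muR, tolerance = 1e-9)
  expect_equal(G[3, 3], 1 / (mu12 * rd^2) + 1 / (muR * R^2), tolerance = 1e-9)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-9)
})

test_that("singular geometries raise a diagnostic naming the coordinate", {
  p <- make_problem("triatomic_toy_3d")
  expect_error(gmatrix_from_embedding(p$cs, c(1, 1, 1e-6)), "singular geometry")
})

test_that("the pseudopotential vanishes for constant G and matches symbolic values", {
  ph <- make_problem("harmonic_1d")
  expect_identical(pseudopotential(ph$kf, matrix(c(-1, 0, 2), ncol = 1)),
                   c(0, 0, 0))
  # G(r) = 1/(1+r^2): U = (2 - 5 r^2) / (8 (1 + r^2)^3), symbolically derived
  cs <- coordinate_system("x", list(coordinate_domain("infinite")),
                          g_field = function(r) matrix(1 / (1 + r^2), 1, 1),
                          g_field_batch = function(R) {
                            R <- as.matrix(R)
                            array(1 / (1 + R[, 1]^2), c(nrow(R), 1, 1))
                          })
  kf <- kinetic_field(cs)
  u <- pseudopotential(kf, matrix(c(0, 0.5, 1), ncol = 1))
  expect_equal(u, c(1 / 4, 6 / 125, -3 / 64), tolerance = 1e-7)
})

test_that("the pseudopotential is invariant under coordinate relabeling", {
  p <- make_problem("triatomic_toy_3d")
  # swap the two equivalent stretches (masses are symmetric)
  R <- matrix(c(0.9, 1.2, 1.9), 1)
  Rsw <- matrix(c(1.2, 0.9, 1.9), 1)
  expect_equal(p$kf$U(R), p$kf$U(Rsw), tolerance = 1e-12)
})

test_that("spectra are invariant under a nonlinear change of coordinates (full KEO)", {
  # harmonic oscillator expressed in warped coordinates x = r + 0.3 sin r;
  # G = 1/(dx/dr)^2 and the Podolsky pseudopotential must restore E_n = n + 1/2
  sp_ <- function(r) 1 + 0.3 * cos(r)
  s_ <- function(r) r + 0.3 * sin(r)
  cs <- coordinate_system("r", list(coordinate_domain("infinite")),
                          g_field = function(r) matrix(1 / sp_(r)^2, 1, 1),
                          g_field_batch = function(R) {
                            R <- as.matrix(R)
                            array(1 / sp_(R[, 1])^2, c(nrow(R), 1, 1))
                          })
  kf <- kinetic_field(cs)
  V <- function(R) 0.5 * s_(as.matrix(R)[, 1])^2
  bs <- basis_spec("hermite", 0, 1, nmax = 59L)
  g <- build_quadrature(bs, 80L)
  h <- build_hamiltonian(bs, NULL, kf, V, g, truncation_rule(1L, 59L))
  sp <- solve_spectrum(h, 10)
  expect_lt(max(abs(sp$energies - (1:10 - 0.5))), 1e-6)
})
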