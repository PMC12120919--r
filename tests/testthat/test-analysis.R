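test_that("1D contractions of a separable problem reproduce oscillator ladders", {
  p <- make_problem("coupled_harmonic_2d", params = list(theta = 0))
  bs <- p$bs; bs$nmax <- c(10L, 10L)
  cts <- lapply(1:2, function(i) contract_1d(bs, NULL, p$kf, p$V, i, c(0, 0), 30L))
  expect_lt(max(abs(cts[[1]]$energies[1:5] - 1.0 * (1:5 - 0.5))), 1e-8)
  expect_lt(max(abs(cts[[2]]$energies[1:5] - 1.3 * (1:5 - 0.5))), 1e-8)
})

test_that("contracting a 1D problem is the full solve", {
  p <- make_problem("morse_1d")
  bs <- p$bs; bs$nmax <- 11L
  ct <- contract_1d(bs, NULL, p$kf, p$V, 1, 0, 40L)
  g <- build_quadrature(bs, 40L)
  sp <- solve_spectrum(build_hamiltonian(bs, NULL, p$kf, p$V, g,
                                         truncation_rule(1L, 11L)))
  expect_equal(ct$energies, sp$energies, tolerance = 1e-10)
})

test_that("identity-flow contraction equals the reference-coordinate contraction", {
  fx <- fixture_1d(nmax = 8L)
  ct_ref <- contract_1d(fx$bs, NULL, fx$p$kf, fx$p$V, 1, 0, 40L)
  ct_fl <- contract_1d(fx$bs, fx$fm, fx$p$kf, fx$p$V, 1, 0, 40L)
  expect_equal(ct_ref$energies, ct_fl$energies, tolerance = 1e-9)
})

test_that("an exactly separable Hamiltonian is fully assigned with p_max = 1", {
  p <- make_problem("coupled_harmonic_2d", params = list(theta = 0))
  bs <- p$bs; bs$nmax <- c(10L, 10L)
  rule <- truncation_rule(c(1L, 1L), 10L)
  g <- build_quadrature(bs, c(22L, 22L))
  sp <- solve_spectrum(build_hamiltonian(bs, NULL, p$kf, p$V, g, rule), 12)
  cts <- lapply(1:2, function(i) contract_1d(bs, NULL, p$kf, p$V, i, c(0, 0), 30L))
  asn <- assign_states(sp, cts)
  expect_equal(asn$records$p_max, rep(1, 12), tolerance = 1e-8)
  expect_identical(asn$summary$N_assign, 12L)
  expect_true(all(vapply(seq_len(12), function(m)
    sum(asn$records$labels[[m]]) <= 10, logical(1))))
})

test_that("a projection of exactly one half is not a unique assignment", {
  sp <- structure(list(energies = c(1, 2),
                       coefficients = matrix(c(1, 1, 1, -1) / sqrt(2), 2),
                       idx = matrix(c(0L, 1L), ncol = 1), M = 2L),
                  class = "vf_spectrum")
  cts <- list(list(energies = c(0, 1), vectors = diag(2), coord = 1L))
  asn <- assign_states(sp, cts)
  expect_equal(asn$records$p_max, c(0.5, 0.5))
  expect_false(any(asn$records$unique))
  expect_identical(asn$summary$N_assign, 0L)
})

test_that("assignment metrics are invariant under relabeling degenerate states", {
  p <- make_problem("coupled_harmonic_2d", params = list(omega = c(1, 1), theta = 0))
  bs <- p$bs; bs$nmax <- c(8L, 8L)
  rule <- truncation_rule(c(1L, 1L), 8L)
  g <- build_quadrature(bs, c(20L, 20L))
  sp <- solve_spectrum(build_hamiltonian(bs, NULL, p$kf, p$V, g, rule), 6)
  cts <- lapply(1:2, function(i) contract_1d(bs, NULL, p$kf, p$V, i, c(0, 0), 28L))
  asn1 <- assign_states(sp, cts)
  # swap the two members of the degenerate pair (states 2 and 3)
  sp2 <- sp
  sp2$coefficients[, 2:3] <- sp2$coefficients[, 3:2]
  asn2 <- assign_states(sp2, cts)
  expect_equal(sort(asn1$records$p_max), sort(asn2$records$p_max), tolerance = 1e-10)
  expect_identical(asn1$summary$N_assign, asn2$summary$N_assign)
})

test_that("convergence fits recover exact and noisy power laws", {
  Ns <- c(100, 200, 400)
  f <- fit_convergence(exp(2) * Ns^-3, Ns)
  expect_equal(f$k, 3, tolerance = 1e-12)
  expect_equal(f$logA, 2, tolerance = 1e-12)
  expect_error(fit_convergence(c(1, 2), c(10, 20)), "at least 3")
  expect_error(fit_convergence(c(1, -2, 3), c(10, 20, 40)), "positive")
  set.seed(8)
  Ns <- round(10^seq(1.5, 3, length.out = 12))
  L <- exp(1.7) * Ns^-2.4 * exp(rnorm(12, 0, 0.01))
  f2 <- fit_convergence(L, Ns)
  expect_lt(abs(f2$k - 2.4), 3 * f2$k_se)
})

test_that("potential cuts pass through identity and affine flows correctly", {
  fx <- fixture_1d()
  p2 <- make_problem("coupled_harmonic_2d")
  bs2 <- p2$bs; bs2$nmax <- c(9L, 9L)
  g2 <- build_quadrature(bs2, c(20L, 20L))
  fm2 <- flow_model(g2, p2$domains, n_blocks = 1L, hidden = c(4L, 4L), seed = 5)
  q1 <- seq(-1, 1, length.out = 9); q2 <- seq(-1, 1, length.out = 9)
  cut_id <- pes_cut(p2$V, NULL, c(1, 2), c(0, 0), q1, q2)
  expect_equal(cut_id$V, p2$V(cbind(cut_id$q1, cut_id$q2)), tolerance = 1e-14)
  cut_fl <- pes_cut(p2$V, fm2, c(1, 2), c(0, 0), q1, q2)  # identity-initialized
  expect_equal(cut_fl$V, cut_id$V, tolerance = 1e-10)
  # affine flow: cut equals the affinely remapped raw cut
  fm_aff <- fm2
  fm_aff$beta <- fm_aff$beta + 0.25
  fm_aff <- vibflow:::flow_prepare(fm_aff)
  cut_aff <- pes_cut(p2$V, fm_aff, c(1, 2), c(0, 0), q1, q2)
  R <- cbind(cut_id$q1, cut_id$q2) - 0.25
  expect_equal(cut_aff$V, p2$V(R), tolerance = 1e-10)
})
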