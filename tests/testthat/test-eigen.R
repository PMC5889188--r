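test_that("characteristic determinant vanishes at the known first root and scan brackets match a dense unscaled-determinant scan", {
  # near-root value is tiny relative to values a step away
  d0 <- char_determinant("free_full", 8.719)
  d1 <- char_determinant("free_full", 9.5)
  expect_lt(abs(d0), 1e-3 * abs(d1))
  expect_error(char_determinant("free_full", -1), "positive")

  # scaled production determinant vs plain-double unscaled determinant:
  # identical roots on a range where nothing overflows
  shape <- list(l_frac = 0.05, c_frac = 0.6)
  dense <- dense_scan_roots("contact_truncated", shape, 1, 40)
  pkg <- find_eigenvalues("contact_truncated", shape, n_modes = length(dense))
  expect_equal(pkg, dense, tolerance = 1e-8)
})

test_that("free full-length roots reproduce the reference decimals and truncated roots converge to them as truncation vanishes", {
  b <- find_eigenvalues("free_full", n_modes = 10)
  expect_equal(round(b, 3), free_full_roots10)
  bt <- find_eigenvalues("free_truncated", list(l_frac = 1e-5), n_modes = 5)
  expect_equal(bt, b[1:5], tolerance = 1e-4)
})

test_that("contact-case eigenvalues agree with an independent finite-element discretization", {
  shape <- list(l_frac = 0, c_frac = 0.5)
  ba <- find_eigenvalues("contact_full", shape, n_modes = 5)
  bf <- fem_betas(0, 0.5, n_el = 300, k = 5)
  expect_equal(bf, ba, tolerance = 1e-3)
  # and for the truncated contact case
  shape2 <- list(l_frac = 0.05, c_frac = 0.6)
  ba2 <- find_eigenvalues("contact_truncated", shape2, n_modes = 4)
  bf2 <- fem_betas(0.05, 0.6, n_el = 300, k = 4)
  expect_equal(bf2, ba2, tolerance = 1e-3)
})

test_that("scan reports a shortfall when the ceiling is too low", {
  expect_error(find_eigenvalues("free_full", n_modes = 10, beta_max = 100),
               "found only")
})

test_that("built modes satisfy their imposed boundary conditions", {
  # free full-length: clamped base
  b1 <- find_eigenvalues("free_full", n_modes = 1)
  m <- build_eigenmode("free_full", list(l_frac = 0), b1)
  zg <- seq(1e-6, b1, length.out = 300)
  amp <- max(abs(chi_eval(m, zg)))
  expect_lt(abs(chi_eval(m, b1)) / amp, 1e-8)
  expect_lt(abs(chi_eval(m, b1, 1L)) / amp, 1e-8)

  # truncated free: moment z^4 chi'' and shear vanish at the tip
  sh <- list(l_frac = 0.05)
  bt <- find_eigenvalues("free_truncated", sh, n_modes = 1)
  mt <- build_eigenmode("free_truncated", sh, bt)
  g <- mt$gamma
  ampt <- max(abs(chi_eval(mt, seq(g, bt, length.out = 300))))
  expect_lt(abs(g^4 * chi_eval(mt, g, 2L)) / ampt, 1e-6)
  shear <- g^4 * chi_eval(mt, g, 3L) + 4 * g^3 * chi_eval(mt, g, 2L)
  expect_lt(abs(shear) / ampt, 1e-6)

  # contact: node at the support for the first four modes
  shc <- list(l_frac = 0, c_frac = 0.3)
  bc <- find_eigenvalues("contact_full", shc, n_modes = 4)
  for (b in bc) {
    mc <- build_eigenmode("contact_full", shc, b)
    zz <- seq(1e-6, b, length.out = 400)
    expect_lt(abs(chi_eval(mc, mc$eta)) / max(abs(chi_eval(mc, zz))), 1e-8)
    expect_lt(abs(chi_eval(mc, b)) / max(abs(chi_eval(mc, zz))), 1e-8)
  }
  expect_error(build_eigenmode("free_full", list(l_frac = 0), b1 * 1.07),
               "not a root")
})

test_that("modes satisfy the dimensionless mode equation pointwise", {
  # (z^4 chi'')'' = z^4 chi'''' + 8 z^3 chi''' + 12 z^2 chi'' must equal z^2 chi
  cases <- list(
    list(case = "free_truncated", shape = list(l_frac = 0.05)),
    list(case = "contact_truncated", shape = list(l_frac = 0.05, c_frac = 0.6)))
  for (cs in cases) {
    b <- find_eigenvalues(cs$case, cs$shape, n_modes = 3)
    for (bj in b) {
      m <- build_eigenmode(cs$case, cs$shape, bj)
      z <- seq(m$gamma + 0.01 * bj, bj - 1e-9, length.out = 200)
      if (!is.na(m$eta)) z <- z[abs(z - m$eta) > 0.01 * bj]
      lhs <- z^4 * chi_eval(m, z, 4L) + 8 * z^3 * chi_eval(m, z, 3L) +
        12 * z^2 * chi_eval(m, z, 2L)
      rhs <- z^2 * chi_eval(m, z)
      expect_lt(max(abs(lhs - rhs)) / max(abs(lhs), abs(rhs)), 1e-6)
    }
  }
})

test_that("eigenmode Gram matrices are the identity under the x^2 weight", {
  w <- std_whisker()
  free6 <- eigenmode_basis(w, n_modes = 6)
  G1 <- orthogonality_matrix(free6$modes)
  expect_lt(max(abs(G1 - diag(6))), 1e-6)
  ct6 <- eigenmode_basis(w, c_frac = 0.6, n_modes = 6)
  G2 <- orthogonality_matrix(ct6$modes)
  expect_lt(max(abs(G2 - diag(6))), 1e-6)
  expect_equal(as.numeric(orthogonality_matrix(free6$modes[1])), 1,
               tolerance = 1e-9)
  expect_error(orthogonality_matrix(list(free6$modes[[1]], ct6$modes[[1]])),
               "share")
})

test_that("second orthogonality relation holds with the eigenvalue on the diagonal", {
  # int X_i (x^4 X_j'')'' dx = (4 rho omega_i^2 / (E xi^2)) delta_ij
  w <- std_whisker(alpha = 0)
  bs <- eigenmode_basis(w, c_frac = 0.6, n_modes = 4)
  q4 <- 4 * w$rho * bs$omega^2 / (w$E * w$xi^2)
  bmax <- max(bs$beta)
  brk <- whiskerbeam:::osc_breaks(c(0.05, 0.6, 1) * bmax, per_osc = 8) / bmax
  g <- whiskerbeam:::gl_grid(brk * w$L)
  X <- vapply(bs$modes, eval_eigenmode, g$x, geom = w, x = g$x)
  op <- vapply(bs$modes, function(m) {
    g$x^4 * eval_eigenmode(m, w, g$x, 4L) +
      8 * g$x^3 * eval_eigenmode(m, w, g$x, 3L) +
      12 * g$x^2 * eval_eigenmode(m, w, g$x, 2L)
  }, g$x)
  Gm <- t(X) %*% (op * g$w)
  expect_lt(max(abs(Gm - diag(q4))) / max(q4), 1e-5)
})

test_that("beta depends only on shape ratios; omega maps carry the material scalings", {
  sh <- list(l_frac = 0.05, c_frac = 0.55)
  b <- find_eigenvalues("contact_truncated", sh, n_modes = 2)
  # three whiskers with very different E, rho, R but identical shape
  w1 <- whisker_geometry(L = 18e-3, R = 37e-6, trunc = 0.9e-3, rho = 1000, E = 3e9)
  w2 <- whisker_geometry(L = 18e-3, R = 74e-6, trunc = 0.9e-3, rho = 1400, E = 9e9)
  w3 <- whisker_geometry(L = 12e-3, R = 20e-6, trunc = 0.6e-3, rho = 800, E = 1e9)
  for (w in list(w1, w2, w3)) {
    bb <- eigenmode_basis(w, c_frac = 0.55, n_modes = 2)
    expect_equal(bb$beta, b, tolerance = 1e-12)
  }
  w <- w1
  expect_equal(omega_from_beta(w, 2 * b[1]), 2 * omega_from_beta(w, b[1]))
  w4 <- whisker_geometry(L = w$L, R = w$R, trunc = w$trunc, rho = w$rho,
                         E = 4 * w$E)
  expect_equal(omega_from_beta(w4, b[1]), 2 * omega_from_beta(w, b[1]))
  expect_equal(beta_from_omega(w, omega_from_beta(w, b[1])), b[1],
               tolerance = 1e-12)
})

test_that("modulus inversion reproduces the worked example and round-trips", {
  E <- young_modulus_from_frequency(L = 17.14e-3, R = 37.15e-6, rho = 1000,
                                    omega = 962)
  expect_equal(E / 1e9, 3.04, tolerance = 0.01 / 3.04)
  # quadratic scaling in omega
  E2 <- young_modulus_from_frequency(17.14e-3, 37.15e-6, 1000, 2 * 962)
  expect_equal(E2, 4 * E)
  # inverse pair with omega_from_beta
  w <- whisker_geometry(L = 17.14e-3, R = 37.15e-6, rho = 1000, E = E)
  b1 <- find_eigenvalues("free_full", n_modes = 1)
  expect_equal(omega_from_beta(w, b1), 962, tolerance = 1e-12)
  expect_error(young_modulus_from_frequency(1, 1, 1, -5), "positive")
})

test_that("pole constraint raises the fundamental frequency for every contact point", {
  b_free <- find_eigenvalues("free_truncated", list(l_frac = 0.05), 1)
  for (cf in c(0.1, 0.3, 0.5, 0.7, 0.9)) {
    b_ct <- find_eigenvalues("contact_truncated",
                             list(l_frac = 0.05, c_frac = cf), 1)
    expect_gte(b_ct, b_free)
  }
})
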