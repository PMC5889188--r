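# shared small simulation used by several blocks (16 modes keeps this fast;
# displacement-level quantities are fully converged at this depth)
sim_small <- local({
  val <- NULL
  function() {
    if (is.null(val))
      val <<- simulate_touch(std_whisker(), c_frac = 0.6,
                             profile = standard_touch(), n_modes = 16)
    val
  }
})

test_that("modal projections match a dense trapezoid quadrature and decay with mode order", {
  w <- std_whisker()
  st <- static_deflection(w, c_frac = 0.6)
  bs <- eigenmode_basis(w, c_frac = 0.6, n_modes = 20)
  P <- modal_projection(st, bs)
  P_or <- projection_oracle(st, bs)
  expect_lt(max(abs(P - P_or)) / max(abs(P)), 1e-6)
  # the fundamental dominates and the tail trails off
  expect_gt(abs(P[1]), max(abs(P[-1])))
  expect_gt(abs(P[1]), 5 * stats::median(abs(P[11:20])))
  expect_error(modal_projection(static_deflection(w, c_frac = 0.5), bs),
               "different contact")
})

test_that("zero drive leaves the whisker at rest; ramp response matches the closed form", {
  w <- std_whisker(alpha = 0)
  st <- static_deflection(w, c_frac = 0.6)
  bs <- eigenmode_basis(w, c_frac = 0.6, n_modes = 4)
  t <- seq(0, 5e-3, by = 2.5e-4)
  co0 <- contact_coefficients(bs, st, force_profile("ramp", s = 0), t)
  expect_equal(max(abs(co0$phi)), 0)
  # undamped ramp: phi_j = -(s P_j / omega_j) sin(omega_j t)
  s <- 1e-4
  co <- contact_coefficients(bs, st, force_profile("ramp", s = s), t)
  for (j in 1:4) {
    ref <- -(s * co$P[j] / bs$omega[j]) * sin(bs$omega[j] * t)
    expect_equal(co$phi[, j], ref, tolerance = 1e-10)
  }
  # with damping, the propagator-independent closed form still starts at rest
  wd <- std_whisker()
  bsd <- eigenmode_basis(wd, c_frac = 0.6, n_modes = 2)
  cod <- contact_coefficients(bsd, static_deflection(wd, c_frac = 0.6),
                              force_profile("ramp", s = s), t)
  expect_equal(cod$phi[1, ], c(0, 0))
})

test_that("exact propagator agrees with direct Duhamel quadrature", {
  w <- std_whisker()
  st <- static_deflection(w, c_frac = 0.6)
  bs <- eigenmode_basis(w, c_frac = 0.6, n_modes = 3)
  fp <- standard_touch()
  t <- c(0.5e-3, 2e-3, 6e-3, 10e-3)
  a <- contact_coefficients(bs, st, fp, t)
  b <- contact_coefficients(bs, st, fp, t, method = "duhamel")
  expect_lt(max(abs(a$phi - b$phi)) / max(abs(b$phi)), 1e-6)
  expect_lt(max(abs(a$dphi - b$dphi)) / max(abs(b$dphi)), 1e-6)
})

test_that("over-damped configurations are rejected", {
  w <- std_whisker(alpha = 5e5)        # alpha/2 above the first frequencies
  st <- static_deflection(w, c_frac = 0.6)
  bs <- eigenmode_basis(w, c_frac = 0.6, n_modes = 2)
  expect_error(contact_coefficients(bs, st, standard_touch(), 0),
               "under-damp")
})

test_that("whisker starts at rest and the vibrational part vanishes at the support", {
  sim <- sim_small()
  df <- displacement_field(sim, t = c(0, 1e-3, 5e-3))
  expect_equal(max(abs(df$y_total[1, ])), 0)
  # y_e(c, t) = 0 throughout contact
  dfc <- displacement_field(sim, x = sim$c_pos, t = seq(0, 10e-3, by = 5e-4))
  expect_lt(max(abs(dfc$y_vib)) / max(abs(dfc$y_total)), 1e-8)
  # decomposition is definitional
  expect_equal(df$y_total, df$y_static + df$y_vib)
})

test_that("touch onset launches a wave that travels from the contact point toward the base", {
  sim <- sim_small()
  xs <- seq(sim$c_pos, sim$geom$L, length.out = 200)
  df <- displacement_field(sim, x = xs, t = c(0.10e-3, 0.15e-3, 0.20e-3))
  peak_at <- apply(abs(df$y_vib), 1, function(r) xs[which.max(r)])
  expect_true(all(diff(peak_at) > 0))
  expect_lt(peak_at[1], sim$c_pos + 0.4 * (sim$geom$L - sim$c_pos))
})

test_that("displacement and velocity are continuous across detachment", {
  sim <- sim_small()
  expect_lt(sim$detach$residual, 1e-3)
  tf <- sim$profile$t_f
  df <- displacement_field(sim, t = c(tf - 1e-9, tf + 1e-9))
  peak <- max(abs(df$y_total))
  expect_lt(max(abs(df$y_total[1, ] - df$y_total[2, ])) / peak, 1e-3)
})

test_that("undamped free vibration conserves modal energy after detachment", {
  w <- std_whisker(alpha = 0)
  sim <- simulate_touch(w, c_frac = 0.6, profile = standard_touch(),
                        n_modes = 12)
  t <- seq(sim$profile$t_f, 2 * sim$profile$t_f, length.out = 41)
  fr <- detach_and_free(sim, t)
  En <- rowSums(fr$dphi^2) +
    rowSums(sweep(fr$phi^2, 2, sim$free$omega^2, `*`))
  expect_lt(diff(range(En)) / mean(En), 1e-8)
})

test_that("free-phase envelopes decay at alpha / 2", {
  sim <- sim_small()
  alpha <- sim$geom$alpha
  omt1 <- sqrt(sim$free$omega[1]^2 - (alpha / 2)^2)
  t <- seq(sim$profile$t_f, sim$profile$t_f + 60 * pi / omt1,
           length.out = 6000)
  fr <- detach_and_free(sim, t)
  a1 <- abs(fr$phi[, 1])
  pk <- which(diff(sign(diff(a1))) < 0) + 1L
  slope <- stats::coef(stats::lm(log(a1[pk]) ~ t[pk]))[[2]]
  expect_equal(-2 * slope, alpha, tolerance = 0.01)
})

test_that("everything scales linearly with the peak force; follicle ratios do not", {
  w <- std_whisker()
  sim1 <- simulate_touch(w, c_frac = 0.6, profile = standard_touch(1e-6),
                         n_modes = 8)
  sim2 <- simulate_touch(w, c_frac = 0.6, profile = standard_touch(2e-6),
                         n_modes = 8)
  f1 <- follicle_signal(sim1); f2 <- follicle_signal(sim2)
  expect_equal(2 * f1$M_total, f2$M_total, tolerance = 1e-10)
  expect_equal(2 * f1$V_total, f2$V_total, tolerance = 1e-10)
  r1 <- max(abs(f1$M_vib)) / max(abs(f1$M_static))
  r2 <- max(abs(f2$M_vib)) / max(abs(f2$M_static))
  expect_equal(r1, r2, tolerance = 1e-10)
})

test_that("follicle signal is zero at rest, rings about the quasi-static trace, and reaches the adiabatic limit for slow forces", {
  sim <- sim_small()
  fs <- follicle_signal(sim)
  expect_equal(fs$M_total[1], 0)
  expect_equal(fs$V_total[1], 0)
  expect_equal(fs$V_static, fs$F)                 # static shear is the force
  # vibrational part oscillates around zero during contact and rings down after
  vc <- fs$V_vib[fs$phase == "contact"]
  expect_gt(max(vc), 0); expect_lt(min(vc), 0)
  post <- fs$M_vib[fs$phase == "free"]
  expect_gt(max(abs(post)), 0)
  # adiabatic limit: a 100x slower force leaves only the quasi-static part
  slow <- force_profile("gaussian_smooth", F_max = 1e-6, t_f = 1,
                        tau = 1e-3, C = 0.5)
  w <- std_whisker()
  st <- static_deflection(w, c_frac = 0.6)
  bs <- eigenmode_basis(w, c_frac = 0.6, n_modes = 6)
  t <- seq(0.1, 0.9, by = 0.02)
  co <- contact_coefficients(bs, st, slow, t, dt_int = 2e-4)
  X2 <- vapply(bs$modes, eval_eigenmode, numeric(length(w$L)), geom = w,
               x = w$L, deriv = 2L)
  Mvib <- w$E * w$I0 * as.numeric(co$phi %*% X2)
  Mstat <- force_eval(slow, t) * (w$L - 0.6 * w$L)
  expect_lt(max(abs(Mvib)) / max(abs(Mstat)), 5e-4)
})

test_that("retained-mode count is converged for displacement fields", {
  w <- std_whisker()
  xg <- seq(w$trunc, w$L, length.out = 101)
  tg <- seq(0, 10e-3, by = 5e-4)
  pk <- function(n) {
    sim <- simulate_touch(w, c_frac = 0.6, profile = standard_touch(),
                          n_modes = n, n_free = 4)
    max(abs(displacement_field(sim, x = xg, t = tg)$y_vib))
  }
  p30 <- pk(30); p60 <- pk(60)
  expect_lt(abs(p60 - p30) / p60, 1e-3)
})

test_that("full displacement field matches the finite-element method-of-lines oracle", {
  w <- std_whisker()
  t_out <- seq(0, 10e-3, by = 5e-4)
  ff <- fem_touch_field(w, 0.6, standard_touch(), t_out, n_el = 240,
                        n_modes = 20)
  sim <- simulate_touch(w, c_frac = 0.6, profile = standard_touch(),
                        n_modes = 20, n_free = 8)
  df <- displacement_field(sim, x = ff$x, t = t_out)
  expect_lt(max(abs(df$y_total - ff$y)) / max(abs(ff$y)), 0.02)
})
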