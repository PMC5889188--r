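test_that("fundamental contact frequency is single-peaked in contact position; higher modes are multi-peaked", {
  w <- whisker_geometry(L = 18e-3, R = 37e-6, rho = 1000, E = 3e9)  # full cone
  grid <- seq(0.05, 0.99, length.out = 200)
  sw <- frequency_sweep(w, grid, n_modes = 3)
  peaks <- function(y) sum(diff(sign(diff(y))) < 0)
  b1 <- sw$beta[sw$mode == 1]
  expect_equal(peaks(b1), 1)
  expect_gt(which.max(b1), 5)                       # interior maximum
  expect_lt(which.max(b1), length(b1) - 4)
  expect_equal(peaks(sw$beta[sw$mode == 2]), 2)
  expect_equal(peaks(sw$beta[sw$mode == 3]), 3)
})

test_that("contact frequencies are a pure shape property (invariant to E, rho, R)", {
  grid <- c(0.3, 0.6, 0.9)
  w1 <- whisker_geometry(L = 18e-3, R = 37e-6, rho = 1000, E = 3e9)
  w2 <- whisker_geometry(L = 18e-3, R = 80e-6, rho = 1300, E = 7e9)
  s1 <- frequency_sweep(w1, grid, n_modes = 2)
  s2 <- frequency_sweep(w2, grid, n_modes = 2)
  expect_equal(s1$beta, s2$beta, tolerance = 1e-12)
})

test_that("truncation shifts high modes more than the fundamental and matches the full-cone limit", {
  sw <- truncation_sweep(c(0, 0.05, 0.1), c_frac = 0.6, n_modes = 5)
  full <- find_eigenvalues("contact_full", list(l_frac = 0, c_frac = 0.6), 5)
  expect_equal(sw$beta[sw$l_frac == 0], full, tolerance = 1e-10)
  b0 <- sw$beta[sw$l_frac == 0]
  b05 <- sw$beta[sw$l_frac == 0.05]
  rel <- abs(b05 - b0) / b0
  expect_lt(rel[1], rel[5])
  # spot value against the dense unscaled-determinant scan
  dense <- dense_scan_roots("contact_truncated",
                            list(l_frac = 0.05, c_frac = 0.6), 1, 20)
  expect_equal(b05[1], dense[1], tolerance = 1e-8)
  expect_error(truncation_sweep(c(0, 0.7), c_frac = 0.6), "c_frac")
})

test_that("modal excitation is insensitive to shortening the onset below 0.1 ms", {
  w <- std_whisker()
  sp <- excitation_spectrum(w, c_frac = 0.6, profile = standard_touch(),
                            tau = c(0.05e-3, 0.1e-3), n_modes = 6)
  a1 <- sp$amplitude[sp$tau == 0.05e-3]
  a2 <- sp$amplitude[sp$tau == 0.10e-3]
  rel <- abs(a1 - a2) / a2
  # the low modes (periods >> tau) are essentially tau-independent; modes 5-6
  # have periods within ~4x of tau and retain a few percent of sensitivity
  expect_lt(max(rel[1:3]), 0.01)
  expect_lt(max(rel[4:6]), 0.08)
})

test_that("the second mode dominates excitation near c/L = 0.3", {
  w <- std_whisker()
  sp <- excitation_spectrum(w, c_frac = c(0.3, 0.6),
                            profile = standard_touch(),
                            sweep = "contact", n_modes = 6)
  a03 <- sp$amplitude[sp$c_frac == 0.3]
  a06 <- sp$amplitude[sp$c_frac == 0.6]
  expect_gt(a03[2], a03[1])      # mode 2 over mode 1 near c/L = 0.3
  expect_gt(a06[1], a06[2])      # fundamental dominates at c/L = 0.6
})

test_that("vibrational/static follicle ratios are force-invariant and grow toward the tip", {
  w <- std_whisker()
  r1 <- ratio_analysis(w, standard_touch(1e-6), c_frac_grid = c(0.3, 0.8),
                       n_modes = 12)
  r2 <- ratio_analysis(w, standard_touch(5e-6), c_frac_grid = c(0.3, 0.8),
                       n_modes = 12)
  expect_equal(r1$V_ratio_avg, r2$V_ratio_avg, tolerance = 1e-10)
  expect_equal(r1$M_ratio_max, r2$M_ratio_max, tolerance = 1e-10)
  # monotone increase toward the tip (x measured from the tip: smaller c/L)
  expect_gt(r1$V_ratio_avg[1], r1$V_ratio_avg[2])
  expect_gt(r1$M_ratio_max[1], r1$M_ratio_max[2])
})

test_that("frequency is the steadier cue proximally; force ratio overtakes near the tip", {
  w <- std_whisker()
  grid <- seq(0.12, 0.97, by = 0.025)
  rc <- rate_of_change_comparison(w, grid)
  mid <- !is.na(rc$freq_pct_per_mm)
  # proximal half of the whisker: c/L > 0.5 (x runs tip -> base); the
  # frequency cue changes faster than the force-ratio cue at every point
  prox <- mid & rc$c_frac >= 0.5
  expect_true(all(rc$freq_pct_per_mm[prox] > rc$ratio_pct_per_mm[prox]))
  expect_true(all(rc$freq_pct_per_mm[prox] > 4.5 &
                  rc$freq_pct_per_mm[prox] < 11))     # ~4.5-10 %/mm band
  # the force-ratio rate is flat and small proximally, and rises steeply
  # toward the tip (>100 %/mm for distal contacts of a full cone)
  expect_lt(min(rc$ratio_pct_per_mm[prox]), 2.2)
  wf <- whisker_geometry(L = w$L, R = w$R, rho = w$rho, E = w$E)
  rcf <- rate_of_change_comparison(wf, c(0.02, 0.03, 0.04, 0.06, 0.1))
  expect_gt(max(rcf$ratio_pct_per_mm, na.rm = TRUE), 100)
  tipward <- mid & rc$c_frac < 0.25
  expect_gt(max(rc$ratio_pct_per_mm[tipward]),
            10 * min(rc$ratio_pct_per_mm[prox]))
  # frequency rate in %/mm is invariant to a uniform rescaling of E
  w2 <- whisker_geometry(L = w$L, R = w$R, trunc = w$trunc, rho = w$rho,
                         E = 4 * w$E, alpha = w$alpha)
  rc2 <- rate_of_change_comparison(w2, grid)
  expect_equal(rc$freq_pct_per_mm[mid], rc2$freq_pct_per_mm[mid],
               tolerance = 1e-9)
})

test_that("sweep results are reproducible from their stored parameters", {
  w <- std_whisker()
  s1 <- frequency_sweep(w, c(0.4, 0.6), n_modes = 2)
  s2 <- frequency_sweep(w, c(0.4, 0.6), n_modes = 2)
  expect_identical(s1$beta, s2$beta)
})
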