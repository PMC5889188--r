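# Independent numerical oracles, deliberately built on different machinery
# than the production code paths they check.

# Static bending oracle: integrate y'' = M(x) / (E I(x)) twice, backwards
# from the clamped base (y(L) = y'(L) = 0), by cumulative trapezoid on a
# dense grid. Independent of the closed-form solution.
static_oracle <- function(geom, c_pos, F, x_out, n_grid = 40001L) {
  xs <- seq(geom$trunc, geom$L, length.out = n_grid)
  if (!c_pos %in% xs) xs <- sort(c(xs, c_pos))
  M <- ifelse(xs <= c_pos, 0, (xs - c_pos) * F)
  ypp <- M / (geom$E * (pi / 4) * (geom$xi * xs)^4)
  revcumtrapz <- function(x, y) {
    # int_x^L y ds via trapezoid, vectorized
    n <- length(x)
    seg <- diff(x) * (y[-1] + y[-n]) / 2
    c(rev(cumsum(rev(seg))), 0)
  }
  yp <- -revcumtrapz(xs, ypp)       # y'(x) = -int_x^L y'' ds
  y <- -revcumtrapz(xs, yp)
  list(x = xs,
       y = stats::approx(xs, y, xout = x_out)$y,
       yp = stats::approx(xs, yp, xout = x_out)$y)
}

# Dense-scan root oracle: the UNSCALED boundary determinant evaluated in
# plain double precision (safe for beta <= ~40, where I_nu(2 sqrt beta) does
# not overflow), scanned on a fine grid with uniroot refinement.
unscaled_det <- function(case, beta, shape) {
  l <- shape$l_frac %||% 0
  cf <- shape$c_frac
  gam <- beta * l; eta <- if (is.null(cf)) NA else beta * cf
  B <- function(kind, ord, z) {
    x <- 2 * sqrt(z)
    switch(kind, J = besselJ(x, ord), Y = besselY(x, ord),
           I = besselI(x, ord), K = besselK(x, ord))
  }
  row4 <- function(ord, z) {
    sg <- (-1)^(ord - 2L)
    c(sg * B("J", ord, z), sg * B("Y", ord, z), B("I", ord, z),
      sg * B("K", ord, z))
  }
  m <- switch(case,
    free_full = rbind(c(B("J", 2, beta), B("I", 2, beta)),
                      c(-B("J", 3, beta), B("I", 3, beta))),
    free_truncated = rbind(row4(2, beta), row4(3, beta), row4(4, gam),
                           c(B("J", 3, gam), B("Y", 3, gam), B("I", 3, gam),
                             -B("K", 3, gam))),
    contact_full = {
      l2 <- function(ord) c((-1)^(ord - 2L) * B("J", ord, eta),
                            B("I", ord, eta))
      m <- matrix(0, 6, 6)
      m[1, 3:6] <- row4(2, beta); m[2, 3:6] <- row4(3, beta)
      m[3, 1:2] <- l2(2); m[4, 3:6] <- row4(2, eta)
      m[5, 1:2] <- l2(3); m[5, 3:6] <- -row4(3, eta)
      m[6, 1:2] <- l2(4); m[6, 3:6] <- -row4(4, eta)
      m
    },
    contact_truncated = {
      m <- matrix(0, 8, 8)
      m[1, 5:8] <- row4(2, beta); m[2, 5:8] <- row4(3, beta)
      m[3, 1:4] <- row4(2, eta); m[4, 5:8] <- row4(2, eta)
      m[5, 1:4] <- row4(3, eta); m[5, 5:8] <- -row4(3, eta)
      m[6, 1:4] <- row4(4, eta); m[6, 5:8] <- -row4(4, eta)
      m[7, 1:4] <- row4(4, gam)
      m[8, 1:4] <- c(B("J", 3, gam), B("Y", 3, gam), B("I", 3, gam),
                     -B("K", 3, gam))
      m
    })
  det(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

dense_scan_roots <- function(case, shape, beta_lo = 1, beta_hi = 40,
                             step = 0.002) {
  f <- function(b) unscaled_det(case, b, shape)
  bs <- seq(beta_lo, beta_hi, by = step)
  v <- vapply(bs, f, 0)
  i <- which(v[-length(v)] * v[-1] < 0)
  vapply(i, function(k)
    uniroot(f, c(bs[k], bs[k + 1]), tol = 1e-13)$root, 0)
}

# dense trapezoid quadrature oracle for the modal projections
projection_oracle <- function(static, basis, n_grid = 60001L) {
  geom <- basis$geom
  xs <- seq(geom$trunc, geom$L, length.out = n_grid)
  xs <- sort(unique(c(xs, static$c_pos)))
  ys <- static$ytilde(xs)
  vapply(basis$modes, function(m) {
    f <- ys * xs^2 * eval_eigenmode(m, geom, xs)
    sum(diff(xs) * (f[-1] + f[-length(f)]) / 2)
  }, 0)
}
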