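# Finite-element (Hermite cubic beam) oracle: an independent spatial
# discretization of the conical-beam operator, used to cross-check both the
# closed-form eigenvalues and full simulated displacement fields.

# element matrices for coefficient functions a(s) (stiffness weight) and
# b(s) (mass weight) on [s0, s0 + h], 6-point Gauss-Legendre in u
fem_element <- function(s0, h, afun, bfun) {
  gp <- c(0.0337652428984240, 0.1693953067668678, 0.3806904069584015,
          0.6193095930415985, 0.8306046932331322, 0.9662347571015760)
  gw <- c(0.0856622461895852, 0.1803807865240693, 0.2339569672863455,
          0.2339569672863455, 0.1803807865240693, 0.0856622461895852)
  Ke <- matrix(0, 4, 4); Me <- matrix(0, 4, 4)
  for (k in seq_along(gp)) {
    u <- gp[k]; s <- s0 + h * u
    N <- c(1 - 3 * u^2 + 2 * u^3, h * (u - 2 * u^2 + u^3),
           3 * u^2 - 2 * u^3, h * (u^3 - u^2))
    d2 <- c(-6 + 12 * u, h * (-4 + 6 * u), 6 - 12 * u, h * (6 * u - 2)) / h^2
    Ke <- Ke + gw[k] * h * afun(s) * tcrossprod(d2)
    Me <- Me + gw[k] * h * bfun(s) * tcrossprod(N)
  }
  list(K = Ke, M = Me)
}

# assemble clamped-base beam on [a, b]; nodes include `extra` exactly
fem_assemble <- function(a, b, n_el, afun, bfun, extra = NULL) {
  nodes <- sort(unique(c(seq(a, b, length.out = n_el + 1L), extra)))
  ne <- length(nodes) - 1L
  ndof <- 2L * (ne + 1L)
  K <- matrix(0, ndof, ndof); M <- matrix(0, ndof, ndof)
  for (e in seq_len(ne)) {
    el <- fem_element(nodes[e], nodes[e + 1L] - nodes[e], afun, bfun)
    ix <- c(2 * e - 1, 2 * e, 2 * e + 1, 2 * e + 2)
    K[ix, ix] <- K[ix, ix] + el$K
    M[ix, ix] <- M[ix, ix] + el$M
  }
  # clamp the base (last node): drop its w and w' dofs
  keep <- seq_len(ndof - 2L)
  list(nodes = nodes, K = K, M = M, keep = keep)
}

# generalized symmetric eigensolve K v = lambda M v on retained dofs
fem_eigs <- function(K, M, k) {
  R <- chol(M)
  Ri <- backsolve(R, diag(nrow(M)))
  A <- t(Ri) %*% K %*% Ri
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  n <- length(e$values)
  idx <- n:(n - k + 1L)                 # smallest k, ascending order
  list(values = e$values[idx], vectors = Ri %*% e$vectors[, idx])
}

# dimensionless betas: (s^4 chi'')'' = beta^2 s^2 chi on [l_frac, 1]
fem_betas <- function(l_frac, c_frac = NULL, n_el = 300, k = 5) {
  asm <- fem_assemble(l_frac, 1, n_el, function(s) s^4, function(s) s^2,
                      extra = c_frac)
  drop_dofs <- integer(0)
  if (!is.null(c_frac)) {
    ic <- which.min(abs(asm$nodes - c_frac))
    drop_dofs <- 2L * ic - 1L             # w dof at the support
  }
  keep <- setdiff(asm$keep, drop_dofs)
  ev <- fem_eigs(asm$K[keep, keep], asm$M[keep, keep], k)
  sqrt(ev$values)
}

# full method-of-lines touch simulation: FEM statics + FEM modes + exact
# per-step modal propagation (local copy, independent of the package path).
# Assembled in dimensionless coordinates s = x/L ((s^4 w'')'' operator, s^2
# mass weight) and mapped back:
#   static per unit force  y_s(Ls) = (4 / (pi E xi^4 L)) w_hat(s)
#   eigenvalues            omega = sqrt(lambda) (xi / (2 L)) sqrt(E / rho)
#   mass-normalized modes  X(Ls) = L^{-3/2} v(s)
fem_touch_field <- function(geom, c_frac, profile, t_out, n_el = 240,
                            n_modes = 20) {
  l_frac <- geom$trunc / geom$L
  asm <- fem_assemble(l_frac, 1, n_el, function(s) s^4, function(s) s^2,
                      extra = c_frac)
  ic <- which.min(abs(asm$nodes - c_frac))
  wdof_c <- 2L * ic - 1L
  keep <- asm$keep
  Kb <- asm$K[keep, keep]; Mb <- asm$M[keep, keep]
  # dimensionless static shape (unit point load at the contact w dof);
  # diagonal equilibration tames the w / w' scale mismatch
  f <- numeric(length(keep)); f[wdof_c] <- 1
  kk <- 4 / (pi * geom$E * geom$xi^4 * geom$L)
  d <- 1 / sqrt(diag(Kb))
  ys_hat <- d * solve(Kb * tcrossprod(d), d * f)
  ys <- kk * ys_hat                       # dimensional, per unit force
  # contact-constrained modes: additionally pin w at the contact node
  keep_c <- setdiff(seq_along(keep), wdof_c)
  ev <- fem_eigs(Kb[keep_c, keep_c], Mb[keep_c, keep_c], n_modes)
  om <- sqrt(ev$values) * (geom$xi / (2 * geom$L)) * sqrt(geom$E / geom$rho)
  V <- ev$vectors
  Vfull <- matrix(0, length(keep), n_modes)
  Vfull[keep_c, ] <- V
  # P_j = int ys x^2 X_j dx = kk L^{3/2} v_j' Mhat ys_hat
  P <- kk * geom$L^1.5 * as.numeric(crossprod(Vfull, Mb %*% ys_hat))
  alpha <- geom$alpha
  # exact propagation for piecewise-linear drive (local implementation)
  tau <- profile$tau
  tg <- sort(unique(c(seq(0, tau, length.out = 301L),
                      seq(0, profile$t_f, by = 2e-6), t_out)))
  drv <- -(force_eval(profile, tg, 2L) + alpha * force_eval(profile, tg, 1L))
  omt <- sqrt(om^2 - (alpha / 2)^2); w2 <- om^2
  phi <- matrix(0, length(tg), n_modes); dphi <- phi
  for (i in seq_len(length(tg) - 1L)) {
    h <- tg[i + 1L] - tg[i]; g0 <- drv[i]; g1 <- (drv[i + 1L] - drv[i]) / h
    xp0 <- (g0 - alpha * g1 / w2) / w2; vp <- g1 / w2
    x0 <- phi[i, ] - xp0; v0 <- dphi[i, ] - vp
    e <- exp(-alpha * h / 2); cs <- cos(omt * h); sn <- sin(omt * h)
    phi[i + 1L, ] <- e * (x0 * cs + (v0 + alpha / 2 * x0) / omt * sn) +
      xp0 + g1 * h / w2
    dphi[i + 1L, ] <- e * (v0 * cs - (w2 * x0 + alpha / 2 * v0) / omt * sn) + vp
  }
  it <- match(t_out, tg)
  phi <- sweep(phi[it, , drop = FALSE], 2, P, `*`)
  # displacement at the w dofs of the free nodes (clamped base excluded)
  wdofs <- seq(1L, length(keep), by = 2L)
  Ft <- force_eval(profile, t_out)
  Y <- outer(Ft, ys[wdofs]) +
    phi %*% t(Vfull[wdofs, , drop = FALSE]) * geom$L^(-1.5)
  list(x = asm$nodes[-length(asm$nodes)] * geom$L, t = t_out, y = Y,
       omega = om)
}
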