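# Damped modal time evolution: projection of the quasi-static shape onto the
# contact-constrained eigenmodes, exact propagation of the modal oscillator
# equations, matching onto free modes at detachment, and reconstruction of
# displacement fields and follicle forces.

#' Projection of the unit-force static shape onto eigenmodes
#'
#' \eqn{P_j = \int_\ell^L \tilde y_s(x)\, x^2 X_j(x)\, dx}, the modal drive
#' amplitudes appearing in the forced-oscillator equations. Quadrature panels
#' are oscillation-aware with a forced break at the contact point (the static
#' shape has a slope kink at the support).
#'
#' @param static a [static_deflection()] object (any force; the unit-force
#'   factor \code{ytilde} is used).
#' @param basis a [eigenmode_basis()] object for the same geometry and
#'   contact point (contact case).
#' @return numeric vector of projections, one per mode (units m/N x m^{3/2}).
#' @export
modal_projection <- function(static, basis) {
  stopifnot(inherits(static, "whisker_static"), inherits(basis, "whisker_modes"))
  geom <- basis$geom
  if (!isTRUE(all.equal(geom$L, static$geom$L)) ||
      !isTRUE(all.equal(geom$E, static$geom$E)))
    stop("static solution and mode basis belong to different whiskers")
  if (startsWith(basis$case, "contact") &&
      !isTRUE(all.equal(basis$shape$c_frac, static$c_pos / geom$L)))
    stop("static solution and mode basis have different contact points")
  bmax <- max(basis$beta)
  sbrk <- osc_breaks(c(basis$shape$l_frac,
                       static$c_pos / geom$L, 1) * bmax, per_osc = 8) / bmax
  g <- gl_grid(sbrk * geom$L)
  ys <- static$ytilde(g$x)
  X <- basis_matrix(basis, g$x)
  as.numeric(crossprod(X, g$w * g$x^2 * ys))
}

# exact step propagation of x'' + alpha x' + omega^2 x = g(t) with g
# piecewise linear on tg; vectorized across modes. Returns nt x n matrices.
propagate_pl <- function(omega, alpha, tg, g) {
  omt <- sqrt(omega^2 - (alpha / 2)^2)
  w2 <- omega^2
  nt <- length(tg); n <- length(omega)
  phi <- matrix(0, nt, n); dphi <- matrix(0, nt, n)
  for (i in seq_len(nt - 1L)) {
    h <- tg[i + 1L] - tg[i]
    g0 <- g[i]; g1 <- (g[i + 1L] - g[i]) / h
    xp0 <- (g0 - alpha * g1 / w2) / w2
    vp <- g1 / w2
    x0 <- phi[i, ] - xp0; v0 <- dphi[i, ] - vp
    e <- exp(-alpha * h / 2); cs <- cos(omt * h); sn <- sin(omt * h)
    phi[i + 1L, ]  <- e * (x0 * cs + (v0 + alpha / 2 * x0) / omt * sn) +
      xp0 + g1 * h / w2
    dphi[i + 1L, ] <- e * (v0 * cs - (w2 * x0 + alpha / 2 * v0) / omt * sn) + vp
  }
  list(phi = phi, dphi = dphi)
}

# internal time grid for the contact phase: dense over the onset, fixed fine
# step elsewhere, with the requested output times included exactly
contact_time_grid <- function(profile, t_out, dt_int) {
  tf <- profile$t_f
  tg <- unique(sort(c(
    if (profile$kind == "gaussian_smooth")
      seq(0, profile$tau, length.out = 2001L),
    seq(0, tf, by = dt_int), tf, t_out)))
  tg[tg >= 0 & tg <= tf]
}

#' Contact-phase modal coefficients
#'
#' Solves \eqn{\ddot\phi_j + \alpha\dot\phi_j + \omega_j^2\phi_j =
#' -(\ddot F + \alpha\dot F) P_j} from rest. The default engine propagates
#' the modal oscillators exactly over a fine grid on which the drive is
#' interpolated linearly (the oscillatory kernel is integrated in closed
#' form, so the step does not need to resolve the mode periods, only the
#' smoothness of the force). \code{method = "duhamel"} evaluates the
#' convolution integral directly by adaptive quadrature; it is slow and kept
#' as an independent cross-check. Ramp forcing is evaluated in closed form
#' (the impulsive \eqn{\ddot F} at onset contributes the free term
#' \eqn{-sP_j/\tilde\omega_j \, e^{-\alpha t/2}\sin\tilde\omega_j t}).
#'
#' @param basis contact-case [eigenmode_basis()].
#' @param static matching [static_deflection()].
#' @param profile a [force_profile()].
#' @param t output times in \code{[0, t_f]}.
#' @param method \code{"propagator"} (default) or \code{"duhamel"}.
#' @param P optional precomputed [modal_projection()] vector.
#' @param dt_int internal propagation step (s); needs to resolve the force
#'   smoothness only, not the mode periods (the kernel is exact). The onset
#'   interval is always refined to 400 sub-steps.
#' @return list with \code{t}, matrices \code{phi}, \code{dphi}
#'   (\code{length(t)} x n modes) and the projections \code{P}.
#' @export
contact_coefficients <- function(basis, static, profile, t,
                                 method = c("propagator", "duhamel"),
                                 P = NULL, dt_int = 2e-6) {
  method <- match.arg(method)
  stopifnot(inherits(basis, "whisker_modes"), inherits(profile, "force_profile"))
  alpha <- basis$geom$alpha
  omega <- basis$omega
  if (any(omega <= alpha / 2))
    stop("over-damped mode encountered (omega <= alpha/2): the modal solution assumes under-damping")
  if (is.null(P)) P <- modal_projection(static, basis)
  t <- as.numeric(t)
  if (any(t < 0) || (is.finite(profile$t_f) && any(t > profile$t_f + 1e-15)))
    stop("t must lie in the contact window [0, t_f]")
  omt <- sqrt(omega^2 - (alpha / 2)^2)

  if (profile$kind == "ramp") {
    s <- profile$s
    phi <- dphi <- matrix(0, length(t), length(omega))
    for (i in seq_along(t)) {
      ti <- t[i]
      e <- exp(-alpha * ti / 2)
      I <- (omt - e * ((alpha / 2) * sin(omt * ti) + omt * cos(omt * ti))) /
        omega^2
      phi[i, ] <- -(s * P / omt) * (e * sin(omt * ti) + alpha * I)
      dphi[i, ] <- -(s * P / omt) * e *
        (omt * cos(omt * ti) + (alpha / 2) * sin(omt * ti))
    }
    return(list(t = t, phi = phi, dphi = dphi, P = P))
  }

  if (method == "duhamel") {
    drive <- function(u) force_eval(profile, u, 2L) +
      alpha * force_eval(profile, u, 1L)
    qint <- function(f, lo, hi) {
      if (hi <= lo) return(0)
      mids <- unique(pmin(pmax(c(profile$tau), lo), hi))
      brk <- unique(c(lo, mids, hi))
      s <- 0
      for (k in seq_len(length(brk) - 1L))
        s <- s + stats::integrate(f, brk[k], brk[k + 1L],
                                  rel.tol = 1e-10, abs.tol = 0,
                                  subdivisions = 2000L)$value
      s
    }
    phi <- dphi <- matrix(0, length(t), length(omega))
    for (j in seq_along(omega)) {
      for (i in seq_along(t)) {
        ti <- t[i]
        if (ti == 0) next
        phi[i, j] <- -(P[j] / omt[j]) * qint(function(u)
          drive(u) * exp(-alpha * (ti - u) / 2) * sin(omt[j] * (ti - u)),
          0, ti)
        dphi[i, j] <- -P[j] * qint(function(u)
          drive(u) * exp(-alpha * (ti - u) / 2) *
            (cos(omt[j] * (ti - u)) -
             alpha / (2 * omt[j]) * sin(omt[j] * (ti - u))),
          0, ti)
      }
    }
    return(list(t = t, phi = phi, dphi = dphi, P = P))
  }

  tg <- contact_time_grid(profile, t, dt_int)
  gdrv <- -(force_eval(profile, tg, 2L) + alpha * force_eval(profile, tg, 1L))
  pr <- propagate_pl(omega, alpha, tg, gdrv)
  idx <- match(t, tg)
  list(t = t,
       phi = sweep(pr$phi[idx, , drop = FALSE], 2, P, `*`),
       dphi = sweep(pr$dphi[idx, , drop = FALSE], 2, P, `*`),
       P = P)
}

# cross Gram matrix <Z_k, X_j> = int x^2 Z_k X_j dx between two bases of the
# same whisker (free rows x contact columns)
cross_gram <- function(free_basis, contact_basis) {
  geom <- free_basis$geom
  bmax <- max(max(free_basis$beta), max(contact_basis$beta))
  sh <- contact_basis$shape
  sbrk <- osc_breaks(c(sh$l_frac, if (!is.null(sh$c_frac)) sh$c_frac, 1) * bmax,
                     per_osc = 8) / bmax
  g <- gl_grid(sbrk * geom$L)
  Z <- basis_matrix(free_basis, g$x)
  X <- basis_matrix(contact_basis, g$x)
  crossprod(Z * (g$w * g$x^2), X)
}

#' Free vibration after detachment
#'
#' Matches the whisker state at detachment (\code{t = t_f}) onto the free
#' eigenmodes by the weighted projections
#' \eqn{\varphi_k(t_f) = \int x^2 Z_k\, y(x, t_f)\, dx} (and likewise for the
#' velocity), then evolves each free coefficient with the closed-form damped
#' solution. The force ends with \eqn{F(t_f) = 0} but generally
#' \eqn{\dot F(t_f) \ne 0}, so detachment injects velocity proportional to
#' \eqn{\dot F(t_f)\,\tilde y_s}.
#'
#' @param sim a [simulate_touch()] result.
#' @param t times \code{> t_f} (s).
#' @return list with matrices \code{phi} and \code{dphi}
#'   (\code{length(t)} x n free modes).
#' @export
detach_and_free <- function(sim, t) {
  stopifnot(inherits(sim, "whisker_sim"))
  t <- as.numeric(t)
  if (any(t < sim$profile$t_f - 1e-15)) stop("free phase requires t >= t_f")
  free_phase_eval(sim$free$omega, sim$geom$alpha, sim$detach$phi_f,
                  sim$detach$dphi_f, t - sim$profile$t_f)
}

# closed-form damped free evolution from initial (phi0, dphi0) at dt = 0
free_phase_eval <- function(omega, alpha, phi0, dphi0, dt) {
  omt <- sqrt(omega^2 - (alpha / 2)^2)
  nt <- length(dt); n <- length(omega)
  phi <- dphi <- matrix(0, nt, n)
  for (i in seq_len(nt)) {
    e <- exp(-alpha * dt[i] / 2)
    cs <- cos(omt * dt[i]); sn <- sin(omt * dt[i])
    phi[i, ] <- e * (phi0 * (alpha / (2 * omt) * sn + cs) + dphi0 / omt * sn)
    dphi[i, ] <- e * (dphi0 * (cs - alpha / (2 * omt) * sn) -
                      phi0 * (omega^2 / omt) * sn)
  }
  list(phi = phi, dphi = dphi)
}

#' Simulate a whisker touch: contact dynamics plus free ring-down
#'
#' End-to-end driver. Builds the contact-constrained and free eigenmode
#' bases, projects the quasi-static shape, evolves the damped modal
#' coefficients through the contact window, matches the state onto the free
#' modes at detachment and evaluates the free ring-down.
#'
#' @param geom a [whisker_geometry()] object.
#' @param c_pos,c_frac contact position (m, or fraction of L).
#' @param profile a [force_profile()]; default is the standard touch
#'   (Gaussian with C = 0.5, t_f = 10 ms, tau = 0.1 ms).
#' @param n_modes number of contact-constrained modes retained.
#' @param n_free number of free modes for the ring-down (default
#'   \code{n_modes}).
#' @param dt output time step (s).
#' @param t_max end of the simulated window (default \code{2 t_f}).
#' @return object of class \code{"whisker_sim"}; see
#'   [follicle_signal()] and [displacement_field()] for derived outputs.
#'   The field \code{detach$residual} reports the relative continuity error
#'   of the displacement across detachment.
#' @examples
#' \donttest{
#' sim <- simulate_touch(standard_whisker(), c_frac = 0.6, n_modes = 20)
#' fs <- follicle_signal(sim)
#' head(fs)
#' }
#' @export
simulate_touch <- function(geom, c_pos = NULL, c_frac = NULL,
                           profile = force_profile(), n_modes = 60,
                           n_free = n_modes, dt = 1e-5, t_max = NULL) {
  stopifnot(inherits(geom, "whisker_geometry"))
  if (profile$kind == "ramp")
    stop("simulate_touch() models a finite contact; use contact_coefficients() for the ramp force")
  cc <- contact_position(geom, c_pos, c_frac)
  tf <- profile$t_f
  if (is.null(t_max)) t_max <- 2 * tf
  static <- static_deflection(geom, cc, F = 1)
  cb <- eigenmode_basis(geom, c_pos = cc, n_modes = n_modes)
  P <- modal_projection(static, cb)
  t_c <- unique(c(seq(0, tf, by = dt), tf))
  co <- contact_coefficients(cb, static, profile, t_c, P = P)

  fb <- eigenmode_basis(geom, n_modes = n_free)
  if (any(fb$omega <= geom$alpha / 2))
    stop("over-damped free mode encountered (omega <= alpha/2)")
  G <- cross_gram(fb, cb)
  Pfree <- modal_projection(static, fb)
  Ftf <- force_eval(profile, tf); dFtf <- force_eval(profile, tf, 1L)
  phi_f <- as.numeric(Ftf * Pfree + G %*% co$phi[length(t_c), ])
  dphi_f <- as.numeric(dFtf * Pfree + G %*% co$dphi[length(t_c), ])

  # continuity of displacement across detachment, relative to peak |y(t_f)|
  xs <- seq(geom$trunc, geom$L, length.out = 241L)
  Xl <- basis_matrix(cb, xs); Zl <- basis_matrix(fb, xs)
  y_end <- Ftf * static$ytilde(xs) + as.numeric(Xl %*% co$phi[length(t_c), ])
  u_start <- as.numeric(Zl %*% phi_f)
  resid <- max(abs(y_end - u_start)) / max(abs(y_end))

  t_u <- seq(tf, t_max, by = dt)
  fr <- free_phase_eval(fb$omega, geom$alpha, phi_f, dphi_f, t_u - tf)

  structure(list(
    geom = geom, profile = profile, c_pos = cc, static = static,
    contact = cb, free = fb, P = P,
    t_contact = t_c, phi = co$phi, dphi = co$dphi,
    t_free = t_u, phi_free = fr$phi, dphi_free = fr$dphi,
    detach = list(phi_f = phi_f, dphi_f = dphi_f, gram = G,
                  P_free = Pfree, residual = resid)
  ), class = "whisker_sim")
}

#' @export
print.whisker_sim <- function(x, ...) {
  cat("Whisker touch simulation\n")
  cat(sprintf("  contact at c/L = %.3f, %d contact + %d free modes\n",
              x$c_pos / x$geom$L, ncol(x$phi), ncol(x$phi_free)))
  cat(sprintf("  contact window %.3g ms, simulated to %.3g ms (dt = %.3g ms)\n",
              x$profile$t_f * 1e3, max(x$t_free) * 1e3,
              diff(x$t_contact[1:2]) * 1e3))
  cat(sprintf("  detachment continuity residual: %.3g (relative)\n",
              x$detach$residual))
  invisible(x)
}

#' Whisker displacement field
#'
#' Reconstructs \eqn{y(x,t) = F(t)\tilde y_s(x) + \sum_j \phi_j(t) X_j(x)}
#' during contact and \eqn{u(x,t) = \sum_j \varphi_j(t) Z_j(x)} afterwards,
#' over the whole whisker including beyond the contact point.
#'
#' @param sim a [simulate_touch()] result.
#' @param x positions (m); default 201 points spanning tip to base.
#' @param t times (s); default the simulation grids.
#' @return object of class \code{"displacement_field"}: list with \code{x},
#'   \code{t}, \code{phase} ("contact"/"free" per time), and matrices
#'   \code{y_static}, \code{y_vib}, \code{y_total} (time x position).
#'   \code{as.data.frame()} converts to long format.
#' @export
displacement_field <- function(sim, x = NULL, t = NULL) {
  stopifnot(inherits(sim, "whisker_sim"))
  geom <- sim$geom
  if (is.null(x)) x <- seq(geom$trunc, geom$L, length.out = 201L)
  tf <- sim$profile$t_f
  if (is.null(t)) t <- c(sim$t_contact, sim$t_free[-1])
  t <- as.numeric(t)
  contact <- t <= tf
  Xl <- basis_matrix(sim$contact, x)
  Zl <- basis_matrix(sim$free, x)
  ys <- sim$static$ytilde(x)
  ns <- length(t)
  y_static <- y_vib <- matrix(0, ns, length(x))
  if (any(contact)) {
    tc <- t[contact]
    co <- contact_coefficients(sim$contact, sim$static, sim$profile, tc,
                               P = sim$P)
    y_static[contact, ] <- outer(force_eval(sim$profile, tc), ys)
    y_vib[contact, ] <- co$phi %*% t(Xl)
  }
  if (any(!contact)) {
    fr <- free_phase_eval(sim$free$omega, geom$alpha, sim$detach$phi_f,
                          sim$detach$dphi_f, t[!contact] - tf)
    y_vib[!contact, ] <- fr$phi %*% t(Zl)
  }
  structure(list(x = x, t = t,
                 phase = ifelse(contact, "contact", "free"),
                 y_static = y_static, y_vib = y_vib,
                 y_total = y_static + y_vib),
            class = "displacement_field")
}

#' @export
as.data.frame.displacement_field <- function(x, ...) {
  data.frame(t = rep(x$t, times = length(x$x)),
             x = rep(x$x, each = length(x$t)),
             phase = rep(x$phase, times = length(x$x)),
             y_static = as.vector(x$y_static),
             y_vib = as.vector(x$y_vib),
             y_total = as.vector(x$y_total))
}

#' Bending moment and shear force at the follicle
#'
#' During contact,
#' \eqn{M(L;t) = F(t)(L - c) + E I_0 \sum_j \phi_j X_j''(L)} and
#' \eqn{V(L;t) = F(t) + E I_0 \sum_j \phi_j (4 X_j''(L)/L + X_j'''(L))};
#' after detachment the same mode sums run over the free basis and the
#' quasi-static terms vanish. Quasi-static and vibrational components are
#' returned separately.
#'
#' @param sim a [simulate_touch()] result.
#' @param t times (s); default the simulation grids.
#' @return data.frame (class \code{"follicle_signal"}) with columns
#'   \code{t, phase, F, M_static, M_vib, M_total, V_static, V_vib, V_total}
#'   (SI units).
#' @export
follicle_signal <- function(sim, t = NULL) {
  stopifnot(inherits(sim, "whisker_sim"))
  geom <- sim$geom
  tf <- sim$profile$t_f
  EI0 <- geom$E * geom$I0
  if (is.null(t)) t <- c(sim$t_contact, sim$t_free[-1])
  t <- as.numeric(t)
  contact <- t <= tf
  mode_terms <- function(basis) {
    X2 <- as.numeric(basis_matrix(basis, geom$L, deriv = 2L))
    X3 <- as.numeric(basis_matrix(basis, geom$L, deriv = 3L))
    list(m = X2, v = 4 * X2 / geom$L + X3)
  }
  ct <- mode_terms(sim$contact); ft <- mode_terms(sim$free)
  n <- length(t)
  Fv <- Ms <- Mv <- Vs <- Vv <- numeric(n)
  if (any(contact)) {
    tc <- t[contact]
    co <- contact_coefficients(sim$contact, sim$static, sim$profile, tc,
                               P = sim$P)
    Fv[contact] <- force_eval(sim$profile, tc)
    Ms[contact] <- Fv[contact] * (geom$L - sim$c_pos)
    Vs[contact] <- Fv[contact]
    Mv[contact] <- EI0 * as.numeric(co$phi %*% ct$m)
    Vv[contact] <- EI0 * as.numeric(co$phi %*% ct$v)
  }
  if (any(!contact)) {
    fr <- free_phase_eval(sim$free$omega, geom$alpha, sim$detach$phi_f,
                          sim$detach$dphi_f, t[!contact] - tf)
    Mv[!contact] <- EI0 * as.numeric(fr$phi %*% ft$m)
    Vv[!contact] <- EI0 * as.numeric(fr$phi %*% ft$v)
  }
  out <- data.frame(t = t, phase = ifelse(contact, "contact", "free"),
                    F = Fv, M_static = Ms, M_vib = Mv, M_total = Ms + Mv,
                    V_static = Vs, V_vib = Vv, V_total = Vs + Vv)
  class(out) <- c("follicle_signal", "data.frame")
  out
}

#' @export
plot.whisker_sim <- function(x, ...) {
  fs <- follicle_signal(x)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4.5, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(fs$t * 1e3, fs$M_total * 1e9, type = "l",
                 xlab = "time (ms)", ylab = "bending moment (nN m)",
                 main = sprintf("follicle signals, c/L = %.2f",
                                x$c_pos / x$geom$L), ...)
  graphics::lines(fs$t * 1e3, fs$M_static * 1e9, lty = 2, col = "grey40")
  graphics::abline(v = x$profile$t_f * 1e3, col = "grey70", lty = 3)
  graphics::plot(fs$t * 1e3, fs$V_total * 1e6, type = "l",
                 xlab = "time (ms)", ylab = "shear force (uN)", ...)
  graphics::lines(fs$t * 1e3, fs$V_static * 1e6, lty = 2, col = "grey40")
  graphics::abline(v = x$profile$t_f * 1e3, col = "grey70", lty = 3)
  invisible(x)
}
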