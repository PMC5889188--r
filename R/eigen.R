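# Eigenvalue problems for the four boundary cases of a conical whisker:
# fixed base, free tip, with or without truncation, with or without a simple
# support (the pole) at the contact point. Everything here is dimensionless:
# beta = qL, gamma = q*trunc, eta = q*c, with q^2 = 4 rho omega^2 / (E xi^2).

.cases <- c("free_full", "free_truncated", "contact_full", "contact_truncated")

check_case <- function(case) {
  case <- match.arg(case, .cases)
  case
}

check_shape <- function(case, shape) {
  l <- if (is.null(shape$l_frac)) 0 else shape$l_frac
  cf <- shape$c_frac
  if (case %in% c("free_full", "contact_full") && l != 0)
    stop("full-length cases require l_frac = 0")
  if (case %in% c("free_truncated", "contact_truncated") && (l <= 0 || l >= 1))
    stop("truncated cases require 0 < l_frac < 1")
  if (startsWith(case, "contact")) {
    if (is.null(cf)) stop("contact cases require shape$c_frac")
    if (cf <= l || cf >= 1)
      stop("contact position must satisfy l_frac < c_frac < 1")
  } else if (!is.null(cf)) {
    stop("free cases take no contact position")
  }
  list(l_frac = l, c_frac = cf)
}

# Boundary matrix, column-scaled so that modified Bessel growth never
# overflows. Column scaling multiplies the determinant by a positive factor
# and leaves the root locations and the sign pattern unchanged. Coefficient
# vectors extracted from the scaled matrix refer to the scaled basis with
# the per-region references scI (largest argument) and scK (smallest).
boundary_matrix <- function(case, beta, shape) {
  sh <- check_shape(case, shape)
  gam <- beta * sh$l_frac
  eta <- if (is.null(sh$c_frac)) NA_real_ else beta * sh$c_frac
  row4 <- function(ord, z, scI, scK) {
    s <- (-1)^ord          # J/Y/K ladder sign relative to order-2 row
    # ladder signs: value rows (+,+,+,+) at ord 2, slope (-,-,+,-) at 3,
    # moment (+,+,+,+) at 4, third derivative (-,-,+,-) at 5; equivalently
    # sign (-1)^(ord-2) on J, Y, K and +1 on I.
    sg <- (-1)^(ord - 2L)
    c(sg * bessel_basis_raw("J", ord, z),
      sg * bessel_basis_raw("Y", ord, z),
      bessel_basis_raw("I", ord, z, scI),
      sg * bessel_basis_raw("K", ord, z, scK))
  }
  xb <- 2 * sqrt(beta); xe <- if (is.na(eta)) NA else 2 * sqrt(eta)
  xg <- 2 * sqrt(gam)

  switch(case,
    free_full = {
      # columns (J, I); rows: chi(beta) = 0, chi'(beta) = 0
      m <- rbind(
        c(bessel_basis_raw("J", 2L, beta), bessel_basis_raw("I", 2L, beta, xb)),
        c(-bessel_basis_raw("J", 3L, beta), bessel_basis_raw("I", 3L, beta, xb)))
      m
    },
    free_truncated = {
      # rows: base value, base slope, tip moment, tip shear (reduced)
      rbind(row4(2L, beta, xb, xg),
            row4(3L, beta, xb, xg),
            row4(4L, gam, xb, xg),
            # tip shear reduces to (J3, Y3, I3, -K3) at gamma
            c(bessel_basis_raw("J", 3L, gam), bessel_basis_raw("Y", 3L, gam),
              bessel_basis_raw("I", 3L, gam, xb),
              -bessel_basis_raw("K", 3L, gam, xg)))
    },
    contact_full = {
      # cols 1:2 left region (J, I on [0, eta]); cols 3:6 right (J,Y,I,K)
      left2 <- function(ord) {
        sg <- (-1)^(ord - 2L)
        c(sg * bessel_basis_raw("J", ord, eta),
          bessel_basis_raw("I", ord, eta, xe))
      }
      m <- matrix(0, 6, 6)
      m[1, 3:6] <- row4(2L, beta, xb, xe)
      m[2, 3:6] <- row4(3L, beta, xb, xe)
      m[3, 1:2] <- left2(2L)
      m[4, 3:6] <- row4(2L, eta, xb, xe)
      m[5, 1:2] <- left2(3L); m[5, 3:6] <- -row4(3L, eta, xb, xe)
      m[6, 1:2] <- left2(4L); m[6, 3:6] <- -row4(4L, eta, xb, xe)
      m
    },
    contact_truncated = {
      m <- matrix(0, 8, 8)
      m[1, 5:8] <- row4(2L, beta, xb, xe)
      m[2, 5:8] <- row4(3L, beta, xb, xe)
      m[3, 1:4] <- row4(2L, eta, xe, xg)
      m[4, 5:8] <- row4(2L, eta, xb, xe)
      m[5, 1:4] <- row4(3L, eta, xe, xg); m[5, 5:8] <- -row4(3L, eta, xb, xe)
      m[6, 1:4] <- row4(4L, eta, xe, xg); m[6, 5:8] <- -row4(4L, eta, xb, xe)
      m[7, 1:4] <- row4(4L, gam, xe, xg)
      m[8, 1:4] <- c(bessel_basis_raw("J", 3L, gam),
                     bessel_basis_raw("Y", 3L, gam),
                     bessel_basis_raw("I", 3L, gam, xe),
                     -bessel_basis_raw("K", 3L, gam, xg))
      m
    })
}

# raw (un-laddered) scaled Bessel value at order `ord`, argument 2 sqrt z
bessel_basis_raw <- function(kind, ord, z, sc = 0) {
  x <- 2 * sqrt(z)
  switch(kind,
    J = besselJ(x, ord),
    Y = besselY(x, ord),
    I = besselI(x, ord, expon.scaled = TRUE) * exp(x - sc),
    K = besselK(x, ord, expon.scaled = TRUE) * exp(sc - x))
}

#' Characteristic boundary determinant
#'
#' Signed, exponentially rescaled determinant whose zeros in \code{beta} are
#' the dimensionless eigenfrequencies of the given boundary case. The
#' rescaling factor is strictly positive, so the sign pattern (and hence the
#' bracketing of roots) matches the true determinant. For the free
#' full-length cone the reduced 2x2 form
#' \eqn{J_2 I_1 - J_1 I_2} (argument \eqn{2\sqrt\beta}) is used.
#'
#' @param case one of \code{"free_full"}, \code{"free_truncated"},
#'   \code{"contact_full"}, \code{"contact_truncated"}.
#' @param beta positive dimensionless frequency parameter (\code{beta = qL}).
#' @param shape list with \code{l_frac} (truncation / L; 0 for full cases)
#'   and, for contact cases, \code{c_frac} (contact / L).
#' @return scalar determinant value.
#' @examples
#' char_determinant("free_full", 8.719, list(l_frac = 0))   # ~ 0
#' @export
char_determinant <- function(case, beta, shape = list(l_frac = 0)) {
  case <- check_case(case)
  if (!is.numeric(beta) || any(beta <= 0))
    stop("beta must be positive")
  if (length(beta) > 1L)
    return(vapply(beta, char_determinant, 0, case = case, shape = shape))
  if (case == "free_full") {
    x <- 2 * sqrt(beta)
    return(besselJ(x, 2) * besselI(x, 1, TRUE) -
           besselJ(x, 1) * besselI(x, 2, TRUE))
  }
  d <- det(boundary_matrix(case, beta, shape))
  if (!is.finite(d)) stop("boundary determinant overflowed despite scaling (beta = ", beta, ")")
  d
}

#' Dimensionless eigenfrequencies of a conical whisker
#'
#' Finds the \code{n_modes} smallest positive roots of the boundary
#' determinant by a sign-change scan in \eqn{\nu = 2\sqrt\beta} (where roots
#' are asymptotically equally spaced) followed by bisection refinement. The
#' scan is verified against a half-step rescan so that closely spaced roots
#' are not skipped; the trivial root at \eqn{\beta = 0} is excluded by
#' starting the scan at \eqn{\beta = 0.25}.
#'
#' @inheritParams char_determinant
#' @param n_modes number of modes requested.
#' @param nu_step initial scan step in \eqn{\nu = 2\sqrt\beta}.
#' @param beta_max optional scan ceiling; if the scan exhausts it before
#'   finding \code{n_modes} roots an error reports how many were found.
#' @return strictly increasing numeric vector of length \code{n_modes}.
#' @examples
#' find_eigenvalues("free_full", n_modes = 3)   # 8.719 21.146 38.454
#' @export
find_eigenvalues <- function(case, shape = list(l_frac = 0), n_modes = 10,
                             nu_step = 0.05, beta_max = NULL) {
  case <- check_case(case)
  check_shape(case, shape)
  stopifnot(n_modes >= 1)
  f <- function(nu) char_determinant(case, (nu / 2)^2, shape)
  nu_lo <- 1                                    # beta = 0.25
  nu_cap <- if (is.null(beta_max)) max(40, 4.6 * (n_modes + 4)) else 2 * sqrt(beta_max)

  scan_brackets <- function(step, hi) {
    nu <- seq(nu_lo, hi, by = step)
    v <- vapply(nu, f, 0)
    i <- which(v[-length(v)] * v[-1] < 0 | v[-length(v)] == 0)
    cbind(nu[i], nu[i + 1])
  }

  hi <- nu_cap
  repeat {
    br <- scan_brackets(nu_step, hi)
    # half-step verification; refine until the bracket count stabilises
    step <- nu_step
    repeat {
      br2 <- scan_brackets(step / 2, hi)
      if (nrow(br2) == nrow(br)) break
      br <- br2; step <- step / 2
      if (step < nu_step / 32) break
    }
    if (nrow(br) >= n_modes || !is.null(beta_max)) break
    hi <- hi * 1.5                               # extend the window
    if (hi > 1e4) break
  }
  if (nrow(br) < n_modes)
    stop(sprintf("eigenvalue scan found only %d of %d requested roots below beta = %.4g",
                 nrow(br), n_modes, (hi / 2)^2))
  roots_nu <- vapply(seq_len(n_modes), function(k) {
    uniroot(f, br[k, ], tol = 1e-13 * max(1, br[k, 2]))$root
  }, 0)
  (roots_nu / 2)^2
}

#' Construct a normalized closed-form eigenmode
#'
#' Builds the Bessel-coefficient vector for a verified root \code{beta} as
#' the null vector (smallest singular direction) of the scaled boundary
#' matrix, then normalizes the dimensionless shape so that
#' \eqn{\int_\gamma^\beta z^2 \chi^2 \, dz = 1} (equivalent to
#' \eqn{\int_\ell^L x^2 X^2 \, dx = 1} for the dimensional mode
#' \eqn{X(x) = q^{3/2} \chi(qx)}). The sign is fixed so that the mode is
#' positive at its local amplitude maximum closest to the tip.
#'
#' @inheritParams char_determinant
#' @param beta a root of the characteristic determinant (see
#'   [find_eigenvalues()]).
#' @param j optional mode index stored for bookkeeping.
#' @return object of class \code{"eigenmode"}.
#' @export
build_eigenmode <- function(case, shape = list(l_frac = 0), beta, j = NA_integer_) {
  case <- check_case(case)
  sh <- check_shape(case, shape)
  m <- boundary_matrix(case, beta, shape)
  sv <- svd(m)
  n <- ncol(m)
  if (sv$d[n] > 1e-6 * sv$d[1])
    stop(sprintf("beta = %.8g is not a root of the %s determinant (residual %.2e)",
                 beta, case, sv$d[n] / sv$d[1]))
  if (sv$d[n - 1] < 1e-6 * sv$d[1])
    stop(sprintf("degenerate root at beta = %.8g: null space dimension > 1", beta))
  v <- sv$v[, n]

  gam <- beta * sh$l_frac
  eta <- if (is.null(sh$c_frac)) NA_real_ else beta * sh$c_frac
  xb <- 2 * sqrt(beta); xg <- 2 * sqrt(gam)
  xe <- if (is.na(eta)) NA_real_ else 2 * sqrt(eta)

  regions <- switch(case,
    free_full = list(list(zlo = 0, zhi = beta,
                          co = c(v[1], 0, v[2], 0), scI = xb, scK = 0)),
    free_truncated = list(list(zlo = gam, zhi = beta,
                               co = v, scI = xb, scK = xg)),
    contact_full = list(
      list(zlo = 0, zhi = eta, co = c(v[1], 0, v[2], 0), scI = xe, scK = 0),
      list(zlo = eta, zhi = beta, co = v[3:6], scI = xb, scK = xe)),
    contact_truncated = list(
      list(zlo = gam, zhi = eta, co = v[1:4], scI = xe, scK = xg),
      list(zlo = eta, zhi = beta, co = v[5:8], scI = xb, scK = xe)))

  mode <- structure(list(case = case, shape = sh, j = j, beta = beta,
                         gamma = gam, eta = eta, regions = regions,
                         norm = 1),
                    class = "eigenmode")
  # normalization: int z^2 chi^2 dz = 1, panel break at the support
  brk <- osc_breaks(c(gam, if (!is.na(eta)) eta, beta))
  nrm <- quad_gl(function(z) z^2 * chi_eval(mode, z)^2, brk)
  s <- 1 / sqrt(nrm)
  # deterministic sign: positive at the |chi| local maximum nearest the tip
  zg <- seq(max(gam, 1e-8 * beta), beta, length.out = max(200L, 40L * est_order(mode)))
  a <- abs(chi_eval(mode, zg))
  locmax <- which(diff(sign(diff(a))) < 0) + 1L
  ipk <- if (length(locmax)) locmax[1] else which.max(a)
  if (chi_eval(mode, zg[ipk]) < 0) s <- -s
  for (r in seq_along(mode$regions)) mode$regions[[r]]$co <- mode$regions[[r]]$co * s
  mode$norm <- s
  mode
}

# rough oscillation count, for grid sizing
est_order <- function(mode) {
  max(1L, ceiling((2 * sqrt(mode$beta) - 2 * sqrt(mode$gamma)) / pi))
}

#' Evaluate a dimensionless eigenmode
#'
#' @param mode an \code{"eigenmode"} object.
#' @param z dimensionless coordinates in \code{[gamma, beta]}.
#' @param deriv derivative order 0..4.
#' @return numeric vector \eqn{\chi^{(deriv)}(z)}.
#' @export
chi_eval <- function(mode, z, deriv = 0L) {
  stopifnot(inherits(mode, "eigenmode"), deriv %in% 0:4)
  z <- as.numeric(z)
  out <- numeric(length(z))
  rs <- mode$regions
  if (length(rs) == 1L) {
    r <- rs[[1]]
    out <- chi_region_eval(z, r$co, r$scI, r$scK, deriv)
  } else {
    left <- z <= mode$eta
    if (any(left))
      out[left] <- chi_region_eval(z[left], rs[[1]]$co, rs[[1]]$scI,
                                   rs[[1]]$scK, deriv)
    if (any(!left))
      out[!left] <- chi_region_eval(z[!left], rs[[2]]$co, rs[[2]]$scI,
                                    rs[[2]]$scK, deriv)
  }
  out
}

#' Evaluate a dimensional eigenmode shape
#'
#' \eqn{X^{(n)}(x) = q^{3/2 + n} \chi^{(n)}(q x)} with \eqn{q = \beta / L},
#' normalized so \eqn{\int_\ell^L x^2 X^2 dx = 1}.
#'
#' @param mode an \code{"eigenmode"} object.
#' @param geom the whisker the mode belongs to.
#' @param x positions (m).
#' @param deriv derivative order 0..3.
#' @return numeric vector (units m^(-3/2 - deriv)).
#' @export
eval_eigenmode <- function(mode, geom, x, deriv = 0L) {
  q <- mode$beta / geom$L
  q^(1.5 + deriv) * chi_eval(mode, q * x, deriv)
}

#' @export
print.eigenmode <- function(x, ...) {
  cat(sprintf("Eigenmode (%s)%s: beta = %.6g", x$case,
              if (is.na(x$j)) "" else sprintf(" j = %d", x$j), x$beta))
  if (!is.na(x$eta)) cat(sprintf(", node at c/L = %.3f", x$shape$c_frac))
  cat("\n")
  invisible(x)
}

#' Angular frequency from a dimensionless root
#'
#' \eqn{\omega = (\beta/2)(\xi/L)\sqrt{E/\rho} = (\beta/2)(R/L^2)\sqrt{E/\rho}},
#' the unique frequency for which \eqn{qL = \beta} under
#' \eqn{q^2 = 4\rho\omega^2/(E\xi^2)}.
#'
#' @param geom a [whisker_geometry()] object.
#' @param beta dimensionless root(s).
#' @return angular frequency (rad/s).
#' @export
omega_from_beta <- function(geom, beta) {
  stopifnot(all(beta > 0))
  (beta / 2) * (geom$xi / geom$L) * sqrt(geom$E / geom$rho)
}

#' @rdname omega_from_beta
#' @param omega angular frequency (rad/s).
#' @export
beta_from_omega <- function(geom, omega) {
  2 * omega * geom$L / geom$xi * sqrt(geom$rho / geom$E)
}

#' Young's modulus from a measured fundamental frequency
#'
#' Inverts the eigenfrequency relation for the first mode:
#' \eqn{E = \rho \,(2 \omega L^2 / (\beta_1 R))^2}.
#'
#' @param L extrapolated whisker length (m).
#' @param R base radius (m).
#' @param rho density (kg/m^3).
#' @param omega measured fundamental angular frequency (rad/s).
#' @param beta1 first dimensionless root; defaults to the free full-length
#'   cone value computed from the characteristic equation.
#' @return Young's modulus (Pa).
#' @examples
#' young_modulus_from_frequency(17.14e-3, 37.15e-6, 1000, 962) / 1e9  # ~3.04
#' @export
young_modulus_from_frequency <- function(L, R, rho, omega, beta1 = NULL) {
  if (any(c(L, R, rho, omega) <= 0)) stop("all inputs must be positive")
  if (is.null(beta1)) beta1 <- free_full_beta1()
  rho * (2 * omega * L^2 / (beta1 * R))^2
}

# cached first root of the free full-length cone
free_full_beta1 <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- find_eigenvalues("free_full", n_modes = 1)
    val
  }
})

#' Gram matrix of eigenmodes under the x^2 weight
#'
#' \eqn{G_{ij} = \int_\ell^L x^2 X_i X_j \, dx}, evaluated on a shared
#' composite Gauss-Legendre grid sized for the highest mode, with a forced
#' panel break at the contact point. For correctly built modes this is the
#' identity.
#'
#' @param modes list of \code{"eigenmode"} objects sharing case and shape.
#' @return numeric matrix.
#' @export
orthogonality_matrix <- function(modes) {
  stopifnot(length(modes) >= 1, all(vapply(modes, inherits, TRUE, "eigenmode")))
  case <- modes[[1]]$case; sh <- modes[[1]]$shape
  if (!all(vapply(modes, function(m) identical(m$case, case) &&
                  isTRUE(all.equal(m$shape, sh)), TRUE)))
    stop("all modes must share boundary case and shape")
  betas <- vapply(modes, `[[`, 0, "beta")
  # integrate in s = x/L: G_ij = (beta_i beta_j)^{3/2} int s^2 chi_i(b_i s) chi_j(b_j s) ds
  brk_s <- sort(unique(c(
    (osc_breaks(c(sh$l_frac, if (!is.null(sh$c_frac)) sh$c_frac, 1) *
                  max(betas), per_osc = 8) / max(betas)))))
  g <- gl_grid(brk_s)
  V <- vapply(modes, function(m) m$beta^1.5 * chi_eval(m, m$beta * g$x), g$x)
  t(V) %*% (V * (g$w * g$x^2))
}

#' Full eigenmode basis for a whisker
#'
#' Convenience constructor: picks the boundary case from the geometry and
#' the (optional) contact position, finds the first \code{n_modes} roots,
#' builds the normalized modes and attaches dimensional frequencies.
#'
#' @param geom a [whisker_geometry()] object.
#' @param c_pos contact position in m (or use \code{c_frac}); \code{NULL}
#'   for free vibration.
#' @param c_frac contact position as a fraction of \code{L}.
#' @param n_modes number of modes.
#' @return object of class \code{"whisker_modes"}: list with \code{modes},
#'   \code{beta}, \code{omega} (rad/s), \code{case}, \code{shape},
#'   \code{geom}.
#' @examples
#' w <- standard_whisker()
#' b <- eigenmode_basis(w, c_frac = 0.6, n_modes = 5)
#' b$omega / (2 * pi)    # contact-constrained frequencies in Hz
#' @export
eigenmode_basis <- function(geom, c_pos = NULL, c_frac = NULL, n_modes = 10) {
  stopifnot(inherits(geom, "whisker_geometry"))
  l_frac <- geom$trunc / geom$L
  contact <- !is.null(c_pos) || !is.null(c_frac)
  if (contact) {
    cc <- contact_position(geom, c_pos, c_frac)
    cf <- cc / geom$L
  } else cf <- NULL
  case <- if (contact) {
    if (l_frac == 0) "contact_full" else "contact_truncated"
  } else {
    if (l_frac == 0) "free_full" else "free_truncated"
  }
  shape <- list(l_frac = l_frac, c_frac = cf)
  betas <- find_eigenvalues(case, shape, n_modes)
  modes <- lapply(seq_along(betas), function(j)
    build_eigenmode(case, shape, betas[j], j = j))
  structure(list(geom = geom, case = case, shape = shape, modes = modes,
                 beta = betas, omega = omega_from_beta(geom, betas)),
            class = "whisker_modes")
}

#' @export
print.whisker_modes <- function(x, ...) {
  cat(sprintf("%d %s eigenmodes", length(x$modes), x$case))
  if (!is.null(x$shape$c_frac))
    cat(sprintf(" (contact at c/L = %.3f)", x$shape$c_frac))
  cat("\n  beta : ", paste(sprintf("%.3f", utils::head(x$beta, 6)), collapse = ", "),
      if (length(x$beta) > 6) ", ...", "\n", sep = "")
  cat("  f(Hz): ", paste(sprintf("%.1f", utils::head(x$omega / (2 * pi), 6)),
                         collapse = ", "),
      if (length(x$beta) > 6) ", ...", "\n", sep = "")
  invisible(x)
}

# matrix of dimensional mode values on an x grid (nx x nmodes, also for nx = 1)
basis_matrix <- function(basis, x, deriv = 0L) {
  x <- as.numeric(x)
  m <- vapply(basis$modes, eval_eigenmode, numeric(length(x)),
              geom = basis$geom, x = x, deriv = deriv)
  matrix(m, nrow = length(x))
}
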