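# Object-distance cue analyses: how eigenfrequencies, modal excitation and
# the vibrational/quasi-static force balance at the follicle depend on where
# along the whisker the object is touched.

sweep_result <- function(df, kind, meta) {
  attr(df, "kind") <- kind
  attr(df, "meta") <- meta
  class(df) <- c("whisker_sweep", "data.frame")
  df
}

#' @export
print.whisker_sweep <- function(x, ...) {
  cat(sprintf("Whisker sweep (%s), %d rows\n", attr(x, "kind"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 8), ...)
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' Contact-position dependence of eigenfrequencies
#'
#' Dimensionless eigenfrequencies \eqn{\beta_j} of the contact-constrained
#' whisker as the pole position sweeps along the whisker. The mode-1 curve is
#' single-peaked; mode j has j peaks. \eqn{\beta} depends only on the shape
#' ratios, so the curves are independent of E, rho and R; dimensional
#' frequencies for \code{geom} are attached.
#'
#' @param geom a [whisker_geometry()] object (truncation sets the boundary
#'   case; material constants only scale \code{omega}).
#' @param c_frac_grid strictly increasing contact positions (fractions of L)
#'   inside \code{(trunc/L, 1)}.
#' @param n_modes number of modes per grid point.
#' @return \code{"whisker_sweep"} data.frame with columns
#'   \code{c_frac, mode, beta, omega}.
#' @export
frequency_sweep <- function(geom, c_frac_grid, n_modes = 5) {
  stopifnot(inherits(geom, "whisker_geometry"))
  l_frac <- geom$trunc / geom$L
  if (any(diff(c_frac_grid) <= 0)) stop("c_frac_grid must be strictly increasing")
  if (any(c_frac_grid <= l_frac | c_frac_grid >= 1))
    stop("contact grid must lie inside (trunc/L, 1)")
  case <- if (l_frac == 0) "contact_full" else "contact_truncated"
  rows <- lapply(c_frac_grid, function(cf) {
    b <- find_eigenvalues(case, list(l_frac = l_frac, c_frac = cf), n_modes)
    data.frame(c_frac = cf, mode = seq_along(b), beta = b,
               omega = omega_from_beta(geom, b))
  })
  sweep_result(do.call(rbind, rows), "frequency_vs_contact",
               list(l_frac = l_frac, case = case, geom = geom))
}

#' Truncation dependence of contact eigenfrequencies
#'
#' \eqn{\beta_j} as a function of truncation length at a fixed pole position.
#' Truncation barely moves the first mode and increasingly shifts higher
#' modes.
#'
#' @param l_frac_grid strictly increasing truncation fractions in
#'   \code{[0, c_frac)}; 0 selects the full-length contact case.
#' @param c_frac fixed contact position (fraction of L).
#' @param n_modes number of modes per grid point.
#' @return \code{"whisker_sweep"} data.frame with columns
#'   \code{l_frac, mode, beta}.
#' @export
truncation_sweep <- function(l_frac_grid, c_frac = 0.6, n_modes = 5) {
  if (any(diff(l_frac_grid) <= 0)) stop("l_frac_grid must be strictly increasing")
  if (any(l_frac_grid < 0 | l_frac_grid >= c_frac))
    stop("truncation grid must lie in [0, c_frac)")
  rows <- lapply(l_frac_grid, function(lf) {
    case <- if (lf == 0) "contact_full" else "contact_truncated"
    b <- find_eigenvalues(case, list(l_frac = lf, c_frac = c_frac), n_modes)
    data.frame(l_frac = lf, mode = seq_along(b), beta = b)
  })
  sweep_result(do.call(rbind, rows), "frequency_vs_truncation",
               list(c_frac = c_frac))
}

# contact-phase peak modal amplitudes for one (c, profile) configuration
peak_amplitudes <- function(geom, c_frac, profile, n_modes, basis = NULL,
                            P = NULL, dt = 2e-6) {
  static <- static_deflection(geom, c_frac = c_frac, F = 1)
  if (is.null(basis)) basis <- eigenmode_basis(geom, c_frac = c_frac,
                                               n_modes = n_modes)
  tg <- unique(c(seq(0, profile$t_f, by = dt), profile$t_f))
  co <- contact_coefficients(basis, static, profile, tg, P = P)
  list(amp = apply(abs(co$phi), 2, max), basis = basis, P = co$P)
}

#' Modal excitation spectra
#'
#' Peak absolute modal coefficient \eqn{\max_t |\phi_j(t)|} over the contact
#' window, swept over the onset duration \code{tau} (fixed contact point) or
#' over the contact position (fixed \code{tau}). Spectra are reported raw and
#' normalized to the strongest mode per sweep point.
#'
#' @param geom a [whisker_geometry()] object.
#' @param c_frac contact position (fraction of L); a vector when
#'   \code{sweep = "contact"}.
#' @param profile reference [force_profile()] (Gaussian); its \code{tau} is
#'   replaced per point when \code{sweep = "tau"}.
#' @param tau onset durations (s) when \code{sweep = "tau"}.
#' @param sweep \code{"tau"} or \code{"contact"}.
#' @param n_modes number of modes.
#' @return \code{"whisker_sweep"} data.frame with columns \code{tau} or
#'   \code{c_frac}, \code{mode}, \code{amplitude}, \code{normalized}.
#' @export
excitation_spectrum <- function(geom, c_frac = 0.6,
                                profile = force_profile(),
                                tau = c(0.05e-3, 0.1e-3),
                                sweep = c("tau", "contact"),
                                n_modes = 16) {
  sweep <- match.arg(sweep)
  stopifnot(inherits(geom, "whisker_geometry"),
            profile$kind == "gaussian_smooth")
  if (sweep == "tau") {
    basis <- eigenmode_basis(geom, c_frac = c_frac, n_modes = n_modes)
    P <- modal_projection(static_deflection(geom, c_frac = c_frac), basis)
    rows <- lapply(tau, function(tv) {
      pf <- force_profile("gaussian_smooth", F_max = profile$F_max,
                          t_f = profile$t_f, tau = tv, C = profile$C)
      a <- peak_amplitudes(geom, c_frac, pf, n_modes, basis = basis, P = P)$amp
      data.frame(tau = tv, mode = seq_along(a), amplitude = a,
                 normalized = a / max(a))
    })
    sweep_result(do.call(rbind, rows), "excitation_vs_tau",
                 list(c_frac = c_frac, profile = profile))
  } else {
    rows <- lapply(c_frac, function(cf) {
      a <- peak_amplitudes(geom, cf, profile, n_modes)$amp
      data.frame(c_frac = cf, mode = seq_along(a), amplitude = a,
                 normalized = a / max(a))
    })
    sweep_result(do.call(rbind, rows), "excitation_vs_contact",
                 list(profile = profile))
  }
}

#' Vibrational versus quasi-static follicle forces
#'
#' For each contact position, decomposes the base bending moment and shear
#' into quasi-static (\eqn{F(t)(L-c)}, \eqn{F(t)}) and vibrational mode-sum
#' components over the contact window, and reports
#' \describe{
#'   \item{average ratio}{time-average of the absolute vibrational component
#'     divided by the time-average of the absolute quasi-static component
#'     (robust to the zero crossings of the static part at onset/offset);}
#'   \item{maximum ratio}{peak absolute vibrational over peak absolute
#'     quasi-static component.}
#' }
#' Both are invariant to \code{F_max} (the problem is linear).
#'
#' @param geom a [whisker_geometry()] object.
#' @param profile a Gaussian [force_profile()].
#' @param c_frac_grid contact positions (fractions of L).
#' @param n_modes number of contact modes (the shear sum converges slowly;
#'   ~100 modes reproduce the converged values to <0.1\%).
#' @param dt time step for the contact-window statistics (s).
#' @return \code{"whisker_sweep"} data.frame with columns \code{c_frac},
#'   \code{M_ratio_avg}, \code{M_ratio_max}, \code{V_ratio_avg},
#'   \code{V_ratio_max}.
#' @export
ratio_analysis <- function(geom, profile = force_profile(),
                           c_frac_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                           n_modes = 100, dt = 2e-6) {
  stopifnot(inherits(geom, "whisker_geometry"),
            profile$kind == "gaussian_smooth")
  EI0 <- geom$E * geom$I0
  rows <- lapply(c_frac_grid, function(cf) {
    static <- static_deflection(geom, c_frac = cf, F = 1)
    basis <- eigenmode_basis(geom, c_frac = cf, n_modes = n_modes)
    tg <- unique(c(seq(0, profile$t_f, by = dt), profile$t_f))
    co <- contact_coefficients(basis, static, profile, tg)
    X2 <- as.numeric(basis_matrix(basis, geom$L, deriv = 2L))
    X3 <- as.numeric(basis_matrix(basis, geom$L, deriv = 3L))
    Fv <- force_eval(profile, tg)
    Ms <- Fv * (geom$L - cf * geom$L); Vs <- Fv
    Mv <- EI0 * as.numeric(co$phi %*% X2)
    Vv <- EI0 * as.numeric(co$phi %*% (4 * X2 / geom$L + X3))
    data.frame(c_frac = cf,
               M_ratio_avg = mean(abs(Mv)) / mean(abs(Ms)),
               M_ratio_max = max(abs(Mv)) / max(abs(Ms)),
               V_ratio_avg = mean(abs(Vv)) / mean(abs(Vs)),
               V_ratio_max = max(abs(Vv)) / max(abs(Vs)))
  })
  sweep_result(do.call(rbind, rows), "vibrational_static_ratio",
               list(profile = profile, n_modes = n_modes, geom = geom))
}

#' Rate of change of the two candidate distance cues
#'
#' Percent change per millimetre of (i) the fundamental contact-constrained
#' eigenfrequency and (ii) the axial-to-lateral force ratio, as functions of
#' contact position, via centred differences of \eqn{100\, d\ln y / dc}.
#'
#' Comparing the force ratio across contact positions requires a choice of
#' what is held fixed as the pole moves. Touches are normalized to a constant
#' (small) push angle \code{theta}: the pole at \code{c} imposes a deflection
#' \eqn{\delta = \theta (L - c)}, so the applied force is
#' \eqn{F(c) = \theta (L - c) / \tilde y_s(c)} and the ratio becomes
#' \eqn{\tan[\theta (L + 2c)/(2c)]} in the small-angle limit. This is the
#' kinematically natural normalization (the animal controls the whisking
#' angle, not the contact force) and it yields the characteristic flat
#' proximal ratio curve that steepens dramatically toward the tip. The
#' percent-per-mm rates are invariant to \code{theta} and to uniform
#' rescaling of E (frequency).
#'
#' @param geom a [whisker_geometry()] object.
#' @param c_frac_grid contact positions (fractions of L), strictly
#'   increasing, at least 3 points.
#' @param theta push angle used to normalize touches (rad).
#' @return \code{"whisker_sweep"} data.frame with columns \code{c_frac},
#'   \code{omega1}, \code{force_ratio}, \code{freq_pct_per_mm},
#'   \code{ratio_pct_per_mm} (rates are absolute values; NA at the ends).
#' @export
rate_of_change_comparison <- function(geom, c_frac_grid, theta = 1e-3) {
  stopifnot(inherits(geom, "whisker_geometry"), length(c_frac_grid) >= 3)
  l_frac <- geom$trunc / geom$L
  case <- if (l_frac == 0) "contact_full" else "contact_truncated"
  om1 <- vapply(c_frac_grid, function(cf)
    omega_from_beta(geom,
      find_eigenvalues(case, list(l_frac = l_frac, c_frac = cf), 1)), 0)
  fr <- vapply(c_frac_grid, function(cf) {
    st <- static_deflection(geom, c_frac = cf, F = 1)
    Fc <- theta * (geom$L - st$c_pos) / st$ytilde(st$c_pos)
    axial_lateral_ratio(geom, c_frac = cf, F = Fc)
  }, 0)
  cmm <- c_frac_grid * geom$L * 1e3      # contact position in mm
  rate <- function(y) {
    n <- length(y)
    r <- rep(NA_real_, n)
    r[2:(n - 1)] <- 100 * abs((y[3:n] - y[1:(n - 2)]) /
                              (cmm[3:n] - cmm[1:(n - 2)])) / y[2:(n - 1)]
    r
  }
  sweep_result(data.frame(c_frac = c_frac_grid, omega1 = om1,
                          force_ratio = fr,
                          freq_pct_per_mm = rate(om1),
                          ratio_pct_per_mm = rate(fr)),
               "cue_rate_of_change", list(geom = geom, case = case))
}
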