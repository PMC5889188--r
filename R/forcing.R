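#' Time-dependent contact force profiles
#'
#' Two force shapes are supported. \code{"gaussian_smooth"} is the upper part
#' of a Gaussian, cut at a fraction \code{C} of its peak so that the force
#' vanishes at the detachment time \code{t_f}, preceded by a quartic smooth
#' onset of duration \code{tau} that makes the force and its first two time
#' derivatives start from zero and join the Gaussian continuously at
#' \code{t = tau}. \code{"ramp"} is the instantaneous-onset linear force
#' \eqn{F = s t} used for wave-propagation analysis (its second derivative is
#' a Dirac impulse at \code{t = 0}, handled analytically downstream).
#'
#' The Gaussian centre \code{a} is solved from the onset-continuity condition
#' \eqn{F_s(\tau) = F_G(\tau)} with \eqn{F_s(\tau) = (\tau/2)\dot F_G(\tau) -
#' (\tau^2/12)\ddot F_G(\tau)}, and the width from the cutoff condition
#' \eqn{b = (t_f - a)/\sqrt{\ln(1/C)}}.
#'
#' @param kind \code{"gaussian_smooth"} or \code{"ramp"}.
#' @param F_max peak force (N); attained at \code{t = a}.
#' @param t_f contact duration (s).
#' @param tau smooth-onset duration (s); must satisfy \code{tau <= t_f / 10}.
#' @param C Gaussian cutoff, \code{0 < C < 1} (\code{C -> 0} recovers the
#'   uncut Gaussian).
#' @param s ramp slope (N/s), ramp profile only.
#' @return object of class \code{"force_profile"} with solved parameters
#'   \code{a}, \code{b} and onset polynomial coefficients.
#' @examples
#' fp <- force_profile(F_max = 1e-6, t_f = 10e-3, tau = 0.1e-3, C = 0.5)
#' force_eval(fp, fp$a)               # equals F_max
#' force_eval(fp, fp$t_f)             # 0 at detachment
#' @export
force_profile <- function(kind = c("gaussian_smooth", "ramp"),
                          F_max = 1e-6, t_f = 10e-3, tau = 0.1e-3, C = 0.5,
                          s = 1e-4) {
  kind <- match.arg(kind)
  if (kind == "ramp") {
    stopifnot(is.finite(s))
    return(structure(list(kind = "ramp", s = s, t_f = Inf),
                     class = "force_profile"))
  }
  stopifnot(F_max > 0, t_f > 0, tau > 0, C > 0, C < 1)
  if (tau > t_f / 10)
    stop("smooth-onset duration must satisfy tau <= t_f / 10")
  lnC <- sqrt(log(1 / C))
  gauss <- function(t, a, d = 0L) {
    b <- (t_f - a) / lnC
    u <- (t - a) / b
    e <- exp(-u^2)
    switch(d + 1L,
      F_max / (1 - C) * (e - C),
      -2 * F_max / (b * (1 - C)) * u * e,
      2 * F_max / (b^2 * (1 - C)) * (2 * u^2 - 1) * e)
  }
  resid <- function(a)
    (tau / 2) * gauss(tau, a, 1L) - (tau^2 / 12) * gauss(tau, a, 2L) -
      gauss(tau, a, 0L)
  sol <- tryCatch(
    stats::uniroot(resid, c(tau * (1 + 1e-9), t_f * (1 - 1e-9)),
                   tol = .Machine$double.eps),
    error = function(e) stop("no Gaussian centre a in (tau, t_f) for these parameters"))
  a <- sol$root
  b <- (t_f - a) / lnC
  d1 <- gauss(tau, a, 1L); d2 <- gauss(tau, a, 2L)
  # onset F_s(t) = A3 (t/tau)^3 + A4 (t/tau)^4
  A3 <- (tau / 3) * (3 * d1 - tau * d2)
  A4 <- (tau / 4) * (tau * d2 - 2 * d1)
  structure(list(kind = "gaussian_smooth", F_max = F_max, t_f = t_f,
                 tau = tau, C = C, a = a, b = b, A3 = A3, A4 = A4),
            class = "force_profile")
}

#' @export
print.force_profile <- function(x, ...) {
  if (x$kind == "ramp") {
    cat(sprintf("Ramp force: F = %.3g * t N\n", x$s))
  } else {
    cat(sprintf("Smooth-onset truncated Gaussian force\n"))
    cat(sprintf("  F_max = %.3g N at t = %.4g ms, width b = %.4g ms\n",
                x$F_max, x$a * 1e3, x$b * 1e3))
    cat(sprintf("  contact %.3g ms, onset tau = %.3g ms, cutoff C = %.2f\n",
                x$t_f * 1e3, x$tau * 1e3, x$C))
  }
  invisible(x)
}

#' Evaluate a force profile or its time derivatives
#'
#' Piecewise evaluation: the quartic onset on \code{[0, tau]}, the truncated
#' Gaussian on \code{[tau, t_f]}, zero before contact and after detachment.
#' For the ramp, \code{F = s t} for \code{t > 0} with \code{dF = s} and
#' \code{ddF = 0} there (the impulsive second derivative at the origin is
#' treated analytically by [contact_coefficients()]).
#'
#' @param profile a [force_profile()] object.
#' @param t times (s).
#' @param derivative 0, 1 or 2.
#' @return numeric vector (N, N/s or N/s^2).
#' @export
force_eval <- function(profile, t, derivative = 0L) {
  stopifnot(inherits(profile, "force_profile"), derivative %in% 0:2)
  t <- as.numeric(t)
  d <- as.integer(derivative)
  if (profile$kind == "ramp") {
    out <- switch(d + 1L, profile$s * t, rep(profile$s, length(t)),
                  numeric(length(t)))
    out[t < 0] <- 0
    if (d == 0L) out[t == 0] <- 0
    return(out)
  }
  with(profile, {
    out <- numeric(length(t))
    i1 <- t >= 0 & t < tau
    i2 <- t >= tau & t <= t_f
    u <- (t[i2] - a) / b
    e <- exp(-u^2)
    r <- t[i1] / tau
    if (d == 0L) {
      out[i1] <- A3 * r^3 + A4 * r^4
      out[i2] <- F_max / (1 - C) * (e - C)
    } else if (d == 1L) {
      out[i1] <- (3 * A3 * r^2 + 4 * A4 * r^3) / tau
      out[i2] <- -2 * F_max / (b * (1 - C)) * u * e
    } else {
      out[i1] <- (6 * A3 * r + 12 * A4 * r^2) / tau^2
      out[i2] <- 2 * F_max / (b^2 * (1 - C)) * (2 * u^2 - 1) * e
    }
    out
  })
}
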