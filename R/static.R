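#' Quasi-static deflection of a conical whisker under a point force
#'
#' Closed-form small-angle solution of the beam equation
#' \eqn{y'' = M(x)/(E I(x))} for a point force \code{F} applied at
#' \code{x = c} with a clamped base (\eqn{y(L) = y'(L) = 0}) and free tip.
#' Between tip and contact the whisker stays straight (zero moment) and the
#' deflection continues linearly; between contact and base it is a cubic in
#' \eqn{1/x} plus a linear part.
#'
#' @param geom a [whisker_geometry()] object.
#' @param c_pos contact position (m from the virtual tip); alternatively give
#'   \code{c_frac}.
#' @param F applied transverse force (N); positive pushes in +y.
#' @param c_frac contact position as a fraction of \code{L}.
#'
#' @return An object of class \code{"whisker_static"}: a list with
#'   \describe{
#'     \item{y, yp}{deflection and slope functions of \code{x} (m, rad)}
#'     \item{ytilde, yptilde}{the same per unit force (the factorized form
#'       \eqn{y_s(x,t) = F(t) \tilde y_s(x)})}
#'     \item{moment}{bending-moment profile \code{M(x)} (N m)}
#'     \item{base_moment, base_shear}{\code{F (L - c)} and \code{F}}
#'   }
#' @examples
#' w <- standard_whisker()
#' s <- static_deflection(w, c_frac = 0.6, F = 1e-6)
#' s$y(s$c_pos)        # deflection at the contact point
#' s$base_moment
#' @export
static_deflection <- function(geom, c_pos = NULL, F = 1, c_frac = NULL) {
  stopifnot(inherits(geom, "whisker_geometry"))
  cc <- contact_position(geom, c_pos, c_frac)
  if (!is.numeric(F) || length(F) != 1L || !is.finite(F))
    stop("force F must be a single finite number")
  L <- geom$L; E <- geom$E; xi <- geom$xi
  k <- 2 / (3 * pi * E * xi^4)           # common prefactor, per unit force
  y_c  <- 2 * k / L^3 * (L - cc)^3 / cc
  yp_c <- k / L^3 * (3 * L * cc^2 - L^3 - 2 * cc^3) / cc^2

  ytilde <- function(x) {
    x <- as.numeric(x)
    out <- ifelse(x <= cc,
                  yp_c * (x - cc) + y_c,
                  k * ((3 * x - cc) / x^2 +
                       ((3 * L - 2 * cc) * x + 3 * L * (cc - 2 * L)) / L^3))
    out
  }
  yptilde <- function(x) {
    x <- as.numeric(x)
    ifelse(x <= cc, yp_c,
           k * ((2 * cc - 3 * x) / x^3 + (3 * L - 2 * cc) / L^3))
  }
  moment <- function(x) ifelse(x <= cc, 0, (x - cc) * F)

  structure(list(
    geom = geom, c_pos = cc, F = F,
    ytilde = ytilde, yptilde = yptilde,
    y  = function(x) F * ytilde(x),
    yp = function(x) F * yptilde(x),
    moment = moment,
    base_moment = F * (L - cc),
    base_shear = F
  ), class = "whisker_static")
}

#' @export
print.whisker_static <- function(x, ...) {
  cat("Quasi-static point-force solution\n")
  cat(sprintf("  contact at c = %.3f mm (c/L = %.3f), F = %.3g N\n",
              x$c_pos * 1e3, x$c_pos / x$geom$L, x$F))
  cat(sprintf("  y(c) = %.4g m, base moment = %.4g N m, base shear = %.4g N\n",
              x$y(x$c_pos), x$base_moment, x$base_shear))
  invisible(x)
}

#' Static bending moment profile and base reactions
#'
#' The moment vanishes tipward of the contact and grows linearly with lever
#' arm toward the base: \code{M(x) = (x - c) F} for \code{c <= x <= L}. The
#' base reactions are \code{M(L) = F (L - c)} and shear \code{V(L) = F}.
#'
#' @inheritParams static_deflection
#' @return list with \code{moment} (function of x), \code{base_moment} and
#'   \code{base_shear}.
#' @export
static_moment_and_shear <- function(geom, c_pos = NULL, F = 1, c_frac = NULL) {
  s <- static_deflection(geom, c_pos, F, c_frac)
  list(moment = s$moment, base_moment = s$base_moment,
       base_shear = s$base_shear)
}

#' Axial-to-lateral force ratio at the follicle
#'
#' Under the small-angle static solution the whisker axis at the base stays
#' horizontal (clamped), while at the contact point it is rotated by the
#' local slope. The applied force is normal to the whisker there, so the
#' tangent of the base-to-contact slope difference measures the ratio of the
#' axial to the lateral force component felt at the follicle:
#' \eqn{F_{ax}/F_{lat} = \tan|y_s'(c)|}. This is an interpretation of a
#' quantity the underlying derivation never writes explicitly; it is
#' validated only qualitatively (shape of the distance dependence).
#'
#' @inheritParams static_deflection
#' @return dimensionless ratio (monotone in the applied force for fixed c).
#' @export
axial_lateral_ratio <- function(geom, c_pos = NULL, F = 1, c_frac = NULL) {
  s <- static_deflection(geom, c_pos, F, c_frac)
  tan(abs(s$yp(s$c_pos)))
}
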