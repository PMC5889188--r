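#' Conical whisker geometry and material parameters
#'
#' Constructs the physical description of a (possibly truncated) conical
#' whisker. The coordinate axis runs from the extrapolated virtual tip at
#' \code{x = 0} to the base (follicle) at \code{x = L}; the real, possibly
#' trimmed tip sits at \code{x = trunc}. All quantities are SI.
#'
#' @param L extrapolated length from virtual tip to base (m).
#' @param R radius at the base (m).
#' @param trunc truncation length: position of the real tip (m); 0 for a
#'   full-length cone.
#' @param rho volume density (kg/m^3).
#' @param E Young's modulus (Pa).
#' @param alpha frequency-independent viscous damping constant (rad/s).
#'
#' @return An object of class \code{"whisker_geometry"}: a list with the
#'   fields above plus the taper ratio \code{xi = R/L} and the base area
#'   moment \code{I0 = (pi/4) R^4}.
#' @examples
#' w <- whisker_geometry(L = 18e-3, R = 37e-6, trunc = 0.9e-3,
#'                       rho = 1000, E = 3e9, alpha = 430)
#' w$xi
#' @export
whisker_geometry <- function(L, R, trunc = 0, rho = 1000, E, alpha = 0) {
  stopifnot(is.numeric(L), is.numeric(R), is.numeric(trunc),
            is.numeric(rho), is.numeric(E), is.numeric(alpha))
  if (!all(is.finite(c(L, R, trunc, rho, E, alpha))))
    stop("whisker geometry parameters must be finite")
  if (L <= 0 || R <= 0 || rho <= 0 || E <= 0)
    stop("L, R, rho and E must be positive")
  if (trunc < 0 || trunc >= L)
    stop("truncation length must satisfy 0 <= trunc < L")
  if (alpha < 0) stop("damping constant alpha must be non-negative")
  structure(list(L = L, R = R, trunc = trunc, rho = rho, E = E,
                 alpha = alpha, xi = R / L, I0 = (pi / 4) * R^4),
            class = "whisker_geometry")
}

#' Reference whisker used throughout the examples
#'
#' A linearly tapered cone truncated at 5\% of the extrapolated length with
#' \code{L} = 18 mm, \code{R} = 37 um, \code{rho} = 1.0 g/cm^3,
#' \code{E} = 3.0 GPa and \code{alpha} = 430 rad/s — parameter values close
#' to those measured for a mouse C2 whisker.
#'
#' @param trunc_frac truncation as a fraction of \code{L} (default 0.05).
#' @return a \code{"whisker_geometry"} object.
#' @export
standard_whisker <- function(trunc_frac = 0.05) {
  whisker_geometry(L = 18e-3, R = 37e-6, trunc = trunc_frac * 18e-3,
                   rho = 1000, E = 3.0e9, alpha = 430)
}

#' @export
print.whisker_geometry <- function(x, ...) {
  cat("Conical whisker\n")
  cat(sprintf("  L      = %.3f mm (virtual tip to base)\n", x$L * 1e3))
  cat(sprintf("  tip at = %.3f mm (trunc/L = %.3f)\n",
              x$trunc * 1e3, x$trunc / x$L))
  cat(sprintf("  R      = %.2f um   (taper xi = %.3e)\n", x$R * 1e6, x$xi))
  cat(sprintf("  E      = %.3g GPa, rho = %.3g kg/m^3, alpha = %.3g rad/s\n",
              x$E / 1e9, x$rho, x$alpha))
  invisible(x)
}

#' Radius, area moment and linear density profiles
#'
#' For a linear cone, \code{r(x) = xi x}, \code{I(x) = (pi/4) xi^4 x^4} and
#' \code{mu(x) = rho pi xi^2 x^2}.
#'
#' @param geom a \code{"whisker_geometry"} object.
#' @param x axial positions (m), measured from the virtual tip.
#' @return numeric vector.
#' @export
whisker_radius <- function(geom, x) geom$xi * x

#' @rdname whisker_radius
#' @export
area_moment <- function(geom, x) (pi / 4) * (geom$xi * x)^4

#' @rdname whisker_radius
#' @export
linear_density <- function(geom, x) geom$rho * pi * (geom$xi * x)^2

#' Validate an object-contact position
#'
#' The pole (simple support / point force) must lie strictly between the
#' real tip and the base.
#'
#' @param geom a \code{"whisker_geometry"} object.
#' @param c_pos axial contact coordinate (m from the virtual tip), or
#'   \code{NULL} if \code{c_frac} is given.
#' @param c_frac contact position as a fraction of \code{L}.
#' @return the contact coordinate in metres (invisibly validated).
#' @export
contact_position <- function(geom, c_pos = NULL, c_frac = NULL) {
  if (is.null(c_pos)) {
    if (is.null(c_frac)) stop("supply c_pos (m) or c_frac (fraction of L)")
    c_pos <- c_frac * geom$L
  }
  if (!is.numeric(c_pos) || length(c_pos) != 1L || !is.finite(c_pos))
    stop("contact position must be a single finite number")
  if (c_pos <= geom$trunc || c_pos >= geom$L)
    stop(sprintf("contact must lie strictly inside (tip, base) = (%g, %g) m",
                 geom$trunc, geom$L))
  c_pos
}

# distance from follicle (user-facing convenience; x measured from virtual tip)
#' Convert an axial coordinate to distance from the follicle
#' @param geom a \code{"whisker_geometry"} object.
#' @param x axial position(s) (m from the virtual tip).
#' @return \code{L - x}, the distance from the base (m).
#' @export
distance_from_follicle <- function(geom, x) geom$L - x
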