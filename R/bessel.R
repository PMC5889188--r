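# Bessel basis for the dimensionless conical-beam mode equation (internal).
#
# The fourth-order mode equation (z^4 chi'')'' = z^2 chi has the four
# independent solutions J2(2 sqrt z)/z, Y2(2 sqrt z)/z, I2(2 sqrt z)/z,
# K2(2 sqrt z)/z. Their n-th derivatives follow the ladder
#   d^n/dz^n [ Cnu(2 sqrt z)/z ] = s^n C_{2+n}(2 sqrt z) / z^{(2+n)/2},
# with s = -1 for J, Y, K and s = +1 for I.
#
# The modified Bessel terms grow/decay like exp(+-2 sqrt z). Every basis
# evaluation is therefore exponentially rescaled: the I term carries
# exp(2 sqrt z - scI) and the K term exp(scK - 2 sqrt z), where scI / scK are
# fixed per region (largest / smallest argument in that region). Coefficient
# vectors obtained from the similarly column-scaled boundary matrices refer
# to this scaled basis, so mode evaluation never forms an unscaled I or K.

# one basis family value: kind in {"J","Y","I","K"}, base order 2,
# derivative n >= 0, argument vector z >= 0, scale reference sc (I/K only)
bessel_basis <- function(kind, z, n = 0L, sc = 0) {
  ord <- 2L + n
  x <- 2 * sqrt(z)
  sgn <- if (kind == "I") 1 else (-1)^n
  v <- switch(kind,
    J = besselJ(x, ord),
    Y = besselY(x, ord),
    I = besselI(x, ord, expon.scaled = TRUE) * exp(x - sc),
    K = besselK(x, ord, expon.scaled = TRUE) * exp(sc - x))
  out <- sgn * v / z^(ord / 2)
  # z -> 0 limits: J and I terms tend to s^n / (2+n)!, Y and K diverge
  small <- z == 0
  if (any(small)) {
    lim <- switch(kind,
      J = (-1)^n / factorial(ord), I = exp(-sc) / factorial(ord),
      Y = -Inf, K = Inf)
    out[small] <- lim
  }
  out
}

# evaluate c1 J + c2 Y + c3 I + c4 K (scaled basis) and derivatives
chi_region_eval <- function(z, co, scI, scK, n = 0L) {
  out <- 0
  if (co[1] != 0) out <- out + co[1] * bessel_basis("J", z, n)
  if (co[2] != 0) out <- out + co[2] * bessel_basis("Y", z, n)
  if (co[3] != 0) out <- out + co[3] * bessel_basis("I", z, n, scI)
  if (co[4] != 0) out <- out + co[4] * bessel_basis("K", z, n, scK)
  out
}
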