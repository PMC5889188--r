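# Composite Gauss-Legendre quadrature (internal).
#
# The eigenmode integrands oscillate uniformly in nu = 2 sqrt(z), not in z,
# so panel edges are placed uniformly in nu between forced break points
# (region boundaries, the contact-point kink). 16-node panels give machine
# precision at >= 6 panels per oscillation.

# 16-point Gauss-Legendre nodes/weights on [-1, 1] (symmetric; full vectors)
.gl16 <- local({
  x <- c(0.0950125098376374, 0.2816035507792589, 0.4580167776572274,
         0.6178762444026438, 0.7554044083550030, 0.8656312023878318,
         0.9445750230732326, 0.9894009349916499)
  w <- c(0.1894506104550685, 0.1826034150449236, 0.1691565193950025,
         0.1495959888165767, 0.1246289712555339, 0.0951585116824928,
         0.0622535239386479, 0.0271524594117541)
  list(x = c(-rev(x), x), w = c(rev(w), w))
})

# nodes/weights for panels delimited by `breaks` (strictly increasing)
gl_grid <- function(breaks) {
  breaks <- as.numeric(breaks)
  nb <- length(breaks) - 1L
  half <- diff(breaks) / 2
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  x <- as.vector(outer(.gl16$x, half) + rep(mid, each = 16L))
  w <- as.vector(outer(.gl16$w, half))
  list(x = x, w = w)
}

# panel breaks uniform in nu = 2 sqrt(z) between forced breakpoints `zbrk`,
# with about `per_osc` panels per pi of nu plus a floor
osc_breaks <- function(zbrk, per_osc = 6, min_panels = 8) {
  zbrk <- sort(unique(as.numeric(zbrk)))
  nu <- 2 * sqrt(pmax(zbrk, 0))
  out <- numeric(0)
  for (i in seq_len(length(zbrk) - 1L)) {
    n <- max(min_panels, ceiling(per_osc * (nu[i + 1] - nu[i]) / pi))
    nus <- seq(nu[i], nu[i + 1], length.out = n + 1L)
    seg <- (nus / 2)^2
    seg[1] <- zbrk[i]; seg[length(seg)] <- zbrk[i + 1]
    out <- c(out[-length(out)], seg)
  }
  out
}

# integrate f over panels defined by breaks
quad_gl <- function(f, breaks) {
  g <- gl_grid(breaks)
  sum(g$w * f(g$x))
}
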