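# shared fixtures: the reference modelling whisker and the measured C2 dims

std_whisker <- function(alpha = 430) {
  whisker_geometry(L = 18e-3, R = 37e-6, trunc = 0.05 * 18e-3,
                   rho = 1000, E = 3.0e9, alpha = alpha)
}

# dimensions of the measured C2 whisker used in the modulus worked example
c2_dims <- list(L = 17.14e-3, R = 37.15e-6, rho = 1000)

standard_touch <- function(F_max = 1e-6, tau = 0.1e-3) {
  force_profile("gaussian_smooth", F_max = F_max, t_f = 10e-3, tau = tau,
                C = 0.5)
}

# the printed first ten dimensionless roots of the free full-length cone
free_full_roots10 <- c(8.719, 21.146, 38.454, 60.680, 87.834,
                       119.919, 156.936, 198.887, 245.771, 297.589)
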