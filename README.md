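# whiskerbeam

Rodents localize objects by sweeping their whiskers against them. Because a
whisker is a thin, tapered elastic beam, every touch excites transverse
vibrations that travel to the follicle, where mechanoreceptors sense the
bending moment and shear force at the whisker base. `whiskerbeam` implements
a closed-form vibration analysis of truncated conical whiskers in active
object contact, for sensory-biomechanics and computational-neuroscience work
on vibrissal touch: which vibration frequencies a contact excites, how large
the vibrational forces at the follicle are relative to the quasi-static
ones, and how both depend on the radial distance of the contact point —
candidate cues for object localization.

## The model

The whisker is an Euler–Bernoulli cone with radius `r(x) = ξx`, clamped at
the base `x = L` and free at its (possibly trimmed) tip `x = ℓ`, with the
virtual cone apex at `x = 0`. Transverse motion under a point force `F(t)`
applied at `x = c` obeys

    ∂²/∂x² (E I(x) ∂²y/∂x²) + μ(x) ÿ + μ(x) α ẏ = F(t) δ(x − c),

with `I(x) = (π/4)ξ⁴x⁴`, `μ(x) = ρπξ²x²`, and a frequency-independent
viscous damping constant `α`. In the dimensionless variable `z = qx`,
`q² = 4ρω²/(Eξ²)`, the eigenmodes of the cone satisfy `(z⁴χ″)″ = z²χ`, whose
four independent solutions are `J₂(2√z)/z`, `Y₂(2√z)/z`, `I₂(2√z)/z`,
`K₂(2√z)/z`. Imposing the boundary conditions — clamped base, free tip, and,
during contact, a simple support (`χ = 0`, continuous slope and moment) at
the pole — gives a characteristic determinant whose roots `β_j = q_jL` are
the dimensionless eigenfrequencies, with

    ω_j = (β_j/2)(R/L²)√(E/ρ).

The package solves all four boundary cases (full-length or truncated cone,
free or in contact), with exponentially rescaled modified-Bessel evaluation
so that arbitrarily high modes remain computable. The forced response is a
modal superposition: the deflection splits exactly into a quasi-static part
`F(t)·ỹ_s(x)` (the closed-form small-angle bending solution) and a
vibrational part `Σ_j φ_j(t) X_j(x)` whose damped-oscillator coefficients
are driven by `−(F̈ + αḞ) P_j`. The contact force is a truncated Gaussian
with a C² quartic onset of duration `τ`; at detachment the state is matched
onto the free modes and rings down. The bending moment and shear force at
the follicle are reported with their quasi-static and vibrational components
separated. A damped-sinusoid fitter
(`A sin(ω̃t + φ) e^(−αt/2)`, Levenberg–Marquardt with 0.95 confidence
intervals) recovers frequency and damping from measured vibration traces and
converts them to a Young's-modulus estimate.

## Worked example

```r
library(whiskerbeam)

whisker <- standard_whisker()   # trimmed cone, L = 18 mm, R = 37 um,
                                # E = 3 GPa, rho = 1 g/cm^3, alpha = 430 rad/s
touch <- force_profile("gaussian_smooth", F_max = 1e-6,
                       t_f = 10e-3, tau = 0.1e-3, C = 0.5)

eigenmode_basis(whisker, c_frac = 0.6, n_modes = 3)
#> 3 contact_truncated eigenmodes (contact at c/L = 0.600)
#>   beta : 13.325, 33.982, 65.224
#>   f(Hz): 209.7, 534.9, 1026.6

sim <- simulate_touch(whisker, c_frac = 0.6, profile = touch, n_modes = 60)
sim
#> Whisker touch simulation
#>   contact at c/L = 0.600, 60 contact + 60 free modes
#>   contact window 10 ms, simulated to 20 ms (dt = 0.01 ms)
#>   detachment continuity residual: 1.41e-06 (relative)

fs <- follicle_signal(sim)
max(abs(fs$M_vib)) / max(abs(fs$M_static))
#> [1] 0.160636
```

The first line reports the contact-constrained spectrum: with the pole 60%
of the way from the (virtual) tip, the fundamental rings at ~210 Hz. The
simulation evolves 60 damped modes through a 10 ms Gaussian touch and the
free ring-down after detachment; the continuity residual confirms the
detachment matching. The last number says that for this touch the peak
vibrational bending moment at the follicle is ~16% of the peak quasi-static
moment.

Fitting a vibration trace (here synthetic, 5% noise) and estimating the
modulus from it:

```r
trace <- synth_vibration_trace(omega = 962, alpha = 430,
                               noise_sd = 0.05, seed = 42)
fit <- fit_damped_oscillation(trace)
fit
#> Damped-oscillation fit: A sin(omega_t t + phase) exp(-alpha t / 2)
#>   omega = 960.8 rad/s (152.9 Hz), alpha = 424.2 rad/s
#>   A = 0.9943, phase = 0.3095 rad, RSS = 1.895

estimate_modulus(fit, L = 17.14e-3, R = 37.15e-6, rho = 1000)$E / 1e9
#> [1] 3.037113
```

A 962 rad/s (153 Hz) fundamental for a 17.14 mm whisker with 37.15 um base
radius implies a Young's modulus of ~3.04 GPa.

Distance-cue analyses live in `frequency_sweep()`, `truncation_sweep()`,
`excitation_spectrum()`, `ratio_analysis()` and
`rate_of_change_comparison()`. A command line entry point
(`inst/exec/whiskerbeam`, subcommands `eigen | simulate | sweep | fit |
fixtures`) drives the same functions from YAML configs; see
`inst/extdata/example_config.yaml`.

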