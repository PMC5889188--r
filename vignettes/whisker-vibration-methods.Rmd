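---
title: "Methods: conical-whisker vibration analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conical-whisker vibration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskerbeam)
```

## Model and assumptions

`whiskerbeam` treats a whisker as a linearly tapered Euler–Bernoulli cone:
radius `r(x) = ξx` with `ξ = R/L`, the base clamped at `x = L` (the follicle
is modelled as a rigid clamp), the real tip free at `x = ℓ` (the truncation
length; `ℓ = 0` for an untrimmed whisker), and the virtual cone apex at
`x = 0`. The assumptions this rests on:

* **Thin beam.** Whisker slenderness is far beyond the regime where shear
  deformation or rotary inertia matter, so Euler–Bernoulli suffices.
* **Small angles.** Deflections are linear in the applied force and the
  applied point force is taken normal to the whisker axis. Push angles of
  tens of degrees would need a nonlinear model.
* **Planar motion, no friction, no tension.** The analysis is 2-D
  transverse bending only; torsion, intrinsic curvature and frictional
  tensioning are out of scope.
* **Point contact as a simple support.** While the pole presses on the
  whisker, the vibrational modes must vanish at the contact point but may
  rotate through it (slope and moment continuous).
* **Frequency-independent viscous damping**, one constant `α` applied to
  every mode, and **under-damping** (`ω_j > α/2`) for every retained mode —
  the solver refuses over-damped configurations rather than silently
  switching branch.

With the dimensionless variable `z = qx`, `q² = 4ρω²/(Eξ²)`, the mode
equation is `(z⁴χ″)″ = z²χ`, solved in closed form by
`J₂(2√z)/z, Y₂(2√z)/z, I₂(2√z)/z, K₂(2√z)/z`. Each boundary case (free or
contact, full or truncated) yields a determinant condition on `β = qL`;
frequencies follow from `ω = (β/2)(R/L²)√(E/ρ)`. This reading of the
frequency relation is fixed by requiring consistency with the definition of
`q`: it is the unique `ω` with `q(ω)L = β`, and it reproduces the modulus
worked example (`ω = 962 rad/s`, `L = 17.14 mm`, `R = 37.15 µm`,
`ρ = 1 g/cm³` → `E ≈ 3.04 GPa`, see `young_modulus_from_frequency()`).

The forced solution decomposes exactly as
`y(x,t) = F(t)·ỹ_s(x) + Σ_j φ_j(t)X_j(x)`: a quasi-static part that tracks
the force through the closed-form small-angle bending solution, and a
vibrational part whose coefficients obey independent damped-oscillator
equations driven by `−(F̈ + αḞ)P_j`, with `P_j = ∫ ỹ_s x² X_j dx`. At
detachment (`t_f`) the state is projected onto the free-whisker modes and
evolves in closed form.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `L`, `R` | 18 mm, 37 µm | m | geometry; set the frequency scale `R/L²` |
| `trunc` (`ℓ`) | 0.05 L | m | trimming; shifts high modes most |
| `E`, `rho` | 3 GPa, 1000 | Pa, kg/m³ | enter only through `√(E/ρ)` |
| `alpha` | 430 | rad/s | ring-down envelope `e^(−αt/2)` |
| `F_max` | 1 µN | N | pure scale factor (everything is linear) |
| `t_f`, `C` | 10 ms, 0.5 | s, – | Gaussian contact duration and cutoff |
| `tau` | 0.1 ms | s | smooth-onset duration; controls how many high modes the impact excites |
| `n_modes` | 60 (100 for follicle-force ratios) | – | modal truncation |
| `dt` | 10 µs | s | output sampling |

The default whisker and force mirror a measured mouse C2 whisker and a
typical active touch. `τ` is the critical impact parameter: modes with
periods well above `τ` are excited `τ`-independently, and the excitation of
the first three modes changes by under 1% between `τ = 0.1 ms` and
`τ = 0.05 ms`. Modes 5–6 (periods within ~4× of `τ`) retain a few percent
of sensitivity at this resolution, which is why the sensitivity test bounds
them separately.

## Numerical choices

* **Scaled Bessel evaluation.** `I` and `K` grow/decay like `e^(±2√z)`;
  every basis evaluation and every boundary-matrix column carries an
  exponential rescaling (referenced to the largest/smallest argument in its
  region), which multiplies determinants by positive factors and therefore
  moves no roots. Coefficient vectors are stored in the scaled basis, so
  mode evaluation never forms an unscaled `I` or `K`. This keeps hundreds of
  modes computable (`β ~ 10⁴`).
* **Root scanning in `ν = 2√β`.** Roots are asymptotically equally spaced
  (~π) in `ν`, so a uniform `ν` scan (step 0.05) with bisection refinement
  is reliable and cheap at any mode order, whereas a uniform `β` step either
  misses high roots or wastes evaluations. A half-step rescan verifies the
  bracket count so closely spaced roots are not skipped; the scan starts at
  `β = 0.25` to exclude the trivial root at zero. Roots are polished to
  ~1e−12 relative.
* **Null vectors via SVD.** Mode coefficients are the smallest singular
  direction of the boundary matrix — robust for the 8×8 truncated-contact
  case — with an explicit degeneracy check (second-smallest singular value
  must be well separated).
* **Oscillation-aware quadrature.** Normalization, projections and Gram
  matrices use composite 16-node Gauss–Legendre panels laid out uniformly in
  `ν` (where the integrand oscillates uniformly), with forced panel breaks
  at the contact point, where the static shape has a slope kink and the
  modes lose smoothness in higher derivatives.
* **Deterministic mode signs.** After normalization
  (`∫x²X² dx = 1`) each mode is flipped, if needed, to be positive at its
  amplitude maximum nearest the tip, so regression output is reproducible.
* **Exact modal propagation.** The oscillator equations are advanced with
  the exponential propagator that is exact for piecewise-linear drive
  (`−(F̈ + αḞ)` interpolated on a fine grid: 2000 sub-steps across the
  onset, 2 µs elsewhere). The kernel is integrated analytically, so the
  step needs to resolve only the smoothness of the force, not the mode
  periods — `O(T)` work instead of the `O(T²)` of direct convolution. The
  Duhamel integral is retained (`method = "duhamel"`) purely as an
  independent cross-check, and the two agree to better than 1e−6 relative
  in the tests. The ramp force, whose second derivative is impulsive, is
  evaluated from its closed-form response instead.
* **Detachment matching.** The contact-phase state at `t_f` is projected
  onto the free basis through the cross-Gram matrix `∫x² Z_k X_j dx`; the
  relative displacement mismatch across detachment is always computed and
  stored (`sim$detach$residual`). Free-mode count defaults to the
  contact-mode count.
* **Degenerate inputs.** Zero force, zero damping, contacts at the domain
  ends, non-finite parameters and over-damped modes are all rejected or
  handled explicitly rather than left to overflow; `z = 0` (the apex of a
  full cone) is evaluated from the analytic small-argument limits.

## Open design decisions

* **Force-ratio normalization.** The axial-to-lateral force ratio is
  `tan` of the slope difference between base (zero, clamped) and contact
  point. Comparing it *across* contact positions requires choosing what a
  touch holds fixed; `rate_of_change_comparison()` normalizes to a constant
  push angle `θ` (pole deflection `θ(L−c)`), under which the small-angle
  ratio reduces to `tan[θ(L+2c)/(2c)]`. This is the kinematically natural
  choice — the animal controls its whisking angle — and it produces the
  characteristic behaviour the analysis probes: a flat, slowly changing
  ratio for proximal contacts and rates exceeding 100 %/mm near the tip of
  a full cone. At constant applied force the proximal percent-rate would
  instead diverge like `2/(L−c)`, which is not a usable cue curve.
* **"Average" and "maximum" force ratios.** `ratio_analysis()` defines the
  average ratio as the time-average of the absolute vibrational component
  divided by the time-average of the absolute quasi-static component over
  the contact window, and the maximum ratio as the ratio of the two peak
  magnitudes. Pointwise-in-time ratio means are not used because the
  quasi-static component crosses zero at onset and offset, making such
  means diverge.
* **Fit-formula family.** The damped-oscillation fit and the Gaussian force
  are implemented in their canonical parameterizations. An alternative
  shorthand for the same force family (centre `2t_d`, width `1.2011 t_d`,
  cutoff 0.5) is internally inconsistent about where the peak occurs and
  omits the `1/(1−C)` normalization; it is treated as the same family via
  `C = 0.5`, `a = 2t_d`, `b = 1.2011 t_d`, not as a separate shape.
* **Boundary case for modulus estimation.** `estimate_modulus()` defaults
  to the full-length free cone's first root; whether a measured
  free-vibration fundamental reflects that case or a truncation- or
  follicle-compliance-shifted mode is left to the user via the `case` and
  `l_frac` arguments.
* **Command line.** The CLI is a thin wrapper over the package functions;
  the package API is the primary interface and the CLI adds only config
  parsing and provenance-stamped file output (no timestamps, so identical
  configs give byte-identical files).

## Synthetic traces: what they do and do not emulate

`synth_vibration_trace()` generates exactly the fitted model — a single
damped sinusoid — plus i.i.d. Gaussian noise, seeded and reproducible. That
emulates the dominant-mode ring-down of a whisker after slipping off a pole,
sampled by high-speed video, and it is the right fixture for calibrating the
fitter (exact recovery on noiseless input; on a 200-replicate Monte-Carlo
ensemble at 5% noise the median frequency error is within 2% and the 0.95
intervals cover the truth in at least 90% of replicates — both asserted in
the tests). It does **not** emulate multi-mode content, tracking artefacts
(correlated noise, outliers near fur or pole shadow), irregular sampling, or
uncompensated active whisker motion; passing the calibration therefore
validates the estimator, not the tracking pipeline that would precede it on
real video data.

## Problem sizes used in the test-suite

Tests run the solver at the depth each question needs: 6 modes for
orthogonality checks, 16–20 for dynamics properties and field comparisons,
60–100 for the follicle-force ratios (the shear mode-sum converges slowly;
displacement-level quantities change by <0.1% between 30 and 60 modes,
asserted explicitly). The independent cross-checks are a double-integration
quadrature oracle for the static solution, a dense unscaled-determinant scan
for the eigenvalues, direct Duhamel quadrature for the modal dynamics, and a
Hermite-cubic finite-element discretization (240–300 elements) for both the
eigenvalues (0.1% agreement) and full displacement fields (within 2% of peak
amplitude).

## Known limitations

Planar bending only (no torsion, 3-D motion or intrinsic curvature); no
friction or axial tension; rigid-clamp follicle (a compliant follicle would
shift frequencies); linear small-angle statics; a single stationary contact
point with no re-contact after detachment; under-damped modes only; and a
linear cone (real whiskers are slightly thinner mid-shaft than a linear fit,
which matters more for bending angles than for mode shapes).
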