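Package: whiskerbeam
Title: Analytical Vibration of Conical Whiskers During Object Contact
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form Euler-Bernoulli vibration analysis of truncated
    conical vibrissae (whiskers). Solves the Bessel-function eigenmode
    problem for a fixed-base, free-tip conical beam with and without a
    simple support at an object-contact point, evolves damped modal
    dynamics under a smooth-onset Gaussian contact force, and computes
    the bending moment and shear force transmitted to the follicle.
    Includes object-distance cue analyses (contact-position dependence of
    eigenfrequencies, modal excitation spectra, vibrational versus
    quasi-static force ratios) and a damped-sinusoid fitter for measured
    vibration traces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
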