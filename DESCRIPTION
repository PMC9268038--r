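Package: vibronic
Title: Vibronic Absorption Spectra from Harmonic Models: Franck-Condon and
    Nuclear-Ensemble Methods
Version: 0.1.0
Authors@R: person("Vibronic", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates electronic absorption spectra of chromophores under
    harmonic models of the ground- and excited-state potential energy
    surfaces. Implements the four standard harmonic constructions of the
    final-state surface (adiabatic Hessian, adiabatic shift, vertical
    Hessian, vertical gradient) as Duschinsky rotation + displacement maps,
    time-independent Franck-Condon stick spectra with Boltzmann hot bands
    and band assignment, the time-dependent correlation-function lineshape
    valid at any temperature, and nuclear-ensemble spectra from Wigner or
    classical-Boltzmann harmonic sampling. Includes normal-mode analysis
    with Eckart projection, spectrum post-processing (broadening, peak
    finding, shifting, spectral distances), analytic model chromophores for
    testing (including a cyanine-like six-mode model), and a force-field
    bond-length-alternation audit for polymethine chains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
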