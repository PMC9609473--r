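Package: revkin
Title: Reversible First-Order Kinetics of Ionic Drug Binding and Release
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the electrostatic (ionic) binding and release of
    doxorubicin from the carboxylated corona of amphiphilic
    N-vinyl-2-pyrrolidone/acrylic-acid copolymer nanoparticles as a
    reversible first-order reaction. Provides the closed-form release
    profile and an ODE cross-check, estimation of the equilibrium release
    conversion and of the separate release and binding rate constants from
    dialysis release time series, Arrhenius activation energies, van't
    Hoff enthalpies and standard Gibbs energy and entropy of release, a
    seeded synthetic-data generator emulating dialysis experiments over
    the studied condition grid (copolymer composition, concentration,
    temperature, pH), and CSV input/output with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr, knitr, rmarkdown
Config/testthat/edition: 3
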