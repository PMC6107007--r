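Package: silkphotonics
Title: Transverse Anderson Localization and Radiative-Cooling Optics of
    Nanostructured Fibers
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for the optics of fibers
    containing dense, randomly placed, axially elongated air voids, such as
    wild-silkmoth cocoon fibers and their biomimetic analogues. Provides a
    seeded generator for random fiber cross-sections with filamentary or
    particulate voids, a scalar split-step (paraxial) beam-propagation
    engine, estimation of the transverse localization length from
    exponential intensity tails and inversion of the localization relation
    for the transport mean free path, exact scattering efficiencies of
    infinite dielectric cylinders for both polarizations, spectral figures
    of merit for passive radiative cooling (solar-weighted reflectance,
    Planck-weighted thermal emissivity, atmospheric-window emissivity), and
    extraction of photon lifetimes from time-of-flight traces by fitting an
    instrument response function convolved with an exponential decay.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    minpack.lm,
    pracma,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
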