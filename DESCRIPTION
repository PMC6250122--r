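Package: PhotoTA
Title: Global and Target Analysis of Time-Resolved Absorption Spectroscopy
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting photoreceptor photochemistry from
    time-resolved difference-absorption data. Implements preprocessing of
    spectro-temporal matrices (streak-camera image arithmetic, pre-time-zero
    scatter subtraction, white-light chirp correction, quasi-logarithmic time
    axes), SVD-based rank analysis, variable-projection global fitting with
    Gaussian instrument-response convolution yielding decay-associated
    difference spectra (DADS), target analysis mapping DADS onto
    species-associated spectra (SAS) through compartmental kinetic models,
    spectral arithmetic for radical-pair recombination estimates, mole-fraction
    decomposition over species basis spectra, polarization anisotropy analysis,
    and a compartmental simulator of the branched flavoprotein photocycle with
    product quantum yields. A seeded synthetic-data generator emulating
    femtosecond, microsecond and millisecond measurement regimes supports
    closed-loop parameter-recovery testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, minpack.lm, pracma
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
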