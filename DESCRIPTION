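Package: oscitemp
Title: Temperature Scaling of the Early Embryonic Cell-Cycle Oscillator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how the early embryonic cell-cycle oscillator
    scales with temperature. Implements the empirical duration-versus-temperature
    scaling laws (Arrhenius, double-exponential, quadratic-exponential and
    power-law-exponential forms) with per-degree median binning, least-squares
    fitting on log durations and stratified bootstrap distributions of apparent
    activation energies; a two-variable cyclin B-Cdk1 relaxation oscillator with
    Hill-function regulatory responses, temperature-scaled kinetic rates,
    nullcline and fixed-point analysis; limit-cycle period detection with thermal
    limits and synthesis/degradation titration scans; likelihood-free (ABC-SMC)
    inference of per-rate activation energies from phase-duration data; and
    pipelines turning droplet FRET-ratio time series and in-vitro assay time
    series into phase durations and rates. A synthetic-data module generates all
    input classes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
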