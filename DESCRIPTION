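Package: luxrep
Title: Retinally Referenced Light Exposure Metrology and Reporting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying and reporting light exposure in human
    chronobiology and sleep research. Reads and writes tabulated spectral
    power distributions (delimited ASCII), computes alpha-opic
    (ir)radiances for the five human photoreceptor classes together with
    photopic illuminance or luminance, photon irradiance, age-dependent
    pre-receptoral filtering corrections, visual angle, light-adapted
    pupil diameter and retinal illuminance in trolands, performs a
    blue-light-hazard risk-group-0 pre-screen, and validates exposure
    records against a seven-item minimum reporting checklist, rendering
    standardized human- and machine-readable reports. Includes a
    synthetic-fixture generator (Planckian radiators, Gaussian LED
    mixtures, monochromatic lines, deliberately deficient records) so the
    full pipeline is testable without measurement hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
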