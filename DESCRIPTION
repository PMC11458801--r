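Package: picquant
Title: Quantitative Analysis of PIC J-Aggregation as an Intracellular
    Crowding Sensor
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify pseudoisocyanine chloride (PIC) J-aggregation
    assays used as a non-protein macromolecular crowding sensor. Provides
    spectral classification of J-aggregate versus monomer pixels in
    multichannel fluorescence images with nucleolus masking and
    stress-granule colocalization, droplet and stress-granule morphometrics
    (area, circularity, background-corrected intensity, group statistics),
    FRAP recovery-curve normalization and single-exponential mobile-fraction
    fitting, time-resolved multi-angle static and dynamic light-scattering
    evaluation (Zimm and Guinier fits, cumulant analysis, Stokes-Einstein
    hydrodynamic radius, rho = Rg/Rh, induction-time detection), detection of
    the J-aggregation threshold temperature from temperature-ramp absorbance
    spectra, and synthetic-data generators with known ground truth for all of
    the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
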