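Package: crseawater
Title: Chromium Redox Speciation, Stable-Isotope Fractionation and Export
    Budgets in the Surface Ocean
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking seawater chromium concentration, Cr(III) redox
    speciation, stable-isotope composition (delta-53Cr vs NIST SRM 979) and
    biological productivity. Provides diel replicate quality control with
    modified Thompson tau outlier rejection, Cr(III)/Cr(VI) speciation with
    propagated uncertainty, a fitted-model interface for delta-53Cr vs
    [Cr(III)] mass-balance fractionation (Delta-53Cr) and Rayleigh-style
    delta-53Cr vs ln[Cr] enrichment-factor (epsilon) estimation, double-spike
    MC-ICP-MS data reduction with isobaric interference correction and isotope
    dilution, mixed-layer Cr deficit and Cr:C export budgets, net community
    production from O2/Ar supersaturation with 60-day weighted wind-speed gas
    exchange, and a seeded synthetic-ocean generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
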