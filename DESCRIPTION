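Package: emulsim
Title: Droplet Single-Cell Culture Simulation and Telomerase Splice-Variant
    Quantitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for nanoliter-droplet single-cell
    culture experiments that measure telomerase (hTERT, hTR) transcript
    abundance by multiplex RT-PCR and capillary-electrophoresis fragment
    analysis.  Provides a synthetic-data generator covering Poisson cell
    encapsulation, volume-limited colony growth, bursty hTERT splice-variant
    transcription, curcumin perturbation and peak-area readout noise;
    limiting-dilution digital PCR Poisson copy-number estimation; a compiled
    implementation of Hartigan's dip test of unimodality with bootstrap
    p-values; and colony-level statistics (GAPDH gating, per-cell
    normalization, splice-variant co-occurrence, growth rates, and fold-change
    calls with Mann-Whitney significance).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
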