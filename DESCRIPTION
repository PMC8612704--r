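Package: axocascade
Title: Single-Axon Live-Imaging Analysis of the Axon Degeneration Cascade
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing live-imaging experiments that follow single
    injured axons through the SARM1-dependent degeneration cascade: ATP loss,
    mitochondrial arrest and depolarization, calcium influx, phosphatidylserine
    exposure, loss of axon continuity and fragmentation. Provides per-channel
    event-onset detectors for GCaMP6, TMRM, PercevalHR, mRuby3 and Annexin-V
    traces, a kymograph motility classifier with arrest-time estimation, a
    morphology-based axon degeneration index, and cohort-level temporal
    ordering statistics (signed event-time differences, frame-ordering
    fractions, least-squares regressions). A synthetic-cohort generator
    reproduces the statistical structure of the cascade so every stage of the
    pipeline can be exercised and validated without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
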