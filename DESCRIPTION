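Package: campariq
Title: Quantification of CaMPARI Photoconversion Snapshot Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for quantifying neuronal activity snapshots recorded with
    the photoconvertible calcium integrator CaMPARI. Implements two-channel
    image corrections (dark current, green-to-red spectral contamination,
    per-hemisphere red autofluorescence), z-slab averaging and cell-level
    fluorescence extraction, per-cell red-to-green ratio (RGR) computation
    with region summaries, the sensitivity index d' for population
    separation, photoconversion light-dose arithmetic, exponential RGR decay
    and polynomial dose-response fitting, integration of drifting-grating
    calcium responses, and the accompanying comparison statistics. A
    synthetic two-photon microscopy data generator with known ground truth
    drives validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
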