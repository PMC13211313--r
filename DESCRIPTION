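Package: nmr2mol
Title: Spectrum-to-Structure Elucidation from Raw Multimodal NMR Spectra
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end molecular structure elucidation from raw one-dimensional
    (1H, 13C) and two-dimensional (HSQC) NMR spectra. Spectra on dense
    chemical-shift grids are cut into patches, embedded per modality, fused
    into a single token stream and encoded by a transformer; an autoregressive
    decoder prompted with the molecular formula generates candidate SMILES
    strings by beam search. Candidates are filtered for chemical validity and
    formula consistency and re-ranked by a Gaussian-kernel local evidence
    score that measures how strongly predicted chemical shifts are supported
    by observed spectral intensity. A deterministic toy molecule and spectrum
    simulator makes the whole pipeline trainable and testable at desk scale.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
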