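Package: thermidp
Title: Intrinsic Structural Disorder Across Prokaryotic Thermal Classes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Comparative analysis of predicted intrinsic structural
    disorder across prokaryotes of different optimal growth temperature
    (OGT). Provides per-residue disorder scoring (a bundled
    composition-window scorer plus an adapter for IUPred-style score
    tracks), per-protein and per-proteome disorder measures (disordered
    residue fractions, mostly disordered proteins, long disordered
    regions), charge-hydropathy (Uversky) classification, thermal-class
    grouping with nonparametric group comparison, transcription-factor
    profiling and GO biological-process profiling of long-IDR proteins,
    and a seeded synthetic proteome generator so the whole pipeline is
    testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, jsonlite, Biostrings
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
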