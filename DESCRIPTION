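Package: flipper
Title: Sequence-Homology-Independent Screening for Pyrenoid Rubisco Linker Proteins
Version: 1.0.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies candidate pyrenoid linker proteins - intrinsically
    disordered, tandem-repeat scaffold proteins whose short amphipathic
    sticker motifs cross-link Rubisco holoenzymes into a liquid-liquid
    phase-separated condensate - from whole-proteome FASTA input, without
    relying on sequence homology. Provides physicochemical profiling
    (isoelectric point, hydropathy, residue-class fractions), a tandem
    repeat detector for unit lengths on the 20-120 residue cross-linking
    scale, a built-in charge-hydropathy disorder predictor with support for
    external per-residue scores, threshold calibration from a reference
    linker, candidate ranking, and enrichment-table triage against
    co-immunoprecipitation proteomics. Also implements the accompanying
    quantitative curve analyses (Hill binding fits, FRAP recovery fits,
    droplet sedimentation fractions, calibration-curve absolute
    quantification) and a seeded synthetic proteome generator for
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, SequenceMatching, Software
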