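Package: softcorona
Title: Soft-Corona Proteomics: emPAI Copy Numbers, Hard/Soft Classification,
    Coverage and SPR Affinity Distributions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis workflow for click-chemistry capture of the soft protein
    corona on nanoparticles. Converts emPAI proteomics tables, BCA total-mass
    and particle-count measurements into per-nanoparticle protein copy
    numbers; identifies soft-corona (SC) proteins against four hard-corona
    control samples by an enrichment-and-consistency rule with two-way
    Ward/Euclidean clustering; classifies SC proteins into Type 1/2/3/new by
    their hard- versus soft-state copy numbers; computes sequence
    physicochemistry (molecular weight, isoelectric point, GRAVY, instability
    index) and number-weighted corona averages; estimates orientation-dependent
    monolayer coverage from geometric protein footprints; and fits surface
    plasmon resonance sensorgrams with a Tikhonov-regularized two-dimensional
    distribution of 1:1 Langmuir binding sites on a 21 x 21 (KD, koff) grid.
    Includes a synthetic-data generator with planted ground truth for
    benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pracma,
    bio3d,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
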