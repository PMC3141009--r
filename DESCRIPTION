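Package: karyevol
Title: Chromosome Number Evolution in Budding Yeasts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of chromosome-number evolution in Saccharomycetaceae
    yeasts with point centromeres. Detects CDEI-CDEII-CDEIII point
    centromeres in DNA by position-frequency-matrix scanning and builds
    consensus models from annotated centromeres; maps extant centromeres
    and telomere locations to an ancestral pre-whole-genome-duplication
    genome by synteny flanks and a parsimony rule; decomposes genomes into
    synteny blocks, extracts breakpoint edges and traces reciprocal-edge
    cycles that resolve breakpoint reuse; classifies chromosome-number
    changing mechanisms (telomere-to-telomere fusion with centromere loss,
    centromere fission, whole-genome duplication); and ships a seeded
    karyotype-evolution simulator that generates ancestors, event
    histories along a species tree and extant genomes with ground-truth
    logs for validating every inference stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'simulate.R'
    'events.R'
    'evolve.R'
    'synteny.R'
    'mapper.R'
    'classify.R'
    'consensus.R'
    'io.R'
    'pipeline.R'
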