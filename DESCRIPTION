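Package: nuticap
Title: Design, Extraction, QC and Interaction Calling for Targeted
    High-Resolution Chromosome Conformation Capture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A toolkit for targeted high-resolution chromosome conformation
    capture (Capture-C style 3C) experiments. Provides in-silico restriction
    digestion and capture-probe design with a co-targeting audit, chimeric
    read decomposition into restriction slices with sonication-breakpoint
    deduplication, quantification of inter-nuclear ligation noise from
    two-species admixture libraries, a closed-form model of
    capture-enrichment bias between co-targeted fragments, cis-normalised
    binned and windowed interaction profiles, distance-decay residual
    z-normalisation with a spike-and-slab sampler yielding marginal posterior
    probabilities of contact, regulatory-organisation summaries
    (promoter hubs, enhancer directionality, super-enhancer target sets),
    and a seeded 3C read simulator with a per-read truth table for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    methods,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
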