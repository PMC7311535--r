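Package: mutread
Title: Reduced-Representation Mutational Signature Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: In-silico double-restriction-digest simulation for enzyme-pair
    selection in reduced-representation sequencing (ddRAD-style) experiments,
    construction of 96-channel trinucleotide mutational spectra from somatic
    SNV calls, refitting of mutational-signature exposures by non-negative
    least squares with cosine-similarity evaluation, somatic-variant filtering
    with cohort-specific thresholds, and UMI/inner-barcode read preprocessing
    (PCR-clone removal, demultiplexing, RAD-tag verification, quality
    filtering). Includes a synthetic-data module that generates genomes with
    planted restriction sites, SNV sets drawn from known signature-exposure
    mixtures, and reads in the UMI + barcode + residual-site layout, so the
    whole pipeline is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    pracma,
    jsonlite,
    withr
Config/testthat/edition: 3
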