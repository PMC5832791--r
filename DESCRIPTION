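Package: wobblebias
Title: AA:AG Wobble-Codon Bias Analysis for Elongator-Dependent Translation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying synonymous codon bias at the tRNA wobble
    position for lysine, glutamine and glutamate codons (the AA:AG ratio),
    scanning ORFeome-scale CDS collections, integrating transcriptome and
    proteome fold-change tables to classify post-transcriptional
    misregulation, profiling protein fold-change classes across codon-bias
    and transcript-length thresholds, designing synonymously recoded
    codon-bias biosensors, and generating synthetic multi-omics studies with
    known ground truth for end-to-end pipeline validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
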