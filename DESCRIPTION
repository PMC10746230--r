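Package: phagecode
Title: CRISPR Spacer-Based Phage-Host Linking and Dual Genetic-Code
    Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Links candidate phage sequences to bacterial hosts through
    CRISPR spacer-protospacer matching and profiles each phage's genetic
    code by comparing coding densities under the standard bacterial code
    (translation table 11) and the alternative code in which TGA encodes
    glycine (table 25). Provides a deterministic six-frame ORF caller
    aware of alternative stop-codon sets, a CRT-style CRISPR array
    detector with an evidence-level proxy, spacer database construction
    and dereplication, rule-based CRISPR-Cas subtype classification from
    cas gene annotations, an ungapped end-anchored spacer matcher,
    co-targeting and spacer-sharing analyses, in-frame TGA and
    backup-stop-codon terminus reports, and a seed-reproducible synthetic
    genome/phage generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
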