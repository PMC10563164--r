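Package: clirms
Title: Analysis of Protein-RNA Cross-Linking Mass Spectrometry Data with
    Isotope-Labeled RNA
Version: 0.1.0
Authors@R: person("RNx", "Tools", email = "rnxtools@example.org",
    role = c("aut", "cre"))
Description: Toolkit for CLIR-MS style protein-RNA cross-linking mass
    spectrometry experiments in which the RNA carries a 1:1 mixture of
    light and heavy stable-isotope labels. Enumerates RNA-derived peptide
    adduct species and their light/heavy delta masses, groups them into
    parallel search definitions, builds decoy protein databases, detects
    light/heavy precursor scan pairs in mzXML data, consolidates and
    reranks cross-link spectrum matches, estimates false discovery rates
    by target-decoy competition (observed, per-composition-bin
    transferred, and Percolator PIN export), refines identifications by a
    fitted mass-error window, and produces protein-centric and
    RNA-centric reports. Includes a synthetic-data generator emulating
    the statistical structure of such experiments so the whole pipeline
    is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    xml2,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
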