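Package: fsannot
Title: Function-Structure-Adaptability Annotation of Protein Residues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Assigns per-residue roles in a protein by contrasting amino-acid
    conservation in curated natural-homolog multiple sequence alignments with
    conservation in sequences designed by structure-conditioned neural
    networks (e.g. ProteinMPNN). Positions are tested per physicochemical
    class for enrichment over the whole-protein baseline with a Mann-Whitney
    U test, filtered by an information-scaled differential-distribution norm,
    and classified as functional (conserved by nature only), structural
    (conserved by both), adaptable (conserved by design only) or unlabeled.
    Includes readers for FASTA alignments (plain and multi-chain design
    dialect) and ASCII psiblast-style PSSMs, a synthetic paired-alignment
    generator with planted ground truth for benchmarking, tidy accessors,
    ggplot2 visualisations and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
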