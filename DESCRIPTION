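Package: mondoevo
Title: Comparative Evolution of Duplicated Gene Families: Intron
    Architecture and Paralog Conservation Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of a duplicated vertebrate gene
    family, exemplified by the glucose-responsive transcription factors
    MondoA (MLXIP) and ChREBP (MLXIPL) and their partner Mlx.  Derives
    intron positions and phases from coding exon models, projects them onto
    protein alignments, clusters phase-matched intron positions into
    homologous groups and infers the ancestral exon-intron architecture by
    shared presence.  Scores per-column conservation with windowed
    Jensen-Shannon divergence against a BLOSUM62 background, averages
    scores over named domains after gap-column deletion, computes pairwise
    p-distances, contrasts conservation between paralog groups, builds
    consensus frequency matrices, reports residue states at reference
    positions, and reconstructs bootstrapped neighbor-joining trees.  A
    simulator generates paralog families with known ground truth (species
    tree, per-domain per-paralog rates, conserved intron architecture,
    optional pseudogenization) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
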