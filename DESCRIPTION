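Package: lectinomics
Title: Genome-Wide Characterization of Plant Lectin Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for genome-wide characterization of plant lectin
    gene families, with the rice EUL (Euonymus-related lectin) family as the
    motivating case. Classifies genes into the twelve plant lectin families
    from protein-domain annotations and builds census tables; calls tandem
    duplication blocks (same family, same chromosome, at most ten intervening
    genes) and filters segmental duplication blocks by synonymous substitution
    rate; classifies SNP consequences against gene models and clusters rice
    subpopulations by reference-allele usage with UPGMA on RMSD distances;
    maps position weight matrices to 2-kb promoters, filters matches by
    functional regions, builds Pearson co-expression regulons and tests motif
    enrichment with the hypergeometric test under Benjamini-Hochberg FDR
    control; computes stress/hormone fold-change profiles; and quantifies
    EUL-domain conservation (information content, QxW motifs, the D-N-Q
    carbohydrate-binding triad). A synthetic-data module generates every input
    with planted ground truth so all stages are testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
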