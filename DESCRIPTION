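Package: tryptomine
Title: Genome Mining of Gut-Bacterial Tryptophan Catabolism Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based prediction of six neuro-active tryptophan-derived
    metabolite pathways (kynurenine, quinolinate, indole, indole acetic acid,
    indole propionic acid, tryptamine) from annotated bacterial genomes, using
    Pfam domain evidence, protein-homology thresholds and gene-cluster
    proximity. Aggregates strain-level calls into genus-level pathway-potential
    scores (proportion x confidence rank x gut weightage, rescaled to 0-10),
    profiles tryptophan transporters (TnaB, AroP, Mtr) in indole producers,
    and links differentially abundant genera from case/control microbiome
    abundance tables (Wilcoxon rank-sum) to pathway potential as Sankey edge
    lists. Includes seeded synthetic-data generators for genome collections
    with planted evidence and case/control abundance studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    jsonlite,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
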