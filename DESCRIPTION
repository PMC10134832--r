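Package: MetaPanGO
Title: Gene Ontology Information Content, Annotation Concordance, and
    Reference-Free Pangenomes for Metagenome Gene Catalogues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Downstream integration machinery for deep-learning and
    orthology-based functional annotation of metagenome gene catalogues.
    Parses Gene Ontology OBO files into a directed acyclic graph, propagates
    annotations upward, computes Shannon information content and selects
    informative terms by a protein-count threshold; ingests per-gene GO
    prediction tables (score-thresholded) and orthology-mapper annotation
    tables; models CD-HIT style nonredundant gene catalogues and propagates
    centroid annotations to cluster members; integrates metagenome-assembled
    genomes (completeness/contamination filtering, GTDB-style taxonomy, gene
    to MAG mapping, multi-taxonomy gene families); normalizes read counts to
    copies per million and aggregates abundance per GO term; stratifies
    inter-method concordance by information-content level; and constructs
    reference-free pangenomes (core/accessory, shared/unique accessory) from
    nearly complete MAGs. A seeded synthetic-community generator with a
    ground-truth manifest emulates every upstream tool output so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
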