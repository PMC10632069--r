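Package: ontomarine
Title: Ontology-Driven Harmonization and Analysis of Marine Metagenomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained engine for ontology-driven discovery and
    statistical analysis of marine metagenomic count data. Parses OBO-format
    ontologies (Gene Ontology-like DAGs, NCBI Taxonomy-like ranked trees,
    ENVO-like environment vocabularies) and answers recursive subclass-closure
    queries intersected with ontology-annotated functional and taxonomic
    count tables and physicochemical sample metadata. Implements sample
    quality control, relativization by ORF and read totals, clade-level
    aggregation, species/strain rank filtering, prevalence filtering,
    centered log-ratio transformation, Spearman correlation, PERMANOVA,
    multivariate dispersion tests, group-corrected indicator value analysis
    with permutation tests, and elastic-net feature selection with the
    one-standard-error rule. Sample stores export to RDF N-Triples, and a
    seeded synthetic-data generator emulates ocean time-series cohorts with
    planted depth gradients and group indicators for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
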