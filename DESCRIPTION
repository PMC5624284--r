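Package: metacomm
Title: Metacommunity Typing and Functional Profiling of Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for stratifying shotgun-metagenomic cohorts into
    metacommunities with Dirichlet-multinomial mixture models selected by a
    Laplace-approximated negative log posterior, discovering discriminative
    taxa with a bootstrapped linear-discriminant effect-size procedure,
    scoring per-sample dysbiosis, aggregating per-KO differential statistics
    into reporter scores for KEGG pathways, profiling lipopolysaccharide
    acylation and short-chain fatty-acid biosynthetic capacity, inferring
    compositionality-aware correlation networks (SparCC) with empirical
    permutation p-values, and estimating in-situ bacterial growth rates from
    replication origin-to-terminus coverage ratios. Includes a seeded
    synthetic-cohort generator emulating a case-control gut microbiome study
    design, plus diversity, ordination and multivariate association
    statistics shared across the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
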