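Package: irddx
Title: Variant Prioritization and Genetic Diagnosis for Inherited Retinal
    Disease Cohorts
Version: 0.1.0
Authors@R:
    person("IRD", "Diagnostics Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a whole-genome-sequencing variant prioritization
    pipeline for inherited retinal disease (IRD) cohorts: genotype- and
    site-level quality filtering of small variants, dual-population rarity
    filtering of SNVs/indels and structural variants (SVs) with
    reciprocal-overlap matching against reference panels, rule-based
    likely-pathogenic classification (including deep-intronic and
    non-canonical splice-site categories), a retina transcript disruption
    ratio (TDR) score for SVs weighted by transcript expression, pedigree
    segregation analysis under dominant, recessive, compound-heterozygous
    and X-linked models, and per-patient diagnosis reports with cohort
    summaries. A synthetic-cohort simulator with planted causal variants
    makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
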