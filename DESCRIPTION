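Package: plasmaSCNA
Title: Focal Somatic Copy-Number Alteration Profiling of Plasma ctDNA from
    Shallow Whole-Genome Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for copy-number analysis of circulating tumor
    DNA from shallow whole-genome plasma sequencing. Read counts in 50 kb
    genomic windows are normalized for library size and GC content, scaled
    against a healthy-control panel, and segmented by penalized least-squares
    change-point detection. Focal somatic copy-number alterations (SCNAs) are
    called from segments by explicit rule sets for amplifications and
    deletions, tumor fraction is estimated from 1 Mb bins with a hidden-state
    grid search, and focal events overlapping a curated list of osimertinib
    resistance genes are flagged as resistance-related SCNAs (rrSCNAs).
    Cohort-level tools cover droplet digital PCR positivity calling, patient
    evaluability gating, association tests, and survival analysis with Cox
    proportional hazards models and stepwise backward elimination. A
    synthetic-data module generates genomes, binned plasma count profiles,
    control panels, and full clinical cohorts so that every stage of the
    pipeline can be tested without access to sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    survival,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
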