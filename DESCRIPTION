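Package: fusionscape
Title: Gene-Fusion Screening and Resistance-Mechanism Exclusivity Analysis for Recurrent Glioma Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to identify and characterise MGMT gene fusions in
    temozolomide-treated recurrent gliomas from fusion-caller output, and to
    relate them to the other known resistance mechanisms. Implements
    blacklist-based filtering of fusion candidates (normal-tissue events,
    mitochondrial genes, uncharacterised genes, paralog pairs), structural
    annotation of surviving fusions against Ensembl-dialect GTF gene models
    (promoter/5'UTR-swap versus chimeric classes, reading-frame
    reconstruction, protein-domain retention), IDH1/IDH2 hotspot calling from
    RNA-seq pileup base counts with a minimum-depth availability rule,
    assembly of a per-patient alteration landscape with RPKM expression and
    within-cohort Z-scores, exact binomial (Clopper-Pearson) frequency
    estimation, and a seeded bootstrap test of mutual exclusivity among
    alterations with an exact enumeration oracle for small instances. A
    synthetic-data module generates every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
biocViews: Transcriptomics, GeneFusionDetection, StatisticalMethod, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
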