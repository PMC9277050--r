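Package: fragmeth
Title: Fragment-Unit RRBS Differential Methylation and Clinical Association Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Reduced representation bisulfite sequencing (RRBS) analysis using
    in-silico MspI restriction fragments (40-220 bp) as the basic analysis
    units, alongside CpG islands, promoters and gene bodies. Aggregates
    per-CpG methylation calls into unit-level methylation matrices, calls
    differentially methylated fragments under a triple threshold (P, Q and
    absolute mean methylation difference), selects promoter-associated
    candidate genes, and carries the resulting biomarker into clinical
    association testing (mean + 2SD dichotomization, contingency and
    rank tests) and survival analysis (Kaplan-Meier, log-rank, univariate
    and multivariate Cox proportional hazards with a P < 0.200 entry rule).
    Includes a beta-binomial simulator for genomes, methylomes and survival
    cohorts so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    BiocGenerics,
    GenomeInfoDb,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    withr
Config/testthat/edition: 3
biocViews: DNAMethylation, DifferentialMethylation, Epigenetics, Sequencing, Survival
RoxygenNote: 7.3.3
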