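Package: nfkbMirNet
Title: Paired Tumour/Normal Expression of the NF-kB Pathway and Its miRNA
    Associations
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Paired carcinoma/normal differential-expression analysis of the
    KEGG NF-kB signalling pathway in colorectal cancer and association of the
    dysregulated genes with miRNAs. Gene counts are normalized to reads per
    million protein-coding genes (RPMPCG) and tested with a negative binomial
    model with a per-sample library offset and a per-subject effect; miRNA
    array intensities are 75th-percentile scaled and related to gene
    expression on the subject-level paired-difference scale with an
    age/sex-adjusted least-squares model whose F statistic is calibrated by a
    residual bootstrap. Seed regions of 6, 7 and 8 nucleotides are matched
    against 3'UTR sequences. A synthetic-cohort generator with planted fold
    changes, miRNA-gene couplings and seed complementarity provides ground
    truth for calibration and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    SummarizedExperiment,
    Biostrings,
    MASS,
    sandwich,
    glmmTMB
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
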