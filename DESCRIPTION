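Package: recurdrift
Title: Paired Primary-Recurrence Tumor Evolution Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for matched primary breast tumor and
    ipsilateral recurrence (PT-IBTR) pairs across genomic, transcriptomic
    and proteomic layers. Implements a purity-aware somatic SNV filter
    cascade with a binomial likelihood-ratio purity filter, 96-context
    mutational-signature refitting by non-negative least squares with
    per-pair contribution deltas, GC-corrected binned coverage with
    circular binary segmentation and paired per-gene copy-number
    gain/loss calls, cosine-dissimilarity drift between pair members on
    each omics layer, and the clinical association layer (contingency
    tests, rank tests with Benjamini-Hochberg adjustment, Spearman
    correlation, a Ki-67/leukocyte histo-score, and median-split log-rank
    survival). A seeded synthetic paired-cohort generator with known
    ground truth makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    pracma,
    vcfR,
    yaml,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
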