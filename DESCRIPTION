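Package: rnaloops
Title: Regulatory Feed-Forward Loops and ceRNA Networks from Drug-Response
    Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a heterogeneous background "RNA interactome" from
    regulator-target association tables (TF->mRNA, TF->lncRNA, TF->miRNA,
    miRNA->mRNA, miRNA->lncRNA), maps per-condition differential-expression
    calls onto it, extracts condition-specific subnetworks, enumerates and
    classifies three-node feed-forward loops involving transcription
    factors, miRNAs, mRNAs and lncRNAs, derives shared-miRNA competing
    endogenous RNA (ceRNA) candidates, and prioritizes candidate lncRNAs by
    expression presence, guilt-by-association correlation, hypergeometric
    pathway over-representation, and median-split log-rank survival
    screening. A synthetic-data module generates association tables,
    differential-expression statistics, expression matrices and survival
    cohorts with planted ground-truth motifs so the full pipeline can be
    exercised and validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    igraph,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
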