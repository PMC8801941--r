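Package: sigcorr
Title: Signature-Correlation Screening for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("sigcorr", "maintainers", email = "sigcorr@example.org", role = c("aut", "cre"))
Description: A tested pipeline for gene-signature correlation screening in
    single-cell RNA-seq data: per-cell signature scoring as the percentage of
    total UMI counts in a gene set, per-cluster Pearson correlation screens
    with threshold-ranked tables, top-k transcription-factor correlation
    ranking, cross-condition correlation-shift detection, Wilcoxon rank-sum
    differential expression, a competitive gene-set test with inter-gene
    correlation (VIF) adjustment, and a permutation ligand-receptor
    co-expression test. Ships a negative-binomial scRNA-seq simulator with
    planted clusters, co-varying gene modules and condition effects so every
    stage is verifiable against a known ground truth at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
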