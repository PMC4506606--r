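Package: mitoclass
Title: Mitogenic Classifier Genes and Relative Mitogenic Potential of
    Insulin Analogues
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives transcriptomic mitogenic classifier gene sets that
    discriminate IGF1R-driven from INSR-driven insulin-analogue signalling,
    and ranks compounds by their relative mitogenic potential (the sum of
    absolute log2 fold changes over the classifier genes). Implements the
    supporting statistical pipeline: between-array quantile normalization,
    Tukey median-polish probe-set summarization, gene-wise group-mean linear
    models with empirical-Bayes moderated t contrasts against vehicle,
    Benjamini-Hochberg FDR control, Venn partitioning of DEG sets,
    mitogenic/metabolic response clusters, hierarchical clustering of
    compounds, 2^-ddCt relative quantification of qPCR data, and a synthetic
    data generator emulating a receptor-isoform cell-line panel
    (IRA/IRB/IGF1R x treatments x time points) with planted gene programs
    and a scaled inverse-chi-square variance prior for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2), SummarizedExperiment
Imports: methods, stats, utils, S4Vectors, ape
Suggests: testthat (>= 3.0.0), limma, jsonlite, withr
Config/testthat/edition: 3
biocViews: GeneExpression, Microarray, DifferentialExpression, Classification
RoxygenNote: 7.3.3
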