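Package: wmsig
Title: SAM-Based Three-Group Differential Expression and Progression
    Signature Analysis for IgM MGUS / Waldenstrom Macroglobulinemia
    Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline for comparing bone-marrow B-cell (CD19+) and
    plasma-cell (CD138+) expression profiles across Waldenstrom
    Macroglobulinemia (WM), IgM monoclonal gammopathy of undetermined
    significance (IgM MGUS) and healthy controls. Implements Significance
    Analysis of Microarrays (SAM): moderated d statistics with an
    exchangeability constant s0, label-permutation null distributions,
    delta-thresholded gene calling at a target false discovery rate,
    q-values and pairwise permutation p-values. Significant genes are
    classified into four fold-change patterns across the three groups, a
    progression-candidate filter extracts genes with indistinguishable WM
    and MGUS expression that both differ from controls, and sample
    similarity is summarised by a minimum spanning tree over Euclidean
    distances. Includes quantile normalization and empirical-Bayes batch
    adjustment wrappers, probe-set to gene collapsing, a synthetic-data
    generator emulating the study design with planted ground truth, and
    the published differential-expression tables of GEO series GSE171739
    as worked-example fixtures.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    limma,
    sva,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
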