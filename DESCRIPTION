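Package: igora
Title: Imprinted-Gene Enrichment Screening and RNAscope Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether a curated gene set (typically imprinted
    genes) is over-represented among the genes upregulated in individual
    cell-identity groups of a single-cell RNA-seq dataset, and for quantifying
    per-cell RNAscope (smFISH) signal tables. The enrichment pipeline runs a
    gene-wise one-sided Wilcoxon rank-sum upregulation screen per identity
    group, applies a horizontal (per-gene) Benjamini-Hochberg correction,
    calls upregulated genes by q-value and log2 fold-change thresholds, and
    tests set over-representation with an eligibility-gated one-sided Fisher
    exact test under Bonferroni control. The RNAscope module derives channel
    detection thresholds from no-probe controls, resolves fluorescent
    clusters into molecule counts, classifies cells by positivity rules, and
    summarises expression as positives per 1000 cells, H-scores and
    class-wise fold changes, with Mann-Whitney, Kruskal-Wallis and Dunn
    post-hoc comparisons. A synthetic-data module generates count matrices
    and spot tables with the statistical structure the analysis assumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
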