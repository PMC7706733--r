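Package: hybridexpr
Title: Expression Inheritance, Misexpression and Cis-Trans Regulatory
    Divergence from Hybrid RNA-seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk RNA-seq read counts from two parental
    species and their F1 hybrids across tissues. Provides a self-contained
    negative-binomial differential-expression engine (median-of-ratios size
    factors, trended dispersion shrinkage, Wald tests, shrunken log2 fold
    changes), classification of expression inheritance into six modes
    (conserved, additive, dominant toward either parent, over- and
    underdominant), misexpression calling, gene-level allele-specific
    expression testing by beta-binomial aggregation of phased SNP counts with
    a population-level calling rule, tissue-specificity (tau) and TPM
    summaries, between-groups PCA with a Monte-Carlo inertia test, and the
    statistical battery linking expression divergence to allele-specific
    expression, conserved noncoding elements and chromosome class
    (Mann-Whitney, chi-squared, hypergeometric fast-Z, binomial/linear GLMs).
    A seeded synthetic-data generator emulating the study design (two parental
    groups plus hybrids over multiple tissues, with cis, trans and
    compensatory regulatory architectures) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2
Config/testthat/edition: 3
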