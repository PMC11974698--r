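Package: hapshuffle
Title: Feature Ablation by Shuffling for Haplotype-Matrix Predictors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Interprets classifiers and regressors that consume binary
    haplotype-by-site matrices (the "image" input of population-genetic
    neural networks) by shuffling the input in ways that each destroy a
    known class of population-genetic summary statistics: column order
    (short-scale linkage disequilibrium), within-column entries
    (haplotype structure and long-scale LD), all entries (the allele
    frequency spectrum), and block-grouping of derived alleles with or
    without the zero-padding boundary preserved (total diversity).
    Provides readers for ms-style simulator output, phased VCF and a
    plain-text matrix archive; the targeted summary statistics (AFS,
    pairwise heterozygosity, Garud's H1, pairwise r-squared); synthetic
    generators with controllable AFS, LD and haplotype diversity;
    statistic-threshold oracle predictors; and a predictor-agnostic
    degradation harness reporting accuracy, confusion matrices, ROC/AUC,
    Spearman's r and RMSE per shuffle level, with percentile confidence
    intervals across predictor instances.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
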