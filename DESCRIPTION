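Package: connstab
Title: Stability of Connectivity-Mapping Compound Discovery Under
    Reduced RNA-Seq Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantifies how reduced cDNA sequencing depth perturbs RNA-seq
    differential-expression gene signatures and the compound connections
    derived from them by gene expression connectivity mapping. Provides
    binomial thinning of gene-level counts to emulate lower sequencing
    depth, relative-log-expression normalization with a negative-binomial
    Wald test, length-bias-aware category enrichment, signature scoring
    against perturbagen reference profiles with permutation significance,
    and a fraction-by-iteration robustness grid reporting relative
    false-discovery rates, connection frequencies, Venn set partitions and
    top-k compound stability. A synthetic-data generator with planted
    differentially expressed genes and planted reverser/progressor
    compounds supports end-to-end validation with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    DESeq2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
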