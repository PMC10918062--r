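Package: mirprop
Title: miRNA-mRNA Inverse-Correlation Integration with One-Proportion Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integration analysis of miRNA and mRNA expression for two-group
    bulk sequencing designs, modelled on placental studies of fetal growth
    restriction. Provides counts-per-million and trimmed-mean-of-M-values
    (TMM) normalization, per-feature differential expression (pooled-variance
    t, Fisher exact, chi-squared, one-way ANOVA), abundance-based selection
    of the most expressed miRNAs, Spearman correlation of miRNAs against
    predicted mRNA targets with exact permutation p-values at small sample
    sizes, and a continuity-corrected one-proportion test with exact
    Clopper-Pearson confidence intervals on the fraction of inversely
    correlated targets per miRNA. Includes a seeded negative-binomial
    two-omics simulator with planted differential expression and inverse
    regulator-target coupling, and a file-based pipeline with deterministic,
    hash-manifested outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    jsonlite
Config/testthat/edition: 3
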