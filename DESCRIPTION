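Package: rhemc
Title: Randomized Haseman-Elston Regression for Multiple Variance Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scalable method-of-moments estimation of SNP heritability and its
    partitioning across genomic annotations. Implements randomized
    multi-component Haseman-Elston regression: variance components for
    disjoint MAF/LD bins, overlapping binary annotations and non-negative
    continuous annotations are estimated from a single streaming pass over
    PLINK-format genotypes using a Hutchinson sketch in place of exact
    genetic-relatedness-matrix traces, with delete-one-block jackknife
    standard errors and enrichment Z-tests. Includes an exact dense
    small-sample oracle for validation and a genotype/phenotype simulator
    with MAF- and LD-coupled effect-size architectures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), optparse, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
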