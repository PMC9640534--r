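Package: invfert
Title: Inversion Diplotype Calling and Zero-Inflated Negative-Binomial
    Association with Family Size
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for testing association between the chromosome 17q21.31
    H1/H2 inversion and numbers of children in population cohorts. Calls
    inversion diplotypes (H1_H1, H1_H2, H2_H2) from unphased tag-SNP
    genotypes in PLINK text PED/MAP format, fits weighted zero-inflated
    negative-binomial regression in which small family sizes (0-3 children)
    are recoded as non-events, computes pairwise linkage disequilibrium
    (EM haplotype frequencies, D, D', r-squared, LOD) for surrogate-SNP
    selection within +/-50 kb, and produces genotype-by-family-size
    descriptive tables with dominance and recessive contrasts. A synthetic
    cohort generator with known ground truth supports validation of every
    stage without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), glmmTMB, MASS, jsonlite, withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
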