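Package: snpxe
Title: Pattern-Search Testing of SNP-Environment Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects SNP-environment interactions associated with a binary
    or continuous phenotype by enumerating a designed family of interaction
    regression patterns per SNP-environment pair (model structure x SNP
    inheritance mode x risk direction), fitting each with logistic or linear
    regression, and selecting the best pattern by BIC or by the smallest
    interaction p-value. Companion tools compute allele and minor-allele
    frequency summaries, SNP main-effect tests under additive, dominant and
    recessive inheritance modes, outcome-proportion grids by genotype and
    exposure level with heat-table rendering, batch scans with Bonferroni
    correction, a synthetic case-control data generator under
    Hardy-Weinberg equilibrium, and delimited-file plus PLINK .raw readers
    with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, grDevices
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
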