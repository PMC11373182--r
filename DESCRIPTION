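Package: seggwas
Title: Segregation GWAS for Monogenic Categorical Traits with Incomplete
    Penetrance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Genome-wide association for categorical traits governed by a
    single biallelic locus with possibly incomplete, sex-dependent
    penetrance. Posterior genotype probabilities at the putative locus are
    computed from pedigree and phenotype data by iterative peeling; the
    penetrance matrix and founder allele frequency are estimated by
    expectation-maximisation; the probabilities are linearised as expected
    allele counts (EAC) and regressed on SNP genotypes in an additive GWAS.
    Includes a gene-drop simulator (Wright-Fisher burn-in, half-sib
    pedigree generator, penetrance-driven phenotype assignment) to quantify
    the maximum achievable correlation between EAC and a causative
    mutation under varying penetrance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
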