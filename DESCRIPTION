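Package: rnagt
Title: Bayesian Genotype Calling from RNA-Seq Allele Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls genotypes at known biallelic SNPs from RNA-seq allele
    counts using a mixture of three beta-binomial distributions, one per
    genotype. Component means and overdispersions are learned from a random
    subset of sites by Markov chain Monte Carlo, so that allele-specific
    expression and reference mapping bias are absorbed into the learned
    read-count distributions instead of being mistaken for genotype signal.
    The fitted model yields per-site genotype posteriors, dosages and hard
    calls, written as VCF or TSV. Includes a naive count-threshold caller,
    genotype-concordance benchmarking utilities stratified by genotype and
    read depth, a synthetic-data generator under the model's generative
    process, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
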