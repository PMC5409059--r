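Package: cleftgwas
Title: Post-GWAS Statistical Toolkit for Orofacial Cleft Association Studies
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Dosage-based association testing for case-control and
    case-parent-trio designs on imputed genotypes, Z-score and
    inverse-variance meta-combination, Bayesian credible-SNP refinement over
    recombination-distance windows, enrichment of association signal in
    cis-regulatory annotation via binned trend tests, and polygenic-score
    analyses including a transmitted/non-transmitted trio score. A synthetic
    cohort generator with block-LD haplotypes, multiplicative risk models,
    ascertained trios and imputation-quality degradation provides ground
    truth for every analysis stage, so the whole pipeline is testable
    without access-controlled genotype data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    VariantAnnotation,
    knitr
Config/testthat/edition: 3
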