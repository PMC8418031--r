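Package: polydose
Title: Allele Dosage Genotyping of Polyploids from Quantitative PCR
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-allele relative copy numbers at a biallelic locus
    from quantitative PCR cycle-threshold (Ct) data by the delta-delta-Ct
    method, converts them to the allele dosage statistic b and the theta
    angle, and calls allelic configurations (e.g. AAa, Aaaa) at any ploidy.
    Includes a simulator for homozygote DNA-mixture libraries and synthetic
    qPCR plates, separability diagnostics (complete-linkage clustering and
    one-way ANOVA), and a polysomic inheritance module that derives gamete
    distributions from parental configurations, expected phenotype ratios
    for dominant/recessive loci, and chi-square goodness-of-fit tests of
    Mendelian segregation in polyploid crosses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
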