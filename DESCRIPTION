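Package: aseMeta
Title: Meta-Analysis Based Detection of Allele-Specific Expression from
    RNA-Seq Allelic Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects allele-specific expression (ASE) from RNA-Seq
    reference/alternative allele read counts at heterozygous SNVs, without
    requiring haplotype phase. Per-SNV counts are modelled as beta-binomial
    to allow for overdispersion, transformed with the variance-stabilizing
    Freeman-Tukey double-arcsine transform, and combined across SNVs of a
    gene by inverse-variance-weighted meta-analysis into a gene-level major
    haplotype frequency (MAF) estimate. When phase is unknown a "voting"
    pseudo-phasing assigns the higher-count allele at each SNV to a putative
    major haplotype; the resulting anti-conservative nominal inference is
    corrected by Monte-Carlo simulation of the full pipeline under the null,
    yielding calibrated empirical p-values for ASE and for inter-SNV
    heterogeneity (isoform-specific ASE). A two-sample mode tests for
    differential allelic imbalance (e.g. tumor versus matched normal) using
    haplotype-frequency differences anchored on the sample of interest.
    Includes global reference-bias and overdispersion estimators, filtering
    of heterozygous SNV tables, Benjamini-Hochberg based calling rules, and
    a stratified power/FDR simulation benchmark.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    vcfR,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
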