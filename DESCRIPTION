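Package: freqscan
Title: Allele-Frequency Differentiation Scans for Tiny Sequenced Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing exome variants in very small cohorts
    (of the order of seven individuals) against continental reference-panel
    allele frequencies. Classifies variants by functional impact, a
    SIFT/PolyPhen union deleteriousness rule and health-database linkage
    tiers; detects alleles at significantly different frequency using exact
    one-tailed binomial tests against panel frequencies combined with
    Weir-Cockerham Fst and Storey q-value false-discovery-rate control;
    quantifies how representative a tiny cohort's allele frequencies are of
    the source population via Pearson correlation with Fisher-z intervals
    and subsampling experiments; and simulates structured-population
    genotype data under the Balding-Nichols model so that every stage of
    the pipeline can be tested against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
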