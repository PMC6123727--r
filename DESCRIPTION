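Package: introkit
Title: F-Statistics, Admixture Graphs and Drift Dating for Whole-Genome
    Introgression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises introgressive hybridization from
    genome-wide SNP data. Reads multi-sample VCFs, applies standard site
    filters (depth, genotype quality, minor allele frequency, scaffold
    size, private alleles) and linkage-disequilibrium thinning, and
    partitions scaffolds into pseudo-chromosomes. Computes f2, f3 and f4
    drift statistics with weighted block-jackknife standard errors, runs
    the three-population admixture scan, estimates admixture proportions
    by f4-ratio and by fitting admixture graphs under the Gaussian drift
    model, places hybrid populations onto a non-admixed backbone by
    exhaustive attachment search with block-bootstrap intervals, and
    converts mixed-drift branch lengths to generations and calendar years
    via D = 1 - exp(-t / (2 Ne)). A Balding-Nichols graph simulator and a
    forward Wright-Fisher oracle make every stage testable on synthetic
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    pracma,
    stats,
    utils,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
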