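Package: SweepScanX
Title: Hard and Soft Selective Sweep Detection on the X Chromosome and Autosomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward Wright-Fisher simulation of selective sweeps with explicit
    X-chromosome transmission and dosage compensation, haplotype-homozygosity
    scan statistics (H1, H2, H12, H2/H1) with SNP-density-calibrated windows,
    simulation-based false-discovery-rate peak calling, and an approximate
    Bayesian computation classifier that assigns hard or soft labels to sweep
    peaks from their (H12, H2/H1) coordinates. Includes a synthetic-data
    generator emulating Drosophila Genome Nexus style phased haplotype panels
    with residual-heterozygosity missingness and recombination maps, so the
    full pipeline runs end-to-end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
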