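Package: ovipop
Title: Population-Genomic Characterization of Sheep Breeds from SNP-Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for the population-genomic characterization of livestock
    breeds genotyped on SNP arrays, with defaults tuned to sheep (26
    autosomes). Reads and writes PLINK bed/bim/fam and ped/map files,
    applies missingness-based quality control and sliding-window LD
    pruning, and computes per-breed observed and expected heterozygosity,
    F_IS, Weir-Cockerham and Hudson F_ST, Nei and Reynolds genetic
    distances, and genotype PCA with Patterson scaling. Detects runs of
    homozygosity (ROH) per individual with a false-positive-controlled
    minimum-SNP threshold and derives genomic inbreeding coefficients
    (F_ROH) by length class. Estimates current and historical effective
    population size from recombination-binned linkage disequilibrium via
    the Sved relationship. Includes a forward-in-time Wright-Fisher
    simulator with recombination, population splits, bottleneck schedules
    and planted close-relative matings, so every estimator can be
    validated against fixtures with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
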