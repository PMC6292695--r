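Package: gminscan
Title: Windowed Introgression Scans with the G_min Statistic and Coalescent Nulls
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genome scans for recent introgression between two closely
    related populations or species from phased or inbred-line haplotype
    data. Computes windowed population-genetic summary statistics
    (nucleotide diversity, Tajima's D, ZnS linkage disequilibrium, D_XY,
    net divergence, F_ST), the G_min ratio statistic with per-window
    Monte Carlo p-values against a two-population clean-split coalescent
    null, plug-in false discovery rates, introgression-tract calling,
    frequency-weighted ABBA-BABA (Patterson's D) tests with block
    jackknife standard errors, and locus-colocalization permutation
    tests. Includes a self-contained coalescent simulator and a
    synthetic-data generator with known introgression truth so the whole
    pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
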