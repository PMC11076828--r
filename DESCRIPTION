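Package: locadapt
Title: Local-Adaptation Genomics of Structured Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for detecting local adaptation from multi-population
    whole-genome resequencing data. Reads and hard-filters VCF genotypes,
    computes windowed nucleotide diversity, DXY and Weir-Cockerham FST,
    builds 1D and joint site-frequency spectra with hypergeometric
    projection, fits site-frequency-spectrum demographic models by
    coalescent simulation and composite likelihood with AIC model
    comparison and parametric bootstrap, scans for selective sweeps with
    XP-CLR and FST outliers merged into highly differentiated regions,
    computes Fay and Wu's H, runs per-gene McDonald-Kreitman tests, and
    performs redundancy-analysis genotype-environment association with
    loading outliers and enrichment tests. Includes a truth-annotated
    coalescent data generator emitting complete VCF/GFF3/alignment
    bundles for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
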