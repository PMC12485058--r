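Package: purgecheck
Title: K-mer Validation of Pseudo-Haplotype Genome Assemblies
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to judge whether haplotype purging of a diploid genome
    assembly was successful, using k-mer spectra from whole-genome
    sequencing reads. Implements canonical k-mer counting and Jellyfish
    style histogram I/O, a light-weight spectrum-based estimator of
    haploid genome size and heterozygosity, Merqury-style assembly k-mer
    completeness and consensus quality value (QV) estimation, and a
    closed-form model of the maximum and expected k-mer completeness of a
    purged pseudo-haplotype assembly given the organism's heterozygosity.
    A diploid genome and read simulator with known truth makes the whole
    pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
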