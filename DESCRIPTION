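Package: tdt2g
Title: Two-Group Multimarker Transmission/Disequilibrium Tests for Family Trios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Family-based haplotype association testing for nuclear-family
    trios with one affected child. Implements the two-group multimarker
    transmission/disequilibrium test (2G-TDT), a one-degree-of-freedom
    holdout test that learns disease-susceptibility and protective haplotype
    groups on a training half of the trios and scores a McNemar statistic on
    the held-out half, assigning unseen haplotypes to groups by a
    length-similarity rule. Also provides the classic biallelic TDT, the
    multimarker heterozygosity TDT, and the maximum one-versus-rest TDT
    (plain and holdout variants), trio phase resolution from unphased
    genotypes, LINKAGE PED/MAP and ms-format input/output, a sliding-window
    scan engine with per-marker p-value aggregation, trio simulators
    (stratified/admixed null populations, disease-linked trios drawn from a
    coalescent haplotype pool, missing-data injection), and a replicate-level
    evaluation harness for type-I error, power, locus specificity and sample
    reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
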