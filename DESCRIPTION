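Package: paleopair
Title: Pair-Based Population Genetic Analysis of Low-Coverage Ancient Genomes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing one or two low-coverage ancient genomes
    against a modern SNP reference panel: pseudohaploid genotype calling with
    transition masking, a reference-free pseudo-twin kinship test, conditional
    nucleotide diversity on ascertained transversions, outgroup f3 and
    Patterson's D statistics with weighted block-jackknife standard errors,
    qpAdm-style constrained admixture-proportion modelling with feasibility
    flagging, chromosomal sex inference from X/Y read counts, and pileup-based
    phenotype screening (lactase persistence and user-configured variants).
    Ships a synthetic-data generator (drift-structured allele frequencies,
    admixture, relatedness classes, sequencing error, deamination damage,
    contamination) so every statistic can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
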