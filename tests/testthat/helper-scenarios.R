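# Shared simulation scenarios. Parameter choices (sample sizes, drift
# levels) are fixed once and documented in the methods vignette; tests and
# the acceptance suite use these helpers unchanged.

# small deterministic panel for format and unit tests
toy_panel <- function() {
  snp_panel(snp_id = paste0("rs", 1:6),
            chrom = c(1, 1, 1, 2, 2, 2),
            physical_pos = c(100, 200, 300, 50, 150, 250),
            allele1 = c("C", "A", "G", "T", "A", "C"),
            allele2 = c("T", "C", "A", "A", "T", "G"))
}

toy_geno <- function(panel = toy_panel()) {
  set.seed(99)
  g <- matrix(sample(c(0:2, NA), nrow(panel) * 4, replace = TRUE,
                     prob = c(0.3, 0.3, 0.3, 0.1)), nrow(panel), 4)
  genotype_panel(panel,
                 data.frame(id = paste0("i", 1:4),
                            pop = c("A", "A", "B", "B")), g)
}

# the pseudo-twin kinship scenario: one panmictic population, a pair at
# mean depth 5 over 20k ascertained SNPs
kin_config <- function(seed, relatedness = "unrelated", error = 0,
                       n_snps = 20000, depth = 5, F = 0.01) {
  sim_config(n_snps,
             pops = list(pop_spec("P", F = F, n = 0)),
             pair = pair_spec("P", relatedness, depth = depth, error = error),
             seed = seed)
}

run_kin_pipeline <- function(seed, relatedness = "unrelated", error = 0,
                             mask_transitions = FALSE, ...) {
  sim <- simulate_dataset(kin_config(seed, relatedness, error, ...))
  set.seed(seed + 1000000L)
  kinship_test(
    make_pseudo_twins(sim$pair$pileup1, sim$panel, mask_transitions),
    make_pseudo_twins(sim$pair$pileup2, sim$panel, mask_transitions),
    call_pseudohaploid(sim$pair$pileup1, sim$panel, mask_transitions),
    call_pseudohaploid(sim$pair$pileup2, sim$panel, mask_transitions),
    sim$panel)
}

# admixture-recovery scenario: target = 0.6 S1 + 0.4 S2; two of the six
# rights are sisters of the sources (via the unsampled ancestors Anc1/Anc2),
# which makes the source f4 profiles distinguishable
qp_config <- function(seed, n_snps = 50000, weights = c(0.6, 0.4)) {
  sim_config(
    n_snps,
    pops = list(
      pop_spec("Anc1", F = 0.05, n = 0),
      pop_spec("Anc2", F = 0.05, n = 0),
      pop_spec("S1", F = 0.05, n = 20, parent = "Anc1"),
      pop_spec("S2", F = 0.05, n = 20, parent = "Anc2"),
      pop_spec("R1", F = 0.2, n = 15),
      pop_spec("R2", F = 0.05, n = 15, parent = "Anc1"),
      pop_spec("R3", F = 0.05, n = 15, parent = "Anc2"),
      pop_spec("R4", F = 0.1, n = 15),
      pop_spec("R5", F = 0.15, n = 15),
      pop_spec("R6", F = 0.25, n = 15),
      pop_spec("T", n = 10, sources = c("S1", "S2"), weights = weights,
               F = 0.01)
    ), seed = seed)
}

qp_rights <- paste0("R", 1:6)

run_qpadm_pipeline <- function(seed, sources = c("S1", "S2"), ...) {
  sim <- simulate_dataset(qp_config(seed, ...))
  ft <- allele_frequencies(sim$geno)
  fit_qpadm("T", sources, qp_rights, ft, sim$panel)
}

# star phylogeny of four sampled populations: any D between distinct
# populations is a null topology
null_d_config <- function(seed, n_snps = 20000) {
  sim_config(n_snps,
             pops = list(pop_spec("W", F = 0.05, n = 15),
                         pop_spec("X", F = 0.05, n = 15),
                         pop_spec("Y", F = 0.1, n = 15),
                         pop_spec("Z", F = 0.2, n = 15)),
             seed = seed)
}

# affinity-ranking scenario: pair drawn from P, candidates P/C2/C3, outgroup O
rank_config <- function(seed, n_snps = 10000) {
  sim_config(n_snps,
             pops = list(pop_spec("P", F = 0.05, n = 15),
                         pop_spec("C2", F = 0.05, n = 15),
                         pop_spec("C3", F = 0.1, n = 15),
                         pop_spec("O", F = 0.3, n = 15)),
             pair = pair_spec("P", "unrelated", depth = 1),
             seed = seed)
}

run_rank_pipeline <- function(seed) {
  sim <- simulate_dataset(rank_config(seed))
  set.seed(seed + 2000000L)
  ph1 <- call_pseudohaploid(sim$pair$pileup1, sim$panel)
  ph2 <- call_pseudohaploid(sim$pair$pileup2, sim$panel)
  ft <- allele_frequencies(sim$geno, pseudo = list(test = list(ph1, ph2)))
  rank_affinity("test", c("P", "C2", "C3"), "O", ft, sim$panel)
}

# hand-built frequency table (bypasses genotype sampling) for arithmetic
# oracle tests
manual_freq_table <- function(freq) {
  structure(list(freq = freq,
                 count = matrix(2L, nrow(freq), ncol(freq),
                                dimnames = dimnames(freq))),
            class = "freq_table")
}
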