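test_that("config validation rejects inconsistent specifications", {
  expect_error(pop_spec("A", F = 1), "F < 1")
  expect_error(pop_spec("A", sources = c("B"), weights = c(0.5)),
               "sum to 1")
  expect_error(sim_config(100, list(pop_spec("A"), pop_spec("A"))),
               "duplicate")
  expect_error(sim_config(100, list(pop_spec("B", parent = "A"))),
               "undefined")
  expect_error(pair_spec("P", contamination = 0.1), "contaminant")
  expect_error(sim_config(100, list(pop_spec("P")),
                          pair = pair_spec("Q")), "not defined")
})

test_that("zero drift copies the ancestral frequencies exactly", {
  cfg <- sim_config(500, list(pop_spec("A", F = 0), pop_spec("B", F = 0)),
                    seed = 4)
  fr <- simulate_frequencies(cfg)
  expect_identical(fr$freq[, "A"], fr$ancestral)
  expect_identical(fr$freq[, "B"], fr$ancestral)
})

test_that("Balding-Nichols frequencies match the moment oracle", {
  # E[p] = p0, Var[p] = F p0 (1 - p0): check against Monte Carlo moments
  cfg <- sim_config(50000, list(pop_spec("A", F = 0.05)), seed = 12)
  fr <- simulate_frequencies(cfg)
  p0 <- fr$ancestral
  dev <- fr$freq[, "A"] - p0
  expect_lt(abs(mean(dev)), 0.002)
  expect_equal(mean(dev^2), 0.05 * mean(p0 * (1 - p0)), tolerance = 0.03)
})

test_that("identical seed gives bitwise-identical output", {
  cfg <- sim_config(200, list(pop_spec("A", F = 0.1, n = 2)),
                    pair = pair_spec("A", depth = 3), seed = 77)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$freqs, b$freqs)
  expect_identical(a$geno$geno, b$geno$geno)
  expect_identical(a$pair$pileup1$obs, b$pair$pileup1$obs)
})

test_that("genotypes are Binomial(2, p): boundaries and moments", {
  panel <- simulate_panel(3)
  freq <- matrix(c(0, 1, 0.5), 3, 1, dimnames = list(NULL, "A"))
  set.seed(9)
  gp <- simulate_genotype_panel(panel, freq, c(A = 10000L))
  expect_true(all(gp$geno[1, ] == 0L))
  expect_true(all(gp$geno[2, ] == 2L))
  expect_equal(mean(gp$geno[3, ]), 1.0, tolerance = 0.03)
  expect_equal(mean(gp$geno[3, ] == 1L), 0.5, tolerance = 0.03)
})

test_that("read depth is Poisson with the configured mean", {
  cfg <- sim_config(20000, list(pop_spec("P", F = 0.02)),
                    pair = pair_spec("P", depth = 5), seed = 31)
  sim <- simulate_dataset(cfg)
  expect_equal(nrow(sim$pair$pileup1$obs) / 20000, 5, tolerance = 0.02)
})

test_that("noiseless homozygous sites yield unanimous reads", {
  cfg <- sim_config(2000, list(pop_spec("P", F = 0.02)),
                    pair = pair_spec("P", depth = 8), seed = 6)
  sim <- simulate_dataset(cfg)
  hom1 <- which(sim$pair$truth$g1 == 2)   # homozygous allele1
  obs <- sim$pair$pileup1$obs
  expect_true(all(obs$base[obs$site %in% hom1] == 1L))
})

test_that("identical relatedness duplicates the genotype vector", {
  cfg <- sim_config(1000, list(pop_spec("P", F = 0.02)),
                    pair = pair_spec("P", "identical", depth = 2), seed = 13)
  sim <- simulate_dataset(cfg)
  expect_identical(sim$pair$truth$g1, sim$pair$truth$g2)
  expect_equal(sim$pair$truth$theta, 0.5)
})

test_that("full contamination reproduces the contaminant frequencies", {
  cfg <- sim_config(20000,
                    list(pop_spec("P", F = 0.02), pop_spec("C", F = 0.3)),
                    pair = pair_spec("P", depth = 3, contamination = 1,
                                     contaminant = "C"),
                    seed = 15)
  sim <- simulate_dataset(cfg)
  obs <- sim$pair$pileup1$obs
  read_freq <- tapply(obs$base == 1L, obs$site, mean)
  pc <- sim$freqs$freq[as.integer(names(read_freq)), "C"]
  # aggregate allele1 fraction must match the contaminant population
  expect_equal(mean(obs$base == 1L), weighted.mean(pc, tabulate(obs$site)[as.integer(names(read_freq))]),
               tolerance = 0.01)
  expect_gt(cor(as.vector(read_freq), pc), 0.5)
})

test_that("damage hits transition sites only", {
  base_cfg <- function(damage) {
    sim_config(5000, list(pop_spec("P", F = 0.02)),
               pair = pair_spec("P", depth = 4, damage = damage), seed = 42)
  }
  undamaged <- simulate_dataset(base_cfg(0))
  damaged <- simulate_dataset(base_cfg(0.3))
  tv <- damaged$panel$mutation_class == "transversion"
  keep_tv <- function(pu) pu$obs[tv[pu$obs$site], c("site", "base")]
  # transversion-site reads are invariant to the damage rate (qualities are
  # drawn after the damage step, so only site/base can be compared)
  expect_identical(keep_tv(damaged$pair$pileup1),
                   keep_tv(undamaged$pair$pileup1))
  # while transition sites do change
  ts_obs_d <- damaged$pair$pileup1$obs[!tv[damaged$pair$pileup1$obs$site], ]
  ts_obs_u <- undamaged$pair$pileup1$obs[!tv[undamaged$pair$pileup1$obs$site], ]
  expect_false(identical(ts_obs_d$base, ts_obs_u$base))
})

test_that("admixed frequencies are the weighted source mixture before drift", {
  cfg <- sim_config(20000,
                    list(pop_spec("S1", F = 0.1), pop_spec("S2", F = 0.1),
                         pop_spec("M", sources = c("S1", "S2"),
                                  weights = c(0.7, 0.3), F = 0)),
                    seed = 23)
  fr <- simulate_frequencies(cfg)
  expect_equal(fr$freq[, "M"],
               0.7 * fr$freq[, "S1"] + 0.3 * fr$freq[, "S2"])
})
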