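test_that("snp_panel enforces its invariants", {
  p <- toy_panel()
  expect_s3_class(p, "snp_panel")
  # sorted by (chrom, pos)
  expect_true(all(diff(order(chrom_order(p$chrom), p$physical_pos)) == 1))
  # transition classification: C/T and G/A only
  expect_equal(p$mutation_class,
               c("transition", "transversion", "transition",
                 "transversion", "transversion", "transversion"))
  expect_error(snp_panel("a", 1, 1, "C", "C"), "allele1 == allele2")
  expect_error(snp_panel(c("a", "a"), c(1, 1), c(1, 2),
                         c("C", "C"), c("T", "T")), "duplicate")
  expect_error(snp_panel("a", 1, 1, "C", "X"), "unknown allele")
})

test_that("EIGENSTRAT round-trip reproduces panel and genotypes", {
  gp <- toy_geno()
  prefix <- file.path(tempdir(), "toy")
  write_eigenstrat(gp, prefix)
  back <- read_eigenstrat(prefix)
  expect_equal(back$panel, gp$panel)
  expect_equal(back$geno$geno, gp$geno)
  expect_equal(back$geno$ind, gp$ind)

  # larger randomized round-trip
  set.seed(11)
  sim <- simulate_dataset(sim_config(1000,
    pops = list(pop_spec("A", F = 0.1, n = 3),
                pop_spec("B", F = 0.2, n = 2)), seed = 5))
  prefix2 <- file.path(tempdir(), "sim1000")
  write_eigenstrat(sim$geno, prefix2)
  back2 <- read_eigenstrat(prefix2)
  expect_equal(back2$geno$geno, sim$geno$geno)
  expect_equal(back2$panel, sim$panel)
})

test_that("geno coding: 9 is missing, one digit per individual", {
  prefix <- file.path(tempdir(), "code")
  writeLines(c("rs1\t1\t0\t100\tA\tC"), paste0(prefix, ".snp"))
  writeLines(c("i1\tU\tP1", "i2\tU\tP2"), paste0(prefix, ".ind"))
  writeLines("09", paste0(prefix, ".geno"))
  es <- read_eigenstrat(prefix)
  expect_equal(as.vector(es$geno$geno), c(0L, NA))

  # 1 SNP, 3 individuals, genotypes (0,1,2) -> body line "012"
  p <- snp_panel("rs1", 1, 100, "A", "C")
  gp <- genotype_panel(p, data.frame(id = c("a", "b", "c"), pop = "P"),
                       matrix(c(0L, 1L, 2L), 1))
  write_eigenstrat(gp, prefix)
  expect_equal(readLines(paste0(prefix, ".geno")), "012")
})

test_that("empty panel writes and reads three valid empty-bodied files", {
  gp <- genotype_panel(empty_panel(),
                       data.frame(id = character(), pop = character()),
                       matrix(integer(), 0, 0))
  prefix <- file.path(tempdir(), "empty")
  write_eigenstrat(gp, prefix)
  for (ext in c(".geno", ".snp", ".ind")) {
    expect_true(file.exists(paste0(prefix, ext)))
  }
  back <- read_eigenstrat(prefix)
  expect_equal(nrow(back$panel), 0L)
  expect_equal(dim(back$geno$geno), c(0L, 0L))
})

test_that("dimension mismatches name the offending file", {
  prefix <- file.path(tempdir(), "bad")
  writeLines(c("rs1\t1\t0\t100\tA\tC", "rs2\t1\t0\t200\tA\tC"),
             paste0(prefix, ".snp"))
  writeLines("i1\tU\tP1", paste0(prefix, ".ind"))
  writeLines("0", paste0(prefix, ".geno"))   # one row, two SNPs
  expect_error(read_eigenstrat(prefix), "bad\\.geno")
  writeLines(c("0", "00"), paste0(prefix, ".geno"))  # row width mismatch
  expect_error(read_eigenstrat(prefix), "line 2")
})

test_that("pileup ingestion applies quality thresholds and site matching", {
  panel <- toy_panel()
  path <- file.path(tempdir(), "p.tsv")
  writeLines(c("#chrom\tpos\tbase\tbase_quality\tmapping_quality",
               "1\t100\tC\t31\t31",
               "1\t100\tT\t29\t31",    # fails q_min
               "1\t100\tG\t31\t31",    # neither allele: kept, flagged other
               "1\t999\tC\t31\t31"),   # off-panel site
             path)
  expect_warning(pu <- read_pileup(path, panel, q_min = 30, Q_min = 30),
                 "absent from the panel")
  expect_equal(nrow(pu$obs), 2L)
  expect_equal(sort(pu$obs$base), c(1L, 3L))
  expect_equal(pu$filters$n_dropped_quality, 1L)
  expect_equal(pu$filters$n_dropped_offpanel, 1L)

  # empty file -> valid empty PileupData
  writeLines("# header only", path)
  pu0 <- read_pileup(path, panel)
  expect_equal(nrow(pu0$obs), 0L)

  writeLines("1\t100\tC\t31", path)
  expect_error(read_pileup(path, panel), "malformed pileup line 1")
})

test_that("raising thresholds never increases retained reads", {
  panel <- toy_panel()
  path <- file.path(tempdir(), "mono.tsv")
  set.seed(3)
  n <- 200
  rows <- sprintf("%s\t%d\t%s\t%d\t%d",
                  panel$chrom[(1:n - 1) %% 6 + 1],
                  panel$physical_pos[(1:n - 1) %% 6 + 1],
                  sample(c("A", "C", "G", "T"), n, TRUE),
                  sample(20:45, n, TRUE), sample(20:45, n, TRUE))
  writeLines(rows, path)
  counts <- sapply(c(20, 25, 30, 35, 40), function(q)
    nrow(read_pileup(path, panel, q_min = q, Q_min = q)$obs))
  expect_true(all(diff(counts) <= 0))
})

test_that("pileup round-trip preserves observations", {
  set.seed(21)
  sim <- simulate_dataset(sim_config(500,
    pops = list(pop_spec("P", F = 0.05, n = 0)),
    pair = pair_spec("P", depth = 2), seed = 8))
  path <- file.path(tempdir(), "rt.tsv")
  write_pileup(sim$pair$pileup1, sim$panel, path)
  back <- read_pileup(path, sim$panel)
  expect_equal(back$obs[order(back$obs$site, back$obs$bq, back$obs$mq), ],
               sim$pair$pileup1$obs[order(sim$pair$pileup1$obs$site,
                                          sim$pair$pileup1$obs$bq,
                                          sim$pair$pileup1$obs$mq), ],
               ignore_attr = TRUE)
})
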