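lp_panel <- function() {
  v <- lp_variants()
  snp_panel(snp_id = v$variant, chrom = v$chrom, physical_pos = v$pos,
            allele1 = v$ancestral, allele2 = v$derived)
}

lp_pileup <- function(panel, site, base) {
  pileup_data("s1", site, base, rep(35L, length(site)),
              rep(35L, length(site)))
}

test_that("sex inference from X/Y read counts", {
  xx <- infer_sex(10000, 0)
  expect_equal(xx$ry, 0)
  expect_equal(xx$call, "XX")
  xy <- infer_sex(5000, 5000)
  expect_equal(xy$ry, 0.5)
  expect_equal(xy$call, "XY")
  few <- infer_sex(30, 20, min_reads = 100)
  expect_equal(few$call, "indeterminate")
  none <- infer_sex(0, 0)
  expect_equal(none$call, "indeterminate")
  # borderline Ry with a wide interval stays indeterminate
  mid <- infer_sex(97, 3)
  expect_equal(mid$call, "indeterminate")
})

test_that("sex call recovers the karyotype from proportional counts", {
  # X and Y target sizes give males Ry ~ 0.17 of X+Y reads; females only
  # mismapping noise (~0.2% of X reads)
  set.seed(55)
  calls <- replicate(200, {
    male <- runif(1) < 0.5
    n <- 1500
    ny <- rbinom(1, n, if (male) 0.17 else 0.002)
    list(truth = if (male) "XY" else "XX",
         call = infer_sex(n - ny, ny)$call)
  }, simplify = FALSE)
  agree <- vapply(calls, function(x) x$call == x$truth, NA)
  expect_gte(mean(agree), 0.99)
})

test_that("heterozygote and phenotype calls follow the evidence", {
  panel <- lp_panel()
  # -13915T/G is panel row for that variant; find its site index
  site_13915 <- which(panel$snp_id == "-13915T/G")
  pu <- lp_pileup(panel, rep(site_13915, 9),
                  c(2, 2, 2, 2, 2, 1, 1, 1, 1))  # 5 derived, 4 ancestral
  res <- screen_variants(pu, panel)
  row <- res[res$variant == "-13915T/G", ]
  expect_equal(row$n_derived, 5L)
  expect_equal(row$n_ancestral, 4L)
  expect_equal(row$genotype, "het")
  expect_equal(row$phenotype, "positive")   # dominant: het suffices
  # remaining LP variants have no coverage -> no_call
  expect_true(all(res$genotype[res$variant != "-13915T/G"] == "no_call"))
})

test_that("zero coverage yields no_call everywhere", {
  panel <- lp_panel()
  pu <- lp_pileup(panel, integer(), integer())
  res <- screen_variants(pu, panel)
  expect_true(all(res$genotype == "no_call"))
  expect_true(all(res$phenotype == "no_call"))
  expect_true(all(res$note == "no coverage"))
})

test_that("homozygote calls need min_hom unopposed reads", {
  panel <- lp_panel()
  v <- "-13910C/T"
  s <- which(panel$snp_id == v)   # panel is position-sorted
  pick <- function(res) res[res$variant == v, ]
  # single unopposed derived read: no_call, not hom_der
  one <- pick(screen_variants(lp_pileup(panel, s, 2L), panel))
  expect_equal(one$genotype, "no_call")
  # three unopposed derived reads: hom_der
  three <- pick(screen_variants(lp_pileup(panel, rep(s, 3), rep(2L, 3)),
                                panel))
  expect_equal(three$genotype, "hom_der")
  expect_equal(three$phenotype, "positive")
  # ten ancestral reads at a recessive variant: hom_anc, negative
  rec <- lp_variants()
  rec$inheritance <- "recessive"
  anc <- pick(screen_variants(lp_pileup(panel, rep(s, 10), rep(1L, 10)),
                              panel, variants = rec))
  expect_equal(anc$genotype, "hom_anc")
  expect_equal(anc$phenotype, "negative")
  # recessive het is a carrier, not affected
  het <- pick(screen_variants(lp_pileup(panel, rep(s, 4),
                                        c(1L, 1L, 2L, 2L)),
                              panel, variants = rec))
  expect_equal(het$genotype, "het")
  expect_equal(het$phenotype, "negative")
})

test_that("calls are monotone: derived evidence never flips positive to negative", {
  panel <- lp_panel()
  s <- 2L
  for (nd in 1:6) {
    pu <- lp_pileup(panel, rep(s, nd + 2), c(rep(2L, nd), 1L, 1L))
    res <- screen_variants(pu, panel)
    expect_equal(res$phenotype[res$variant == panel$snp_id[s]], "positive")
  }
})

test_that("dominant phenotype is positive iff genotype carries a derived allele", {
  panel <- lp_panel()
  cases <- list(list(b = c(1L, 1L, 1L), gt = "hom_anc", ph = "negative"),
                list(b = c(1L, 2L), gt = "het", ph = "positive"),
                list(b = c(2L, 2L, 2L), gt = "hom_der", ph = "positive"))
  for (cs in cases) {
    res <- screen_variants(lp_pileup(panel, rep(3L, length(cs$b)), cs$b),
                           panel)
    expect_equal(res$genotype[res$variant == panel$snp_id[3]], cs$gt)
    expect_equal(res$phenotype[res$variant == panel$snp_id[3]], cs$ph)
  }
})

test_that("off-panel variant sites are reported, not errors", {
  panel <- toy_panel()
  res <- screen_variants(pileup_data("x", integer(), integer(), integer(),
                                     integer()), panel)
  expect_true(all(res$genotype == "no_call"))
  expect_true(all(res$note == "site not in panel"))
})

test_that("variant tables round-trip through YAML", {
  path <- file.path(tempdir(), "variants.yaml")
  v <- lp_variants()
  yaml::write_yaml(list(variants = lapply(seq_len(nrow(v)), function(i)
    as.list(v[i, ]))), path)
  back <- read_variant_table(path)
  expect_equal(back, v)
})
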