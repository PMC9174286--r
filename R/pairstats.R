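#' Pairwise mismatch distance between two pseudohaploid genomes
#'
#' The fraction of sites, among those called in both genomes, where the two
#' calls differ. For two unrelated individuals from a population with
#' allele-frequency vector p this estimates the mean of `2 p (1 - p)`; for
#' the two halves of a pseudo-twin pair it estimates half of that. Standard
#' error by weighted block jackknife.
#'
#' @param g1,g2 `pseudohap` genomes on the same panel.
#' @param panel the shared [snp_panel].
#' @param partition optional [block_partition]; built over the shared sites
#'   with `n_blocks` blocks when omitted.
#' @param n_blocks block count used when `partition` is NULL.
#' @param sites optional integer vector restricting the comparison to a site
#'   subset (e.g. an ascertained set).
#' @return A `jk_result` (estimate, se, z, n_sites, n_blocks).
#' @export
mismatch_distance <- function(g1, g2, panel, partition = NULL,
                              n_blocks = 50L, sites = NULL) {
  shared <- which(!is.na(g1$calls) & !is.na(g2$calls))
  if (!is.null(sites)) shared <- intersect(shared, sites)
  if (!length(shared)) stop("zero overlapping called sites")
  if (is.null(partition)) {
    partition <- block_partition(panel, shared,
                                 min(n_blocks, length(shared)))
  }
  diff <- as.numeric(g1$calls[shared] != g2$calls[shared])
  ps <- block_sums(cbind(diff, 1), shared, partition)
  jackknife(ps, weights = ps[, 2],
            g = function(s) s[1] / s[2], n_sites = length(shared))
}

#' Reference-free pseudo-twin kinship test for two low-coverage individuals
#'
#' Compares the between-individual pseudohaploid distance with the two
#' within-individual pseudo-twin distances. Because each pseudo-twin pair
#' derives from one diploid genome, its mismatch rate is half the expected
#' distance of an unrelated pair from the same population; the ratio
#' `d_between / mean(d_within)` therefore has expectation `2 (1 - theta)`
#' for kinship coefficient theta: 2.0 for unrelated individuals, 1.5 for
#' first-degree relatives, 1.0 for identical genomes. No external reference
#' panel or allele frequencies are needed.
#'
#' @param twins1,twins2 `pseudo_twins` objects for the two individuals.
#' @param single1,single2 `pseudohap` genomes for the between-individual
#'   distance (drawn independently of the twin pairs).
#' @param panel the shared [snp_panel].
#' @param partition optional [block_partition]; defaults to `n_blocks`
#'   blocks over the union of sites used by the three distances.
#' @param n_blocks block count when `partition` is NULL.
#' @param gate multiple of the ratio's jackknife SE within which the ratio
#'   must fall of an expected value to be classified (default 3).
#' @return A list of class `kinship_result`: the three distances
#'   (`jk_result`s), `ratio`, `se_ratio`, `z_unrelated` (distance of the
#'   ratio from 2 in SE units) and `classification` in \{"identical",
#'   "first_degree", "unrelated", "indeterminate"\}.
#' @export
kinship_test <- function(twins1, twins2, single1, single2, panel,
                         partition = NULL, n_blocks = 50L, gate = 3) {
  wi <- !is.na(twins1$twin_a$calls) & !is.na(twins1$twin_b$calls)
  wj <- !is.na(twins2$twin_a$calls) & !is.na(twins2$twin_b$calls)
  bt <- !is.na(single1$calls) & !is.na(single2$calls)
  any_use <- which(wi | wj | bt)
  if (!length(any_use)) stop("zero usable sites across the three comparisons")
  if (is.null(partition)) {
    partition <- block_partition(panel, any_use,
                                 min(n_blocks, length(any_use)))
  }
  ind <- function(mask, a, b) {
    v <- numeric(nrow(panel))
    v[mask] <- as.numeric(a$calls[mask] != b$calls[mask])
    v
  }
  vals <- cbind(
    mi = ind(wi, twins1$twin_a, twins1$twin_b), oi = as.numeric(wi),
    mj = ind(wj, twins2$twin_a, twins2$twin_b), oj = as.numeric(wj),
    mb = ind(bt, single1, single2), ob = as.numeric(bt))
  ps <- block_sums(vals, seq_len(nrow(panel)), partition)
  d_within_1 <- jackknife(ps[, c("mi", "oi")], ps[, "oi"],
                          function(s) s[1] / s[2], n_sites = sum(wi))
  d_within_2 <- jackknife(ps[, c("mj", "oj")], ps[, "oj"],
                          function(s) s[1] / s[2], n_sites = sum(wj))
  d_between <- jackknife(ps[, c("mb", "ob")], ps[, "ob"],
                         function(s) s[1] / s[2], n_sites = sum(bt))
  ratio_fun <- function(s) {
    names(s) <- colnames(vals)
    (s["mb"] / s["ob"]) / (0.5 * (s["mi"] / s["oi"] + s["mj"] / s["oj"]))
  }
  guarded <- (d_within_1$estimate == 0 || d_within_2$estimate == 0) &&
    d_between$estimate > 0
  if (guarded) {
    ratio <- NA_real_; se_ratio <- NA_real_; cls <- "indeterminate"
  } else {
    jk <- jackknife(ps, rowSums(ps[, c("oi", "oj", "ob")]), ratio_fun,
                    n_sites = length(any_use))
    ratio <- unname(jk$estimate)
    se_ratio <- jk$se
    expected <- c(identical = 1.0, first_degree = 1.5, unrelated = 2.0)
    nearest <- which.min(abs(expected - ratio))
    cls <- if (is.finite(se_ratio) && se_ratio > 0 &&
               abs(ratio - expected[nearest]) <= gate * se_ratio) {
      names(expected)[nearest]
    } else "indeterminate"
  }
  structure(list(d_within_1 = d_within_1, d_within_2 = d_within_2,
                 d_between = d_between, ratio = ratio, se_ratio = se_ratio,
                 z_unrelated = if (is.finite(se_ratio) && se_ratio > 0)
                   (ratio - 2) / se_ratio else NA_real_,
                 classification = cls),
            class = "kinship_result")
}

#' @export
print.kinship_result <- function(x, ...) {
  cat(sprintf(paste0("<kinship_result> within: %.4f / %.4f  between: %.4f\n",
                     "  ratio %.3f +/- %.3f  -> %s\n"),
              x$d_within_1$estimate, x$d_within_2$estimate,
              x$d_between$estimate, x$ratio, x$se_ratio, x$classification))
  invisible(x)
}

#' Conditional nucleotide diversity (CND) of a pair of genomes
#'
#' The pairwise mismatch rate between two pseudohaploid genomes restricted
#' to transversion sites that are polymorphic in an ascertainment panel --
#' a within-population diversity measure that is comparable across
#' low-coverage samples because the site set is fixed by the panel rather
#' than by the samples. Transitions are excluded to avoid deamination
#' artefacts.
#'
#' @param g1,g2 `pseudohap` genomes on the panel.
#' @param panel the [snp_panel].
#' @param geno the [genotype_panel] providing ascertainment frequencies.
#' @param ascertain_pops population labels whose pooled sample must be
#'   polymorphic (0 < frequency < 1) at a site for it to count; default all
#'   populations in `geno` (the array as a whole).
#' @param partition optional [block_partition]; built on the ascertained,
#'   jointly-called sites when omitted.
#' @param n_blocks block count when `partition` is NULL.
#' @return A list of class `cnd_result`: `cnd`, `se`, `z`, `n_sites`,
#'   `n_blocks`, `ascertainment`.
#' @export
conditional_nucleotide_diversity <- function(g1, g2, panel, geno,
                                             ascertain_pops = NULL,
                                             partition = NULL,
                                             n_blocks = 50L) {
  stopifnot(inherits(geno, "genotype_panel"))
  if (is.null(ascertain_pops)) ascertain_pops <- unique(geno$ind$pop)
  miss <- setdiff(ascertain_pops, geno$ind$pop)
  if (length(miss)) stop("unknown ascertainment population(s): ",
                         paste(miss, collapse = ", "))
  cols <- geno$ind$pop %in% ascertain_pops
  sub <- geno$geno[, cols, drop = FALSE]
  count1 <- rowSums(sub, na.rm = TRUE)
  total <- 2L * rowSums(!is.na(sub))
  asc <- which(panel$mutation_class == "transversion" &
                 total > 0 & count1 > 0 & count1 < total)
  if (!length(asc)) stop("empty ascertained site set")
  res <- mismatch_distance(g1, g2, panel, partition = partition,
                           n_blocks = n_blocks, sites = asc)
  structure(list(cnd = res$estimate, se = res$se, z = res$z,
                 n_sites = res$n_sites, n_blocks = res$n_blocks,
                 ascertainment = sprintf(
                   "transversions polymorphic in {%s} (%d sites)",
                   paste(ascertain_pops, collapse = ","), length(asc))),
            class = "cnd_result")
}

#' @export
print.cnd_result <- function(x, ...) {
  cat(sprintf("<cnd_result> CND %.4f +/- %.4f over %d sites\n  %s\n",
              x$cnd, x$se, x$n_sites, x$ascertainment))
  invisible(x)
}
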