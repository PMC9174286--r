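#' Per-population allele frequency table
#'
#' Computes the sample frequency of allele1 per population per site from the
#' diploid genotype panel, optionally adding pseudohaploid test individuals
#' as extra (haploid) populations: a single pseudohaploid genome contributes
#' one allele observation per called site, and several can be pooled under
#' one label (the usual way one or two ancient individuals are grouped).
#'
#' @param geno a [genotype_panel].
#' @param pseudo optional named list; each element is a `pseudohap` or a
#'   list of `pseudohap`s pooled under that name.
#' @return A list of class `freq_table` with matrices `freq` (allele1
#'   frequency; NA where no observations) and `count` (number of observed
#'   alleles: 2 per called diploid, 1 per called haploid).
#' @export
allele_frequencies <- function(geno, pseudo = NULL) {
  stopifnot(inherits(geno, "genotype_panel"))
  pops <- unique(geno$ind$pop)
  n <- nrow(geno$geno)
  freq <- matrix(NA_real_, n, 0)
  count <- matrix(0L, n, 0)
  for (pop in pops) {
    sub <- geno$geno[, geno$ind$pop == pop, drop = FALSE]
    tot <- 2L * rowSums(!is.na(sub))
    c1 <- rowSums(sub, na.rm = TRUE)
    freq <- cbind(freq, ifelse(tot > 0, c1 / tot, NA_real_))
    count <- cbind(count, tot)
  }
  colnames(freq) <- colnames(count) <- pops
  if (!is.null(pseudo)) {
    if (is.null(names(pseudo)) || any(!nzchar(names(pseudo)))) {
      stop("pseudo individuals must be a named list")
    }
    for (lab in names(pseudo)) {
      el <- pseudo[[lab]]
      if (inherits(el, "pseudohap")) el <- list(el)
      c1 <- numeric(n); tot <- integer(n)
      for (ph in el) {
        stopifnot(inherits(ph, "pseudohap"))
        called <- !is.na(ph$calls)
        tot <- tot + called
        c1 <- c1 + (!is.na(ph$calls) & ph$calls == 1L)
      }
      freq <- cbind(freq, ifelse(tot > 0, c1 / tot, NA_real_))
      count <- cbind(count, tot)
      colnames(freq)[ncol(freq)] <- colnames(count)[ncol(count)] <- lab
    }
  }
  structure(list(freq = freq, count = count), class = "freq_table")
}

# sites with data in every listed population
complete_sites <- function(ft, pops) {
  miss <- setdiff(pops, colnames(ft$count))
  if (length(miss)) stop("unknown population label(s): ",
                         paste(miss, collapse = ", "))
  which(rowSums(ft$count[, pops, drop = FALSE] > 0) == length(pops))
}

# shared jackknife-of-a-mean driver for f-type numerators
fstat_mean <- function(values, sites, panel, partition, n_blocks) {
  if (is.null(partition)) {
    partition <- block_partition(panel, sites, min(n_blocks, length(sites)))
  }
  ps <- block_sums(cbind(values, 1), sites, partition)
  jackknife(ps, ps[, 2], function(s) s[1] / s[2], n_sites = length(sites))
}

#' Outgroup f3 statistic: shared drift of two populations
#'
#' `f3(A, B; O)` is the mean over usable sites of
#' `(p_A - p_O)(p_B - p_O)`: the amount of genetic drift shared by A and B
#' after their divergence from outgroup O. Larger values mean closer
#' affinity. Sites require data in all three populations; no small-sample
#' heterozygosity correction is applied, which keeps the estimator valid for
#' pseudohaploid (single-read) test populations.
#'
#' @param A,B,O population labels in `ft`.
#' @param ft a [allele_frequencies()] table.
#' @param panel the [snp_panel].
#' @param partition optional [block_partition]; built per statistic when
#'   omitted.
#' @param n_blocks jackknife block count when `partition` is NULL.
#' @return A `jk_result`.
#' @export
f3_outgroup <- function(A, B, O, ft, panel, partition = NULL,
                        n_blocks = 50L) {
  s <- complete_sites(ft, c(A, B, O))
  if (!length(s)) stop("no sites with data in all three populations")
  v <- (ft$freq[s, A] - ft$freq[s, O]) * (ft$freq[s, B] - ft$freq[s, O])
  fstat_mean(v, s, panel, partition, n_blocks)
}

#' f4 statistic
#'
#' `f4(A, B; C, D)` is the mean of `(p_A - p_B)(p_C - p_D)` over sites with
#' data in all four populations; it is linear in each population's allele
#' frequencies and is the building block of admixture-proportion models.
#'
#' @inheritParams f3_outgroup
#' @param C,D further population labels.
#' @return A `jk_result`.
#' @export
f4_stat <- function(A, B, C, D, ft, panel, partition = NULL,
                    n_blocks = 50L) {
  s <- complete_sites(ft, c(A, B, C, D))
  if (!length(s)) stop("no sites with data in all four populations")
  v <- (ft$freq[s, A] - ft$freq[s, B]) * (ft$freq[s, C] - ft$freq[s, D])
  fstat_mean(v, s, panel, partition, n_blocks)
}

#' Patterson's D statistic (ABBA-BABA test)
#'
#' `D(W, X; Y, Z)` is the ratio of sums over usable sites of
#' `(p_W - p_X)(p_Y - p_Z)` to
#' `(p_W + p_X - 2 p_W p_X)(p_Y + p_Z - 2 p_Y p_Z)`. Under the null that
#' (W, X) form a clade relative to (Y, Z) its expectation is zero; the
#' jackknife Z-score tests treeness.
#'
#' @param W,X,Y,Z population labels in `ft`.
#' @inheritParams f3_outgroup
#' @return A `jk_result`.
#' @export
d_statistic <- function(W, X, Y, Z, ft, panel, partition = NULL,
                        n_blocks = 50L) {
  s <- complete_sites(ft, c(W, X, Y, Z))
  if (!length(s)) stop("no sites with data in all four populations")
  pw <- ft$freq[s, W]; px <- ft$freq[s, X]
  py <- ft$freq[s, Y]; pz <- ft$freq[s, Z]
  num <- (pw - px) * (py - pz)
  den <- (pw + px - 2 * pw * px) * (py + pz - 2 * py * pz)
  if (is.null(partition)) {
    partition <- block_partition(panel, s, min(n_blocks, length(s)))
  }
  ps <- block_sums(cbind(num, den), s, partition)
  w <- block_sums(rep(1, length(s)), s, partition)[, 1]
  jackknife(ps, w, function(x) x[1] / x[2], n_sites = length(s))
}

#' Rank candidate populations by outgroup-f3 affinity to a test population
#'
#' Computes `f3(test, candidate; outgroup)` for every candidate and returns
#' the table sorted by decreasing f3 (ties broken lexicographically by
#' label): the top row is the candidate sharing the most drift with the
#' test population.
#'
#' @param test,outgroup population labels.
#' @param candidates character vector of candidate labels.
#' @inheritParams f3_outgroup
#' @return A data.frame with columns `candidate`, `f3`, `se`, `z`,
#'   `n_sites`.
#' @export
rank_affinity <- function(test, candidates, outgroup, ft, panel,
                          partition = NULL, n_blocks = 50L) {
  stopifnot(length(candidates) >= 1)
  rows <- lapply(candidates, function(cand) {
    r <- f3_outgroup(test, cand, outgroup, ft, panel, partition, n_blocks)
    data.frame(candidate = cand, f3 = r$estimate, se = r$se, z = r$z,
               n_sites = r$n_sites, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$f3, out$candidate), , drop = FALSE]
  rownames(out) <- NULL
  out
}
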