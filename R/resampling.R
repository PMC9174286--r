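#' Partition panel sites into contiguous jackknife blocks
#'
#' Splits the usable sites into `n_blocks` contiguous blocks along the
#' (chromosome, position)-sorted SNP map. Chromosome boundaries always start
#' a new block, so every chromosome holding usable sites contributes at least
#' one block; within a chromosome block sizes differ by at most one SNP.
#' Blocks are allocated to chromosomes proportionally to their usable-site
#' counts (largest-remainder rounding), which means the realised block count
#' can exceed `n_blocks` when there are more chromosomes than requested
#' blocks.
#'
#' @param panel a [snp_panel].
#' @param usable integer site indices (or logical mask over panel rows) to
#'   partition; defaults to all sites.
#' @param n_blocks target number of blocks (default 50, comfortably above
#'   the ~40 blocks usually considered sufficient for stable jackknife SEs).
#' @return A list of class `block_partition` with `block_of` (integer vector
#'   over all panel sites; NA outside the usable set), `weights` (SNP count
#'   per block) and `n_blocks`.
#' @export
block_partition <- function(panel, usable = NULL, n_blocks = 50L) {
  n <- nrow(panel)
  if (is.null(usable)) usable <- seq_len(n)
  if (is.logical(usable)) usable <- which(usable)
  usable <- sort(unique(as.integer(usable)))
  if (n_blocks < 1L) stop("n_blocks must be >= 1")
  if (length(usable) < n_blocks) {
    stop(sprintf("fewer usable sites (%d) than blocks (%d)",
                 length(usable), n_blocks))
  }
  chrom <- panel$chrom[usable]
  chroms <- unique(chrom)          # panel is sorted, so chroms are contiguous
  cnt <- as.integer(table(factor(chrom, levels = chroms)))
  # proportional allocation, >= 1 block per chromosome, <= sites available
  quota <- n_blocks * cnt / sum(cnt)
  alloc <- pmax(1L, floor(quota))
  alloc <- pmin(alloc, cnt)
  rem <- n_blocks - sum(alloc)
  if (rem > 0) {
    frac <- quota - floor(quota)
    for (i in order(frac, decreasing = TRUE)) {
      if (rem <= 0) break
      if (alloc[i] < cnt[i]) { alloc[i] <- alloc[i] + 1L; rem <- rem - 1L }
    }
    while (rem > 0) {           # still short: put blocks where sites remain
      i <- which.max(cnt - alloc)
      if (cnt[i] <= alloc[i]) break
      alloc[i] <- alloc[i] + 1L
      rem <- rem - 1L
    }
  }
  block_of <- rep(NA_integer_, n)
  bid <- 0L
  for (i in seq_along(chroms)) {
    sites_i <- usable[chrom == chroms[i]]
    k <- alloc[i]
    q <- length(sites_i) %/% k
    r <- length(sites_i) %% k
    sizes <- c(rep(q + 1L, r), rep(q, k - r))
    block_of[sites_i] <- bid + rep(seq_len(k), times = sizes)
    bid <- bid + k
  }
  structure(list(block_of = block_of,
                 weights = as.integer(table(block_of[usable])),
                 n_blocks = bid),
            class = "block_partition")
}

#' @export
print.block_partition <- function(x, ...) {
  cat(sprintf("<block_partition> %d blocks over %d sites (block size %d-%d)\n",
              x$n_blocks, sum(x$weights), min(x$weights), max(x$weights)))
  invisible(x)
}

# per-block partial sums of a site-indexed value matrix; rows = blocks
# values: matrix sites x q (or vector); sites: panel indices of the rows
block_sums <- function(values, sites, partition) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  blk <- partition$block_of[sites]
  keep <- !is.na(blk)
  rowsum(values[keep, , drop = FALSE], blk[keep])
}

#' Weighted block-jackknife of a ratio-of-sums statistic
#'
#' The statistic must be expressible as `g(column sums of partial)`, where
#' `partial` holds per-block partial sums (one row per block). The estimate
#' uses all blocks; leave-one-block-out estimates feed the weighted
#' jackknife variance of Busing and colleagues, with block weights `m_b`
#' (usually SNP counts). With equal weights this reduces to the classical
#' delete-1 jackknife, and for the mean with singleton blocks the SE equals
#' `sqrt(s^2 / n)` exactly.
#'
#' @param partial numeric matrix, blocks x components, of per-block sums.
#' @param weights per-block weights `m_b` (length `nrow(partial)`);
#'   zero-weight blocks are dropped.
#' @param g function mapping a vector of column totals to the scalar
#'   statistic.
#' @param n_sites number of sites behind the statistic (for reporting).
#' @return A list of class `jk_result`: `estimate`, `se`, `z`, `n_sites`,
#'   `n_blocks`.
#' @export
jackknife <- function(partial, weights, g, n_sites = sum(weights)) {
  if (is.vector(partial)) partial <- matrix(partial, ncol = 1)
  keep <- weights > 0
  partial <- partial[keep, , drop = FALSE]
  weights <- weights[keep]
  B <- nrow(partial)
  tot <- colSums(partial)
  est <- unname(g(tot))
  if (!is.finite(est)) stop("statistic undefined on the full data (zero denominator?)")
  if (B < 2L) {
    return(structure(list(estimate = est, se = NA_real_, z = NA_real_,
                          n_sites = n_sites, n_blocks = B),
                     class = "jk_result"))
  }
  loo <- vapply(seq_len(B), function(b) unname(g(tot - partial[b, ])), 0)
  se <- busing_se(est, loo, weights)
  structure(list(estimate = est, se = se,
                 z = if (se > 0) est / se else if (est == 0) 0 else Inf,
                 n_sites = n_sites, n_blocks = B),
            class = "jk_result")
}

# Busing weighted-jackknife SE for a scalar estimate with leave-one-out
# values `loo` and block weights m_b
busing_se <- function(est, loo, weights) {
  B <- length(loo)
  n <- sum(weights)
  h <- n / weights
  theta_j <- B * est - sum((1 - weights / n) * loo)
  tau <- h * est - (h - 1) * loo
  sqrt(sum((tau - theta_j)^2 / (h - 1)) / B)
}

# vector-valued version: returns the covariance matrix of the estimate
busing_cov <- function(est, loo, weights) {
  B <- nrow(loo)
  n <- sum(weights)
  h <- n / weights
  theta_j <- B * est - colSums((1 - weights / n) * loo)
  tau <- h * matrix(est, B, length(est), byrow = TRUE) - (h - 1) * loo
  dev <- sweep(tau, 2, theta_j)
  crossprod(dev / sqrt(h - 1)) / B
}

#' @export
print.jk_result <- function(x, ...) {
  cat(sprintf("estimate %.6g  SE %.3g  Z %.3g  (%d sites, %d blocks)\n",
              x$estimate, x$se, x$z, x$n_sites, x$n_blocks))
  invisible(x)
}
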