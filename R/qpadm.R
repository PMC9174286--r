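#' Build the f4 equation system for admixture-proportion modelling
#'
#' With pivot right population R1 (the first listed), the system has one row
#' per remaining right population R_{j+1}:
#' `y_j = f4(T, R1; R_{j+1}, R1)` and
#' `X_{j,i} = f4(S_i, R1; R_{j+1}, R1)`.
#' If the target's allele frequencies are a site-wise mixture
#' `p_T = sum_i w_i p_{S_i}`, then `y = X w` exactly, because f4 is linear
#' in its first argument's frequencies. Per-block partial sums are retained
#' so the fitting stage can form jackknife covariances.
#'
#' @param target target population label.
#' @param sources character vector of k source labels.
#' @param rights character vector of m right (reference) labels, m >= k+1;
#'   the first is the pivot.
#' @param ft a [allele_frequencies()] table.
#' @param panel the [snp_panel].
#' @param partition optional [block_partition] (built over the used sites
#'   when omitted).
#' @param n_blocks jackknife block count when `partition` is NULL.
#' @param allsnps if FALSE (default) all f4s use the sites with data in
#'   every involved population (complete cases); if TRUE each f4 uses the
#'   sites available for its own population quadruple.
#' @return A list of class `f4_system` with `y`, `X`, per-block sums and
#'   bookkeeping used by [fit_qpadm()].
#' @export
f4_system <- function(target, sources, rights, ft, panel,
                      partition = NULL, n_blocks = 50L, allsnps = FALSE) {
  k <- length(sources)
  m <- length(rights)
  if (m < k + 1) {
    stop(sprintf("need m >= k+1 right populations (m = %d, k = %d)", m, k))
  }
  pops <- c(target, sources, rights)
  miss <- setdiff(pops, colnames(ft$count))
  if (length(miss)) stop("unknown population label(s): ",
                         paste(miss, collapse = ", "))
  r1 <- rights[1]
  firsts <- c(target, sources)              # left side of each f4 product
  has <- ft$count[, pops, drop = FALSE] > 0
  colnames(has) <- pops
  if (!allsnps) {
    s_all <- which(rowSums(has) == length(pops))
    if (!length(s_all)) stop("no sites with data in all model populations")
  } else {
    # superset of the per-product site sets; uncovered products zero out
    s_all <- which(has[, r1])
    if (!length(s_all)) stop("no sites with data in the pivot right population")
  }
  n_use <- length(s_all)
  P <- (m - 1) * (k + 1)
  prod_mat <- matrix(0, n_use, P)
  cnt_mat <- matrix(0, n_use, P)
  pr1 <- ft$freq[s_all, r1]
  col <- 0L
  for (a in firsts) {
    pa <- ft$freq[s_all, a]
    for (j in 2:m) {
      col <- col + 1L
      pj <- ft$freq[s_all, rights[j]]
      ok <- if (allsnps) {
        has[s_all, a] & has[s_all, r1] & has[s_all, rights[j]]
      } else rep(TRUE, n_use)
      v <- (pa - pr1) * (pj - pr1)
      v[!ok] <- 0
      prod_mat[, col] <- v
      cnt_mat[, col] <- as.numeric(ok)
    }
  }
  if (is.null(partition)) {
    partition <- block_partition(panel, s_all, min(n_blocks, n_use))
  }
  partial <- block_sums(cbind(prod_mat, cnt_mat), s_all, partition)
  weights <- block_sums(rep(1, n_use), s_all, partition)[, 1]
  tot <- colSums(partial)
  sys <- structure(list(partial = partial, weights = weights,
                        m = m, k = k, n_sites = n_use,
                        target = target, sources = sources, rights = rights,
                        partition = partition, allsnps = allsnps),
                   class = "f4_system")
  yx <- f4_system_eval(sys, tot)
  sys$y <- yx$y
  sys$X <- yx$X
  sys
}

# map a vector of column totals to the (y, X) system
f4_system_eval <- function(sys, tot) {
  P <- (sys$m - 1) * (sys$k + 1)
  means <- tot[seq_len(P)] / tot[P + seq_len(P)]
  blockrows <- sys$m - 1
  y <- means[seq_len(blockrows)]
  X <- matrix(means[-seq_len(blockrows)], blockrows, sys$k)
  colnames(X) <- sys$sources
  list(y = y, X = X)
}

# equality-constrained (sum w = 1) quadratic fit: min (y-Xw)' A (y-Xw)
constrained_fit <- function(X, y, Ainv = NULL) {
  k <- ncol(X)
  XtA <- if (is.null(Ainv)) t(X) else t(X) %*% Ainv
  A <- XtA %*% X
  b <- XtA %*% y
  # the minimizer is invariant to scaling the quadratic form; normalising
  # keeps the KKT system well-conditioned when Ainv is extreme
  s <- max(abs(A), .Machine$double.xmin)
  M <- rbind(cbind(A / s, rep(1, k)), c(rep(1, k), 0))
  rhs <- c(b / s, 1)
  sol <- solve(M, rhs)
  sol[seq_len(k)]
}

#' Fit admixture proportions by constrained generalized least squares
#'
#' Models the target's f4 profile as a weighted mixture of the sources'
#' profiles, with weights constrained to sum to one. The fit proceeds in
#' two stages: an equality-constrained ordinary least-squares solution
#' provides residuals whose weighted block-jackknife covariance Omega is
#' then used for one generalized least-squares refinement. Standard errors
#' of the weights come from a block jackknife of the full fitting
#' functional; the model fit p-value is the upper chi-square tail (df =
#' m - k) of the minimized quadratic form. A model is flagged infeasible
#' when any point estimate is negative, regardless of its standard error.
#'
#' @inheritParams f4_system
#' @param ridge value added to Omega's diagonal if it is singular.
#' @return A list of class `admixture_model`: `target`, `sources`,
#'   `rights`, `weights`, `se`, `chisq`, `df`, `p_value`, `feasible`,
#'   `n_sites`, `n_blocks`.
#' @export
fit_qpadm <- function(target, sources, rights, ft, panel,
                      partition = NULL, n_blocks = 50L, allsnps = FALSE,
                      ridge = 1e-9) {
  sys <- f4_system(target, sources, rights, ft, panel,
                   partition = partition, n_blocks = n_blocks,
                   allsnps = allsnps)
  k <- sys$k
  m <- sys$m
  X <- sys$X
  y <- sys$y
  if (qr(X)$rank < k) {
    stop("singular source system: source f4 profiles are collinear")
  }
  B <- nrow(sys$partial)

  # the full fitting functional on a set of blocks: constrained OLS, Busing
  # jackknife covariance of the residual vector at that solution, one GLS
  # refinement. Re-run in full on every leave-one-block-out set so the SEs
  # include the variability of the estimated covariance (reusing one Omega
  # understates them).
  fit_blocks <- function(idx, warn = FALSE) {
    tot <- colSums(sys$partial[idx, , drop = FALSE])
    yx <- f4_system_eval(sys, tot)
    w0 <- constrained_fit(yx$X, yx$y)
    e0 <- as.vector(yx$y - yx$X %*% w0)
    loo_e <- matrix(vapply(idx, function(b) {
      s <- f4_system_eval(sys, tot - sys$partial[b, ])
      as.vector(s$y - s$X %*% w0)
    }, numeric(m - 1)), ncol = m - 1, byrow = TRUE)
    omega <- busing_cov(e0, loo_e, sys$weights[idx])
    oinv <- NULL
    rc <- tryCatch(rcond(omega), error = function(e) 0)
    if (is.finite(rc) && rc > 1e-10) {
      oinv <- tryCatch(solve(omega), error = function(e) NULL)
    }
    if (is.null(oinv) || !all(is.finite(oinv))) {
      if (warn) warning("singular residual covariance; adding ridge to the diagonal")
      oinv <- solve(omega + diag(ridge, m - 1))
    }
    list(w = constrained_fit(yx$X, yx$y, oinv), oinv = oinv, yx = yx)
  }

  full <- fit_blocks(seq_len(B), warn = TRUE)
  w <- full$w
  e <- full$yx$y - full$yx$X %*% w
  chisq <- drop(t(e) %*% full$oinv %*% e)
  df <- m - k
  p <- stats::pchisq(chisq, df, lower.tail = FALSE)

  loo_w <- matrix(vapply(seq_len(B),
                         function(b) fit_blocks(setdiff(seq_len(B), b))$w,
                         numeric(k)), ncol = k, byrow = TRUE)
  se <- sqrt(diag(busing_cov(w, loo_w, sys$weights)))

  names(w) <- names(se) <- sources
  structure(list(target = target, sources = sources, rights = rights,
                 weights = w, se = se, chisq = chisq, df = df,
                 p_value = p, feasible = all(w >= 0),
                 n_sites = sys$n_sites, n_blocks = B,
                 allsnps = allsnps),
            class = "admixture_model")
}

#' @export
print.admixture_model <- function(x, ...) {
  cat(sprintf("<admixture_model> %s ~ %s%s\n", x$target,
              paste(x$sources, collapse = " + "),
              if (!x$feasible) "  (infeasible)" else ""))
  cat(sprintf("  p = %.6g (chisq %.3f, df %d), %d sites, %d blocks\n",
              x$p_value, x$chisq, x$df, x$n_sites, x$n_blocks))
  for (s in x$sources) {
    cat(sprintf("  %-16s %.3f +/- %.3f\n", s, x$weights[[s]], x$se[[s]]))
  }
  invisible(x)
}

#' Fit the full admixture model and all nested source subsets
#'
#' Fits the model with every proper non-empty subset of the sources as well
#' as the full set, each against the same rights, reporting feasibility and
#' fit p-values. Models are ordered by ascending source count, then by
#' descending p-value, so the most parsimonious well-fitting models come
#' first.
#'
#' @inheritParams fit_qpadm
#' @return A list of `admixture_model` objects (class
#'   `admixture_model_list`).
#' @export
nested_model_search <- function(target, sources, rights, ft, panel,
                                partition = NULL, n_blocks = 50L,
                                allsnps = FALSE) {
  k <- length(sources)
  stopifnot(k >= 2)
  subsets <- unlist(lapply(seq_len(k), function(sz)
    utils::combn(sources, sz, simplify = FALSE)), recursive = FALSE)
  fits <- lapply(subsets, function(ss)
    fit_qpadm(target, ss, rights, ft, panel, partition = partition,
              n_blocks = n_blocks, allsnps = allsnps))
  ord <- order(vapply(fits, function(f) length(f$sources), 0L),
               -vapply(fits, function(f) f$p_value, 0))
  structure(fits[ord], class = "admixture_model_list")
}

#' @export
print.admixture_model_list <- function(x, ...) {
  for (f in x) print(f)
  invisible(x)
}
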