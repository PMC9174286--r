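#' Infer chromosomal sex from X and Y read counts
#'
#' Computes the Ry statistic -- the fraction of Y reads among reads mapping
#' to either sex chromosome -- with a normal-approximation binomial
#' confidence interval. Females (XX) produce Ry near zero (only mismapped
#' reads hit Y); males (XY) produce Ry near the X/(X+Y) target-size ratio,
#' well above 0.075. The call is XX when the whole interval sits below
#' `xx_max`, XY when it sits above `xy_min`, and indeterminate otherwise or
#' when coverage is insufficient.
#'
#' @param n_x,n_y retained read counts on the X and Y chromosomes.
#' @param min_reads minimum `n_x + n_y` for a call (default 100).
#' @param xx_max upper Ry bound compatible with XX (default 0.016).
#' @param xy_min lower Ry bound compatible with XY (default 0.075).
#' @param conf confidence level of the interval (default 0.95).
#' @return A list of class `sex_call`: `n_x`, `n_y`, `ry`, `ci`
#'   (length-2 vector), `call` in \{"XX", "XY", "indeterminate"\}.
#' @export
infer_sex <- function(n_x, n_y, min_reads = 100L,
                      xx_max = 0.016, xy_min = 0.075, conf = 0.95) {
  stopifnot(n_x >= 0, n_y >= 0)
  n <- n_x + n_y
  if (n == 0) {
    return(structure(list(n_x = n_x, n_y = n_y, ry = NA_real_,
                          ci = c(NA_real_, NA_real_),
                          call = "indeterminate"), class = "sex_call"))
  }
  ry <- n_y / n
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  half <- zq * sqrt(ry * (1 - ry) / n)
  ci <- c(max(0, ry - half), min(1, ry + half))
  call <- if (n < min_reads) {
    "indeterminate"
  } else if (ci[2] < xx_max) {
    "XX"
  } else if (ci[1] > xy_min) {
    "XY"
  } else "indeterminate"
  structure(list(n_x = n_x, n_y = n_y, ry = ry, ci = ci, call = call),
            class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("<sex_call> Ry = %.4f [%.4f, %.4f] (%d X + %d Y reads) -> %s\n",
              x$ry, x$ci[1], x$ci[2], x$n_x, x$n_y, x$call))
  invisible(x)
}

#' Default lactase-persistence variant table
#'
#' The five regulatory SNPs upstream of LCT (in introns of MCM6) whose
#' derived alleles confer lactase persistence, a dominant trait: one derived
#' allele suffices for adult milk digestion. Positions are GRCh37/hg19;
#' labels give the position relative to the LCT start codon.
#'
#' @return A data.frame with columns `variant`, `chrom`, `pos`,
#'   `ancestral`, `derived`, `inheritance`.
#' @export
lp_variants <- function() {
  data.frame(
    variant = c("-13910C/T", "-13915T/G", "-13907C/G", "-14010G/C",
                "-14107G/A"),
    chrom = "2",
    pos = c(136608646L, 136608641L, 136608649L, 136608546L, 136608449L),
    ancestral = c("C", "T", "C", "G", "G"),
    derived = c("T", "G", "G", "C", "A"),
    inheritance = "dominant",
    stringsAsFactors = FALSE
  )
}

#' Read a variant table from a YAML file
#'
#' Expects a top-level `variants:` list whose entries carry `variant`,
#' `chrom`, `pos`, `ancestral`, `derived` and `inheritance`
#' (dominant/recessive).
#'
#' @param path YAML file.
#' @return A data.frame in the [lp_variants()] layout.
#' @export
read_variant_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$variants)) stop("no 'variants' key in ", path)
  rows <- lapply(cfg$variants, function(v) {
    data.frame(variant = v$variant, chrom = as.character(v$chrom),
               pos = as.integer(v$pos),
               ancestral = toupper(v$ancestral),
               derived = toupper(v$derived),
               inheritance = match.arg(v$inheritance,
                                       c("dominant", "recessive")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen a pileup for phenotype-associated variants
#'
#' For every variant, counts quality-passing reads carrying the derived and
#' the ancestral allele and calls a genotype: heterozygous as soon as both
#' alleles are seen at least once; homozygous only from `min_hom` or more
#' reads of a single allele with none of the other (a single unopposed read
#' is left uncalled, guarding against sequencing error and residual
#' damage). The phenotype call then follows the inheritance mode: dominant
#' traits are positive with at least one called derived allele, recessive
#' traits only when homozygous derived.
#'
#' @param pileup a [pileup_data].
#' @param panel the [snp_panel] the pileup is indexed against.
#' @param variants data.frame as from [lp_variants()] or
#'   [read_variant_table()].
#' @param min_hom minimum unopposed read count for a homozygous call
#'   (default 3).
#' @return A data.frame with one row per variant: read counts, `genotype`
#'   in \{hom_anc, het, hom_der, no_call\}, `phenotype` in \{positive,
#'   negative, no_call\} and a `note` explaining uncalled entries.
#' @export
screen_variants <- function(pileup, panel, variants = lp_variants(),
                            min_hom = 3L) {
  out <- variants
  out$n_derived <- 0L
  out$n_ancestral <- 0L
  out$genotype <- "no_call"
  out$phenotype <- "no_call"
  out$note <- ""
  key <- paste(panel$chrom, panel$physical_pos)
  for (r in seq_len(nrow(variants))) {
    site <- match(paste(variants$chrom[r], variants$pos[r]), key)
    if (is.na(site)) {
      out$note[r] <- "site not in panel"
      next
    }
    alleles <- c(panel$allele1[site], panel$allele2[site])
    anc_code <- match(variants$ancestral[r], alleles)
    der_code <- match(variants$derived[r], alleles)
    if (is.na(anc_code) || is.na(der_code)) {
      out$note[r] <- "variant alleles do not match panel alleles"
      next
    }
    reads <- pileup$obs[pileup$obs$site == site, , drop = FALSE]
    nd <- sum(reads$base == der_code)
    na_ <- sum(reads$base == anc_code)
    out$n_derived[r] <- nd
    out$n_ancestral[r] <- na_
    gt <- if (nd >= 1 && na_ >= 1) {
      "het"
    } else if (nd >= min_hom && na_ == 0) {
      "hom_der"
    } else if (na_ >= min_hom && nd == 0) {
      "hom_anc"
    } else {
      out$note[r] <- if (nd + na_ == 0) "no coverage" else "insufficient reads"
      "no_call"
    }
    out$genotype[r] <- gt
    out$phenotype[r] <- if (gt == "no_call") {
      "no_call"
    } else if (variants$inheritance[r] == "dominant") {
      if (gt %in% c("het", "hom_der")) "positive" else "negative"
    } else {
      if (gt == "hom_der") "positive" else "negative"
    }
  }
  out
}
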