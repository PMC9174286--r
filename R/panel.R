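#' SNP panel: the ascertained biallelic site map
#'
#' Builds the site map shared by every statistic in the package: one row per
#' biallelic SNP with chromosome, 1-based physical position, genetic position
#' (morgans), the two alleles and the mutation class. Sites are sorted by
#' (chromosome, physical position) and SNP identifiers must be unique.
#'
#' The mutation class is `"transition"` exactly when the allele pair is
#' \{C,T\} or \{G,A\}, otherwise `"transversion"`. Transition sites are the
#' ones affected by post-mortem cytosine deamination and can be masked
#' downstream.
#'
#' @param snp_id character vector of unique SNP identifiers.
#' @param chrom chromosome labels (integer or character; ordered numerically
#'   where possible).
#' @param physical_pos 1-based physical positions (base pairs).
#' @param allele1,allele2 single-character nucleotides (A/C/G/T); must differ
#'   at every site.
#' @param genetic_pos genetic positions in morgans (default 0).
#' @return A `data.frame` of class `snp_panel` with columns `snp_id`, `chrom`,
#'   `genetic_pos`, `physical_pos`, `allele1`, `allele2`, `mutation_class`.
#' @examples
#' p <- snp_panel(c("rs1", "rs2"), c(1, 1), c(100, 200),
#'                c("C", "A"), c("T", "C"))
#' p$mutation_class
#' @export
snp_panel <- function(snp_id, chrom, physical_pos, allele1, allele2,
                      genetic_pos = 0) {
  snp_id <- as.character(snp_id)
  chrom <- as.character(chrom)
  n <- length(snp_id)
  stopifnot(length(chrom) == n, length(physical_pos) == n,
            length(allele1) == n, length(allele2) == n)
  genetic_pos <- rep_len(as.numeric(genetic_pos), n)
  allele1 <- toupper(as.character(allele1))
  allele2 <- toupper(as.character(allele2))
  bad <- !(allele1 %in% c("A", "C", "G", "T")) |
    !(allele2 %in% c("A", "C", "G", "T"))
  if (any(bad)) {
    stop("unknown allele characters at panel rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  if (any(allele1 == allele2)) {
    stop("allele1 == allele2 at rows: ",
         paste(utils::head(which(allele1 == allele2), 5L), collapse = ", "))
  }
  if (anyDuplicated(snp_id)) stop("duplicate snp_id values in panel")
  df <- data.frame(
    snp_id = snp_id, chrom = chrom, genetic_pos = genetic_pos,
    physical_pos = as.integer(physical_pos),
    allele1 = allele1, allele2 = allele2,
    mutation_class = ifelse(is_transition(allele1, allele2),
                            "transition", "transversion"),
    stringsAsFactors = FALSE
  )
  ord <- order(chrom_order(df$chrom), df$physical_pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("snp_panel", "data.frame")
  df
}

# numeric-aware chromosome ordering (1..22 before X/Y/MT)
chrom_order <- function(chrom) {
  num <- suppressWarnings(as.numeric(chrom))
  num[is.na(num)] <- 1e6 + as.numeric(factor(chrom[is.na(num)]))
  num
}

is_transition <- function(a1, a2) {
  pair <- paste(pmin(a1, a2), pmax(a1, a2))
  pair == "C T" | pair == "A G"
}

#' Genotype panel: diploid genotypes per individual over a SNP panel
#'
#' Wraps a genotype matrix (counts of `allele1`, in \{0, 1, 2, NA\}) together
#' with its site map and individual metadata. Population allele frequencies
#' and all f-statistics derive from this object.
#'
#' @param panel a [snp_panel].
#' @param ind data.frame with columns `id` and `pop` (and optionally `sex`),
#'   one row per individual.
#' @param geno integer matrix, sites x individuals, values in \{0, 1, 2, NA\}.
#' @return A list of class `genotype_panel` with elements `panel`, `ind`,
#'   `geno`.
#' @export
genotype_panel <- function(panel, ind, geno) {
  stopifnot(inherits(panel, "snp_panel"), is.matrix(geno))
  if (is.null(ind$sex)) ind$sex <- rep("U", length(ind$id))
  ind <- data.frame(id = as.character(ind$id), sex = as.character(ind$sex),
                    pop = as.character(ind$pop), stringsAsFactors = FALSE)
  if (nrow(geno) != nrow(panel) || ncol(geno) != nrow(ind)) {
    stop(sprintf("genotype matrix is %d x %d but panel has %d SNPs and %d individuals",
                 nrow(geno), ncol(geno), nrow(panel), nrow(ind)))
  }
  storage.mode(geno) <- "integer"
  if (length(geno) && !all(is.na(geno))) {
    r <- range(geno, na.rm = TRUE)
    if (r[1] < 0L || r[2] > 2L) stop("genotype values must be 0, 1, 2 or NA")
  }
  dimnames(geno) <- list(panel$snp_id, ind$id)
  structure(list(panel = panel, ind = ind, geno = geno),
            class = "genotype_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("<snp_panel> %d SNPs on %d chromosome(s); %d transversions, %d transitions\n",
              nrow(x), length(unique(x$chrom)),
              sum(x$mutation_class == "transversion"),
              sum(x$mutation_class == "transition")))
  invisible(x)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d SNPs x %d individuals in %d population(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$ind$pop))))
  invisible(x)
}
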