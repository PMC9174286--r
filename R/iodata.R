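#' Read an EIGENSTRAT geno/snp/ind trio
#'
#' Parses the ASCII EIGENSTRAT dialect: `<prefix>.snp` with six whitespace
#' separated columns (id, chrom, genetic position in morgans, physical
#' position, allele1, allele2); `<prefix>.ind` with (id, sex letter,
#' population); `<prefix>.geno` with one row per SNP and one digit per
#' individual, where 0/1/2 count copies of allele1 and 9 is missing.
#'
#' @param prefix path prefix; `.geno`, `.snp` and `.ind` are appended.
#' @return A list with elements `panel` ([snp_panel]) and `geno`
#'   ([genotype_panel]).
#' @seealso [write_eigenstrat()]
#' @export
read_eigenstrat <- function(prefix) {
  paths <- paste0(prefix, c(".geno", ".snp", ".ind"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("missing file(s): ", paste(missing, collapse = ", "))

  snp_lines <- readLines(paths[2])
  snp_lines <- snp_lines[nzchar(trimws(snp_lines))]
  if (length(snp_lines)) {
    fields <- strsplit(trimws(snp_lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf != 6L)) {
      stop(sprintf("format error in %s: line %d has %d fields (expected 6)",
                   paths[2], which(nf != 6L)[1], nf[nf != 6L][1]))
    }
    m <- do.call(rbind, fields)
    panel <- snp_panel(snp_id = m[, 1], chrom = m[, 2],
                       genetic_pos = as.numeric(m[, 3]),
                       physical_pos = as.integer(m[, 4]),
                       allele1 = m[, 5], allele2 = m[, 6])
  } else {
    panel <- empty_panel()
  }

  ind_lines <- readLines(paths[3])
  ind_lines <- ind_lines[nzchar(trimws(ind_lines))]
  if (length(ind_lines)) {
    fields <- strsplit(trimws(ind_lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf != 3L)) {
      stop(sprintf("format error in %s: line %d has %d fields (expected 3)",
                   paths[3], which(nf != 3L)[1], nf[nf != 3L][1]))
    }
    m <- do.call(rbind, fields)
    ind <- data.frame(id = m[, 1], sex = m[, 2], pop = m[, 3],
                      stringsAsFactors = FALSE)
  } else {
    ind <- data.frame(id = character(), sex = character(), pop = character(),
                      stringsAsFactors = FALSE)
  }

  geno_lines <- readLines(paths[1])
  geno_lines <- geno_lines[nzchar(geno_lines)]
  if (length(geno_lines) != nrow(panel)) {
    stop(sprintf("format error in %s: %d genotype rows but %d SNPs in %s",
                 paths[1], length(geno_lines), nrow(panel), paths[2]))
  }
  if (nrow(panel)) {
    widths <- nchar(geno_lines)
    if (any(widths != nrow(ind))) {
      stop(sprintf("format error in %s: line %d has %d genotypes but %d individuals in %s",
                   paths[1], which(widths != nrow(ind))[1],
                   widths[widths != nrow(ind)][1], nrow(ind), paths[3]))
    }
    chars <- matrix(unlist(strsplit(geno_lines, ""), use.names = FALSE),
                    nrow = nrow(panel), byrow = TRUE)
    bad <- !(chars %in% c("0", "1", "2", "9"))
    if (any(bad)) {
      stop(sprintf("format error in %s: line %d contains character '%s'",
                   paths[1], which(bad, arr.ind = TRUE)[1, 1],
                   chars[bad][1]))
    }
    g <- matrix(as.integer(chars), nrow = nrow(panel))
    g[g == 9L] <- NA_integer_
    # .snp order may differ from the sorted panel; realign rows
    raw_ids <- vapply(strsplit(trimws(snp_lines), "[ \t]+"), `[`, "", 1L)
    g <- g[match(panel$snp_id, raw_ids), , drop = FALSE]
  } else {
    g <- matrix(integer(), nrow = 0, ncol = nrow(ind))
  }
  list(panel = panel, geno = genotype_panel(panel, ind, g))
}

#' Write an EIGENSTRAT geno/snp/ind trio
#'
#' Inverse of [read_eigenstrat()]; `read_eigenstrat(write_eigenstrat(...))`
#' reproduces the input objects.
#'
#' @param geno a [genotype_panel].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_eigenstrat <- function(geno, prefix) {
  stopifnot(inherits(geno, "genotype_panel"))
  panel <- geno$panel
  snp_body <- if (nrow(panel)) {
    sprintf("%s\t%s\t%s\t%d\t%s\t%s", panel$snp_id, panel$chrom,
            formatC(panel$genetic_pos, format = "g", digits = 15),
            panel$physical_pos, panel$allele1, panel$allele2)
  } else character()
  writeLines(snp_body, paste0(prefix, ".snp"))
  ind <- geno$ind
  writeLines(if (nrow(ind)) sprintf("%s\t%s\t%s", ind$id, ind$sex, ind$pop)
             else character(),
             paste0(prefix, ".ind"))
  g <- geno$geno
  g[is.na(g)] <- 9L
  writeLines(if (nrow(g)) apply(g, 1, paste, collapse = "") else character(),
             paste0(prefix, ".geno"))
  invisible(prefix)
}

empty_panel <- function() {
  df <- data.frame(snp_id = character(), chrom = character(),
                   genetic_pos = numeric(), physical_pos = integer(),
                   allele1 = character(), allele2 = character(),
                   mutation_class = character(), stringsAsFactors = FALSE)
  class(df) <- c("snp_panel", "data.frame")
  df
}

#' Construct per-site read observations for one individual
#'
#' Internal-facing constructor used both by [read_pileup()] and by the
#' simulator. Bases are stored as integer codes relative to the panel:
#' 1 = allele1, 2 = allele2, 3 = other (neither panel allele; retained but
#' never used in allele counts).
#'
#' @param individual_id sample identifier.
#' @param site integer panel row index of each read.
#' @param base integer base codes (1/2/3).
#' @param bq,mq phred base and mapping qualities per read.
#' @param filters list recording thresholds applied and drop counters.
#' @return A list of class `pileup_data`.
#' @export
pileup_data <- function(individual_id, site, base, bq, mq,
                        filters = list(q_min = 30, Q_min = 30,
                                       n_dropped_quality = 0L,
                                       n_dropped_offpanel = 0L)) {
  stopifnot(length(site) == length(base), length(site) == length(bq),
            length(site) == length(mq))
  ord <- order(site)
  structure(list(
    individual_id = as.character(individual_id),
    obs = data.frame(site = as.integer(site)[ord],
                     base = as.integer(base)[ord],
                     bq = as.integer(bq)[ord], mq = as.integer(mq)[ord]),
    filters = filters
  ), class = "pileup_data")
}

#' @export
print.pileup_data <- function(x, ...) {
  cat(sprintf("<pileup_data> %s: %d reads over %d sites (q>=%s, Q>=%s; dropped %d by quality, %d off-panel)\n",
              x$individual_id, nrow(x$obs), length(unique(x$obs$site)),
              x$filters$q_min, x$filters$Q_min,
              x$filters$n_dropped_quality, x$filters$n_dropped_offpanel))
  invisible(x)
}

#' Read a pileup-style TSV of per-read site observations
#'
#' Expects columns `chrom`, `pos`, `base`, `base_quality`,
#' `mapping_quality` (one row per read observation; lines starting with `#`
#' are comments). Reads failing either quality threshold are dropped and
#' counted; sites absent from the panel are dropped with a warning count.
#' Bases that are neither panel allele are retained with code 3 ("other")
#' but never enter allele counts downstream.
#'
#' @param path pileup TSV file.
#' @param panel the [snp_panel] defining the site space.
#' @param individual_id sample identifier recorded in the result.
#' @param q_min,Q_min minimum base and mapping quality (inclusive;
#'   default 30, the conventional ancient-DNA threshold).
#' @return A [pileup_data] object.
#' @export
read_pileup <- function(path, panel, individual_id = basename(path),
                        q_min = 30, Q_min = 30) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(pileup_data(individual_id, integer(), integer(), integer(),
                       integer(),
                       filters = list(q_min = q_min, Q_min = Q_min,
                                      n_dropped_quality = 0L,
                                      n_dropped_offpanel = 0L)))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    stop(sprintf("malformed pileup line %d in %s: %d fields (expected 5)",
                 lineno[nf != 5L][1], path, nf[nf != 5L][1]))
  }
  m <- do.call(rbind, fields)
  bq <- suppressWarnings(as.integer(m[, 4]))
  mq <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(bq) || anyNA(mq)) {
    stop(sprintf("malformed pileup line %d in %s: non-integer quality",
                 lineno[which(is.na(bq) | is.na(mq))[1]], path))
  }
  site <- match(paste(m[, 1], m[, 2]),
                paste(panel$chrom, panel$physical_pos))
  off <- is.na(site)
  n_off <- sum(off)
  if (n_off) {
    warning(sprintf("%d read(s) at sites absent from the panel were dropped",
                    n_off))
  }
  pass <- !off & bq >= q_min & mq >= Q_min
  n_qual <- sum(!off & !pass)
  base_chr <- toupper(m[, 3])
  site_k <- site[pass]
  code <- ifelse(base_chr[pass] == panel$allele1[site_k], 1L,
                 ifelse(base_chr[pass] == panel$allele2[site_k], 2L, 3L))
  pileup_data(individual_id, site_k, code, bq[pass], mq[pass],
              filters = list(q_min = q_min, Q_min = Q_min,
                             n_dropped_quality = as.integer(n_qual),
                             n_dropped_offpanel = as.integer(n_off)))
}

#' Write per-read observations as a pileup TSV
#'
#' @param pu a [pileup_data] object.
#' @param panel the [snp_panel] the observations are indexed against.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileup <- function(pu, panel, path) {
  stopifnot(inherits(pu, "pileup_data"))
  obs <- pu$obs
  base_chr <- character(nrow(obs))
  base_chr[obs$base == 1L] <- panel$allele1[obs$site[obs$base == 1L]]
  base_chr[obs$base == 2L] <- panel$allele2[obs$site[obs$base == 2L]]
  base_chr[obs$base == 3L] <- "N"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos\tbase\tbase_quality\tmapping_quality", con)
  if (nrow(obs)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d",
                       panel$chrom[obs$site], panel$physical_pos[obs$site],
                       base_chr, obs$bq, obs$mq), con)
  }
  invisible(path)
}
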